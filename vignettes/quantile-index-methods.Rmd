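---
title: "Quantile-index biomarkers: models, estimation, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-index biomarkers: models, estimation, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative pathology summarizes a stained tissue section by a single
number per protein — almost always the mean signal intensity (MSI), the
average of the cellular signal intensities (CSI) over all segmented cancer
cells. Averaging throws away everything else about the distribution of
expression across cells: bimodality from a distinct high-expressing
subpopulation, loss of expression in a subpopulation, heavy upper tails.
This package derives scalar biomarkers that use the *entire* distribution,
by summarizing each tissue with its empirical quantile function
$Q_{n_i}(p)$, $0 < p < 1$, and learning from data which parts of that
function carry outcome information.

Two index families are implemented:

* the **linear quantile index**
  $\mathrm{QI}_i = \int_0^1 \beta(p)\, Q_{n_i}(p)\, dp$,
  with an unknown weight curve $\beta(p)$; and
* the **nonlinear quantile index**
  $\mathrm{nlQI}_i = \int_0^1 F\!\big(p, Q_{n_i}(p)\big)\, dp$,
  with an unknown bivariate surface $F(p, q)$, which lets the effect of a
  quantile depend on its *value* as well as its *position*.

$\beta$ and $F$ are estimated on a training set by penalized
scalar-on-function regression against the outcome of interest — logistic
for binary outcomes, Gaussian for continuous ones, Cox partial likelihood
for right-censored survival — and the fitted index is then computed for
held-out subjects and used like any scalar biomarker.

## Estimation

**Quantile functions.** `empirical_quantile()` uses the left-continuous
generalized inverse: the $k$-th order statistic with
$k = \lceil n p \rceil$ (the classical type-1 quantile, identical to
`quantile(..., type = 1)`). The default probability grid is 19 equally
spaced points $0.05, \dots, 0.95$ with uniform Riemann weights $1/P$; a
99-point grid is available but adds little beyond computation, so a
moderate grid is recommended. Quantiles are tabulated on the log intensity
scale by default, because raw CSI distributions are strongly right-skewed.
Optional symmetric tail trimming (`probability_grid(trim = )`) increases
robustness to outlying cells. Multiple regions of interest per tissue are
tabulated separately and aggregated pointwise (mean by default; min,
median, max available — the choice is exposed because no single convention
is canonical).

**Bases and penalties.** Both $\beta(p)$ and the margins of $F(p,q)$ are
expanded in uniform B-splines with the discrete difference penalty of the
P-spline literature. The knots are equally spaced and *unclamped*
(extending `degree` intervals beyond the domain). This detail matters: on
unclamped uniform knots a coefficient sequence that is linear in the index
is a function exactly linear in $x$, so the second-order difference
penalty annihilates exactly the polynomials of degree < 2, and infinite
smoothing shrinks a margin to an exact straight line rather than a
boundary-warped one. The defaults are 8 basis functions on the $p$-axis
(both models) and 5 on the $q$-axis, cubic, with a second-order penalty.
Equal $p$-resolution is deliberate: with heavy smoothing along $q$ the
tensor surface degenerates to $F(p,q) = a(p) + b(p)\,q$, whose index
(after centering) is exactly a linear quantile index — the nonlinear
family *nests* the linear one, so added flexibility is never a forced
handicap.

**Identifiability.** The functional term enters next to an intercept (or a
Cox baseline hazard), so only contrasts of its values are identified. The
design columns are centered at their training means, which makes the
training-set sum of $\int F(p, Q_i(p))\,dp$ exactly zero for *every*
coefficient vector. Surfaces that depend on $p$ alone contribute the same
constant to every subject; after centering those directions are annihilated
by the design, and the ones also annihilated by the penalty (constant and
linear-in-$p$ surfaces) would make the penalized system exactly singular.
They are removed by an SVD-based reparameterization onto their orthogonal
complement before fitting and restored (as zeros) afterwards.

**Penalized fitting.** Exponential-family models are fitted by penalized
iteratively reweighted least squares with an unpenalized intercept;
survival models by penalized Cox partial likelihood with Breslow tie
handling, Newton iterations, and step halving (risk-set sums are
accumulated from the latest event time down, so a fit costs
$O(nK + EK^2)$ per iteration). Effective degrees of freedom are the trace
of the influence matrix, $\mathrm{tr}\{(H + \lambda S)^{-1} H\}$.
Convergence is declared at a relative objective change below $10^{-8}$
(cap 100 iterations, 20 step halvings). Exact singularity at $\lambda = 0$
is an error; numerically singular systems at $\lambda > 0$ (tiny folds
with quasi-separation) are stabilized by a negligible ridge.

**Smoothing selection.** Smoothing parameters are chosen on a fixed
log-spaced grid (30 points, $10^{-4}$–$10^{6}$) by GCV for
exponential-family fits and by partial-likelihood AIC
($-2\ell + 2\gamma\,\mathrm{edf}$) for Cox fits, with warm starts along
the grid. Two refinements temper the well-known optimism of these criteria:

* an effective-degrees-of-freedom inflation $\gamma = 1.4$, the standard
  guard against occasional undersmoothing in GCV-type selection;
* for the tensor surface, *anisotropic* selection — each margin has its own
  $\lambda$, searched on an 8×8 sub-grid and then profiled: the $p$-margin
  is re-optimized on the full 30-point grid at the selected $q$-margin, so
  the surface search has the same $\lambda_p$ resolution as the linear fit.

Criterion ties resolve to the smoothest candidate (lowest edf, then larger
$\lambda$); an optional `band` argument extends that preference to
candidates within a fixed criterion margin of the minimum, but the default
is strict minimization — a band of 2 was measured to over-smooth on
simulated studies and is not used.

**Orientation and standardization.** The raw index units are meaningless,
and the sign of the fitted coefficients is arbitrary. Fitted models are
sign-adjusted so that the Spearman correlation between training indices
and the training median CSI (the grid column nearest $p = 0.5$) is
non-negative; negation of a centered quantity preserves the
identifiability constraint. Spearman is used for robustness (the
convention is a package choice). For reporting, indices are standardized
by subtracting the median and dividing by the IQR (type-7 quartiles);
constants can be frozen from a reference set, and by default the vector
being standardized supplies its own constants.

**Cross-fitting.** `qindex_crossfit()` assigns subjects to $k$ folds
stratified by event/class status (so every training remainder keeps both
classes, or at least one event) and computes each subject's index from a
model never trained on it. Fold assignment is seed-deterministic.

## Comparator biomarkers

* **MSI** — the per-subject mean CSI, on the log scale by default
  (matching the scale of the index models; the raw-scale option is kept
  because the conventional definition averages raw intensities).
* **OQ (optimal quantile)** — for each grid probability, the standardized
  column $Q(p)$ is fitted as a univariable predictor (logistic or Cox,
  unpenalized); the probability with the largest absolute Wald $z$ wins,
  ties toward the smaller $p$, selection frozen before test application.
  This is a fully specified rendition of the single-best-quantile idea;
  continuous (not dichotomized) quantiles are used.

## The simulator

`simulate_study()` generates paired training/test studies with the
structure the index models are designed for: per-subject log-CSI samples
from 2-component normal mixtures with subject-level random effects in all
mixture parameters, and outcomes driven by a latent risk group.

Random effects: each subject receives a shared intensity shift
$\delta_i \sim N(0, 0.35^2)$ added to both component means — tissue-level
staining variability, the dominant nuisance in real immunofluorescence
data — plus independent per-component mean jitter ($\tau = 0.12$),
log-normal perturbation of the component SDs ($\tau = 0.15$), and a
logit-scale perturbation of the mixing weight ($\tau = 0.3$). The shared
shift is what makes the problem interesting: any single quantile (and the
mean) inherits its full variance, while contrasts between quantile regions
cancel it. Index biomarkers can learn such contrasts; MSI and OQ cannot.

Scenarios (group-level parameters, log scale; low-risk $\pi = 0.65$
throughout):

| scenario | low risk | high risk | structure |
|---|---|---|---|
| A | $\mu=(2.0, 3.0)$, $\sigma=(0.6, 0.8)$ | $\mu=(1.8, 3.8)$, $\sigma=(0.6, 0.5)$ | high risk distinctly bimodal, extra high-expression component |
| B | $\mu=(2.2, 3.0)$, $\sigma=(0.6, 0.8)$ | $\mu=(1.5, 3.0)$, $\sigma=(0.6, 0.8)$ | loss of expression (component 1) marks high risk |
| C | $\mu=(2.0, 3.8)$, $\sigma=(0.6, 0.6)$ | $\mu=(2.0, 4.4)$, $\sigma=(0.6, 0.6)$ | high-expression component (component 2) shifted up |
| D | as A low | as A low | null — no group difference |

These values were calibrated once, before any benchmark was run, against
closed-form and oracle Monte-Carlo targets chosen to reproduce the
qualitative regime the index biomarkers address: group differences
localized in specific quantile ranges, subject-level mean separation weak
(oracle MSI discrimination ≈ 0.6–0.8), single best quantile moderate
(≈ 0.8–0.9), and the full quantile profile strongly informative (≥ 0.95).
They were not adjusted afterwards.

Outcomes: binary events are Bernoulli with high-risk probability 0.61 and
group odds ratio 2.5 (implied low-risk probability 0.3849); survival times
are Weibull by inverse transform (shape 1.5, rate 0.1, group log hazard
ratio $\log 2.5$, administrative censoring at 3), giving roughly 55–75%
events depending on group. Parameter draws, cell draws, and outcome draws
use separate deterministically derived sub-seeds, so a study is fully
reproducible from (spec, seed).

**What the simulator does not emulate.** Cells have no spatial
coordinates, so marks are independent of locations by construction;
intensities within a subject are i.i.d. given the subject's mixture (no
within-tissue spatial correlation, no batch effects between studies);
mixtures have exactly two components. Passing benchmarks on these studies
shows the estimation machinery recovers distributional signals of the
kinds described above — it does not certify performance on real imaging
data, where segmentation error, staining batch effects, and spatial
structure add further variation.

## Evaluation harness

`evaluate_replicate()` trains QI, nlQI and the OQ selection on the
training half (binary or survival outcome), computes all four biomarkers
on the test half, and scores each by the Mann–Whitney AUC for the *true*
risk-group label. AUC uses the exact pairwise U-statistic with half credit
for ties and, by default, the orientation-free value $\max(a, 1-a)$ —
sign adjustment orients indices by median expression, which in
loss-of-expression scenarios points away from risk, and ROC software
conventionally picks the favourable direction. `run_benchmark()` crosses
scenarios, outcome types, sample sizes and grid sizes with
seed-per-replicate bookkeeping; replicate seeds deliberately exclude the
grid size, so 19- versus 99-quantile comparisons are paired on identical
studies. Non-converged fits are recorded with reasons and excluded from
summary quantiles.

The test suite exercises this harness at 120 subjects per group, 100
cells per subject, 19 quantiles and 50 replicates per cell (plus a
200-cell survival configuration and a 19-vs-99 grid comparison) — sizes
chosen to keep the full suite under ten minutes while leaving the median
AUC estimates stable to ±0.005.

Under these conditions the package reproduces the qualitative findings the
indices were designed for: in scenarios A–C both indices beat MSI and OQ
by wide margins (≥ 0.05 in median AUC, typically 0.08–0.35), the null
scenario D is calibrated at 0.5, and grid resolution is immaterial. The
linear and nonlinear indices themselves are statistical ties here — the
per-replicate median difference is exactly zero, and which one's median is
a few thousandths higher varies by cell. That is expected: these scenarios
separate groups through localized mean differences, which a linear
functional captures; the nonlinear index earns its keep when the
quantile–risk relation is non-monotone or level-dependent, and its nesting
construction guarantees it loses essentially nothing when the truth is
linear.

## Numerical choices and degenerate inputs

* Quantile convention: type 1, $k=\lceil np \rceil$; at a jump $p = k/n$
  the left-continuous value is used.
* Integration: uniform weights $1/P$ (Riemann sum on an equally spaced
  grid); no trapezoid end corrections.
* $q$-domain: training range of quantile values widened by 5% per side;
  test values outside are clamped to the boundary with a message (the
  surface is undefined beyond its training support, and clamping is
  deterministic and conservative).
* Empty samples, non-positive intensities under the log transform,
  single-class outcomes, event-free folds, all-identical quantile
  functions, and zero-IQR biomarkers are errors with specific messages;
  zero-variance training medians leave the orientation at +1 with a
  warning.
* Model files are JSON with 17 significant digits, so a round trip through
  `write_qindex()` / `read_qindex()` reproduces index values bit-exactly.

## Limitations

* Smoothing selection is grid search with information criteria, not REML;
  the grids and γ are pragmatic defaults, and selection noise — not
  representational capacity — is the binding constraint on the nonlinear
  index at a few hundred subjects.
* The Cox fitter handles ties by Breslow only, has no stratification,
  time-varying effects, or frailty; proportional-hazards diagnostics are
  out of scope.
* The OQ comparator implements one fully specified selection rule
  (max-|z|, no multiplicity adjustment); published variants differ.
* Real-data concerns — batch normalization of intensities, segmentation
  quality, spatial structure — are upstream of this package.
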