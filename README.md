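# qfindex — quantile-function index biomarkers for single-cell expression data

Quantitative pathology usually reduces a stained tissue to one number per
protein: the **mean signal intensity (MSI)**, the average cellular signal
intensity (CSI) over all segmented cancer cells. The mean discards how
expression is *distributed* across cells — bimodality from a
high-expressing subclone, loss of expression in a subpopulation, heavy
tails — which is often where the prognostic information lives.

`qfindex` derives tissue-level scalar biomarkers from the **entire CSI
distribution**. Each tissue is summarized by its empirical quantile
function `Q(p)` tabulated on a common probability grid, and a
scalar-on-function regression against a clinical outcome learns which
parts of the distribution matter:

* **linear quantile index**: `QI = ∫ β(p) Q(p) dp`, with a P-spline weight
  curve `β(p)` estimated by a penalized functional GLM (binary or Gaussian
  outcome) or a linear functional Cox model (right-censored survival);
* **nonlinear quantile index**: `nlQI = ∫ F(p, Q(p)) dp`, with a
  tensor-product P-spline surface `F(p, q)` estimated by a functional
  additive model or an additive functional Cox model, so the effect of a
  quantile may depend on its value, not only its position.

Both are trained on a training cohort (centering for identifiability,
anisotropic smoothing selection, sign adjustment so that higher index
means higher median expression) and then computed for new subjects, where
they are used like any continuous biomarker. The package also provides the
MSI and optimal-quantile (OQ) comparators, k-fold cross-fitting, ROI
aggregation, a mixture-model study simulator with subject-level random
effects, an AUC benchmark harness, and a command-line interface.

## Worked example

Simulate a two-arm study in which the high-risk group carries a shifted
high-expression mixture component (scenario "C"), train a nonlinear index
on the binary outcome, and evaluate it on the held-out half:

```r
library(qfindex)

spec  <- scenario_spec("C", n_per_group = 80, n_cells = 100, outcome = "binary")
study <- simulate_study(spec, seed = 7)

Q_train <- tabulate_quantiles(study$train$cells, probability_grid())
Q_test  <- tabulate_quantiles(study$test$cells,  probability_grid())

fit <- qindex(Q_train, study$train$outcome, kind = "nonlinear")
fit
#> Fitted nonlinear quantile index (nlQI) model
#>   outcome family: binomial, trained on 160 subjects
#>   grid: 19 probabilities in [0.05, 0.95]
#>   surface basis: 8 x 5, q-domain [-0.245, 6.29]
#>   lambda = 1 / 41750, edf = 3.00, orientation sign = -1

idx <- predict(fit, Q_test, standardize = TRUE)
round(head(idx), 3)
#> te001 te002 te003 te004 te005 te006
#> 1.037 0.300 0.533 0.043 0.422 0.602

auc_mann_whitney(idx, study$test$group == "high", direction = "auto")
#> 0.939

association_report(idx, study$test$outcome)$univariable
#>          term estimate    se     z      p ratio lower upper
#> 1 (Intercept)   -0.167 0.161 -1.04 0.3003 0.847 0.618 1.160
#> 2   biomarker   -0.492 0.248 -1.98 0.0472 0.612 0.376 0.994
```

The index separates the true risk groups with AUC 0.939 and is a
significant predictor of the (noisy) binary outcome in the test set
(OR 0.61 per IQR, p = 0.047; the sign is negative because the index is
oriented by median expression, which runs *against* risk here). The
conventional biomarkers do markedly worse on the same test set — MSI
reaches AUC 0.587, and the optimal single quantile (p = 0.9, selected on
the training set) reaches 0.78 — because a subject-level staining shift
inflates every single-location summary, while the fitted surface uses
contrasts across the quantile function that cancel it.

Useful follow-ups: `plot(fit)` draws the fitted surface (or weight
curve), `write_qindex(fit, "model.json")` /
`read_qindex("model.json")` round-trip the model bit-exactly,
`qindex_crossfit()` produces out-of-fold indices for single-cohort
studies, and `run_benchmark()` reproduces the simulation study across
scenarios A–D.

A command-line interface wrapping the same functions
(`tabulate`, `train`, `predict`, `crossfit`, `simulate`, `benchmark`)
is installed at:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "qfindex.R", package = "qfindex"))') --help
```

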