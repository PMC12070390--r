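# Synthetic single-cell study generator.
#
# Per-subject log-intensity samples are drawn from 2-component normal
# mixtures with subject-level random effects in every mixture parameter:
# a shared subject intensity shift on both component means (tissue-level
# staining variability), independent per-component mean jitter, log-normal
# perturbation of the component SDs, and a logit-scale perturbation of the
# mixing weight. Group structure follows four scenarios:
#   A: high-risk group distinctly bimodal with an extra high-expression
#      component; low-risk components merge into a unimodal shape.
#   B: groups differ in the first (low-expression) component only - loss of
#      expression marks high risk; the second component is shared.
#   C: groups differ in the second (high-expression) component only.
#   D: null - both groups share one distribution.

#' Scenario specification for simulated studies
#'
#' Bundles the group-level mixture parameters, subject-level random-effect
#' scales, sample sizes, and outcome model for one simulation scenario.
#'
#' @param scenario \code{"A"}, \code{"B"}, \code{"C"} or \code{"D"}.
#' @param n_per_group subjects per risk group (default 120).
#' @param n_cells cells (intensity observations) per subject (default 100).
#' @param outcome \code{"binary"} (Bernoulli, event probability 0.61 in the
#'   high-risk group, group odds ratio 2.5) or \code{"survival"} (Weibull
#'   hazard, group log hazard ratio \code{log(2.5)}, administrative
#'   censoring).
#' @param tau_shift SD of the shared subject intensity shift added to both
#'   component means (default 0.35, log-intensity units).
#' @param tau_comp SD of independent per-component mean jitter (default 0.12).
#' @param tau_logsd SD of the log-normal perturbation of component SDs
#'   (default 0.15).
#' @param tau_logitweight SD of the logit-scale perturbation of the mixing
#'   weight (default 0.3).
#' @param p_high high-risk event probability for binary outcomes (0.61).
#' @param odds_ratio high/low odds ratio for binary outcomes (2.5).
#' @param weibull_shape,weibull_rate Weibull baseline parameters for survival
#'   outcomes (1.5, 0.1).
#' @param log_hr group log hazard ratio (default \code{log(2.5)}).
#' @param censor_time administrative censoring time (default 3).
#' @return object of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(scenario = c("A", "B", "C", "D"),
                          n_per_group = 120L, n_cells = 100L,
                          outcome = c("binary", "survival"),
                          tau_shift = 0.35, tau_comp = 0.12,
                          tau_logsd = 0.15, tau_logitweight = 0.3,
                          p_high = 0.61, odds_ratio = 2.5,
                          weibull_shape = 1.5, weibull_rate = 0.1,
                          log_hr = log(2.5), censor_time = 3.0) {
  scenario <- match.arg(scenario)
  outcome <- match.arg(outcome)
  base <- list(pi = 0.65, mu = c(2.0, 3.0), sd = c(0.6, 0.8))
  groups <- switch(scenario,
    A = list(low = base,
             high = list(pi = 0.65, mu = c(1.8, 3.8), sd = c(0.6, 0.5))),
    B = list(low = list(pi = 0.65, mu = c(2.2, 3.0), sd = c(0.6, 0.8)),
             high = list(pi = 0.65, mu = c(1.5, 3.0), sd = c(0.6, 0.8))),
    C = list(low = list(pi = 0.65, mu = c(2.0, 3.8), sd = c(0.6, 0.6)),
             high = list(pi = 0.65, mu = c(2.0, 4.4), sd = c(0.6, 0.6))),
    D = list(low = base, high = base))
  structure(list(scenario = scenario, groups = groups,
                 n_per_group = as.integer(n_per_group),
                 n_cells = as.integer(n_cells), outcome = outcome,
                 tau_shift = tau_shift, tau_comp = tau_comp,
                 tau_logsd = tau_logsd, tau_logitweight = tau_logitweight,
                 p_high = p_high, odds_ratio = odds_ratio,
                 weibull_shape = weibull_shape, weibull_rate = weibull_rate,
                 log_hr = log_hr, censor_time = censor_time),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s: %d subjects/group, %d cells/subject, %s outcome\n",
              x$scenario, x$n_per_group, x$n_cells, x$outcome))
  for (g in c("low", "high")) {
    gp <- x$groups[[g]]
    cat(sprintf("  %-4s pi=%.2f mu=(%.2f, %.2f) sd=(%.2f, %.2f)\n",
                g, gp$pi, gp$mu[1], gp$mu[2], gp$sd[1], gp$sd[2]))
  }
  invisible(x)
}

#' Draw subject-level mixture parameters
#'
#' Perturbs the group-level mixture parameters with the subject random
#' effects: component means receive a shared shift plus independent jitter,
#' SDs a log-normal factor, and the mixing weight a logit-scale shift.
#' With all random-effect scales zero the group parameters are returned
#' exactly.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param group \code{"low"} or \code{"high"}.
#' @return list with \code{pi}, \code{mu} (length 2), \code{sd} (length 2),
#'   \code{group}. Uses the current RNG stream.
#' @export
draw_subject_params <- function(spec, group = c("low", "high")) {
  group <- match.arg(group)
  g <- spec$groups[[group]]
  shift <- stats::rnorm(1L, 0, spec$tau_shift)
  mu <- g$mu + shift + stats::rnorm(2L, 0, spec$tau_comp)
  sd <- g$sd * exp(stats::rnorm(2L, 0, spec$tau_logsd))
  lp <- log(g$pi / (1 - g$pi)) + stats::rnorm(1L, 0, spec$tau_logitweight)
  list(pi = 1 / (1 + exp(-lp)), mu = mu, sd = sd, group = group)
}

#' Simulate a subject's cell intensities
#'
#' Draws \code{n} log-intensities from the subject's 2-component normal
#' mixture and returns them on the raw intensity scale
#' (\code{csi = exp(log-intensity)}), so that the standard log-transforming
#' tabulation recovers the mixture exactly.
#'
#' @param params subject parameters from \code{\link{draw_subject_params}}.
#' @param n number of cells (>= 1).
#' @return numeric vector of \code{n} positive intensities.
#' @export
simulate_cells <- function(params, n) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  comp <- 1L + (stats::runif(n) > params$pi)
  exp(stats::rnorm(n, params$mu[comp], params$sd[comp]))
}

#' Simulate binary outcomes
#'
#' Bernoulli outcomes with the high-risk event probability \code{p_high} and
#' the low-risk probability implied by the group odds ratio:
#' \code{odds_low = odds(p_high) / odds_ratio}. With the defaults
#' (\code{p_high = 0.61}, \code{odds_ratio = 2.5}) the low-risk event
#' probability is about 0.3849.
#'
#' @param group character vector of \code{"low"}/\code{"high"} labels, one
#'   per subject.
#' @param p_high,odds_ratio outcome parameters (defaults 0.61 and 2.5).
#' @return integer 0/1 vector. Uses the current RNG stream.
#' @export
simulate_binary_outcome <- function(group, p_high = 0.61, odds_ratio = 2.5) {
  odds_high <- p_high / (1 - p_high)
  odds_low <- odds_high / odds_ratio
  p_low <- odds_low / (1 + odds_low)
  pr <- ifelse(group == "high", p_high, p_low)
  stats::rbinom(length(group), 1L, pr)
}

#' Simulate right-censored Weibull survival outcomes
#'
#' Latent times are drawn by inverse transform from a Weibull proportional-
#' hazards model, \eqn{T = (-\log U / (\lambda e^{\beta_g}))^{1/\gamma}},
#' with \eqn{\beta_g} the group log hazard ratio applied to high-risk
#' subjects, then administratively censored at \code{censor_time}.
#'
#' @param group character vector of \code{"low"}/\code{"high"} labels.
#' @param shape,rate Weibull shape \eqn{\gamma} and rate \eqn{\lambda}.
#' @param log_hr group log hazard ratio.
#' @param censor_time administrative censoring time.
#' @return data frame with columns \code{time} and \code{event}.
#' @export
simulate_survival_outcome <- function(group, shape = 1.5, rate = 0.1,
                                      log_hr = log(2.5), censor_time = 3.0) {
  if (shape <= 0 || rate <= 0 || censor_time <= 0)
    stop("'shape', 'rate' and 'censor_time' must be positive")
  u <- stats::runif(length(group))
  lam <- rate * exp(log_hr * (group == "high"))
  latent <- (-log(u) / lam)^(1 / shape)
  data.frame(time = pmin(latent, censor_time),
             event = as.integer(latent <= censor_time))
}

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

simulate_half <- function(spec, seed, prefix) {
  n <- spec$n_per_group
  group <- rep(c("low", "high"), each = n)
  ids <- sprintf("%s%03d", prefix, seq_along(group))

  set.seed(derive_seed(seed, paste0(prefix, "-params")))
  params <- lapply(group, function(g) draw_subject_params(spec, g))

  set.seed(derive_seed(seed, paste0(prefix, "-cells")))
  cell_list <- lapply(params, simulate_cells, n = spec$n_cells)
  cells <- data.frame(
    subject_id = rep(ids, each = spec$n_cells),
    csi = unlist(cell_list))

  set.seed(derive_seed(seed, paste0(prefix, "-outcome")))
  if (spec$outcome == "binary") {
    y <- simulate_binary_outcome(group, spec$p_high, spec$odds_ratio)
    outcome <- stats::setNames(y, ids)
  } else {
    sv <- simulate_survival_outcome(group, spec$weibull_shape,
                                    spec$weibull_rate, spec$log_hr,
                                    spec$censor_time)
    outcome <- survival::Surv(sv$time, sv$event)
    rownames(outcome) <- ids
  }
  list(cells = cells, outcome = outcome,
       group = stats::setNames(group, ids), subject_ids = ids)
}

#' Generate a paired training/test study
#'
#' Draws two independent studies (disjoint subject ids) from the same
#' scenario specification: the training half is used to fit index models,
#' the test half to evaluate the resulting biomarkers. Parameter draws,
#' cell draws, and outcome draws use separate RNG sub-streams derived
#' deterministically from \code{seed}, so a study is fully reproducible
#' from \code{(spec, seed)}.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param seed integer master seed.
#' @return object of class \code{"simulated_study"}: a list with
#'   \code{train} and \code{test} (each holding \code{cells},
#'   \code{outcome}, \code{group}, \code{subject_ids}), plus \code{spec}
#'   and \code{seed}.
#' @examples
#' st <- simulate_study(scenario_spec("C", n_per_group = 10, n_cells = 20), seed = 1)
#' table(st$train$group)
#' @export
simulate_study <- function(spec, seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  seed <- as.integer(seed)
  structure(list(train = simulate_half(spec, seed, "tr"),
                 test = simulate_half(spec, seed, "te"),
                 spec = spec, seed = seed),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated study (scenario %s, seed %d): %d train / %d test subjects\n",
              x$spec$scenario, x$seed, length(x$train$subject_ids),
              length(x$test$subject_ids)))
  invisible(x)
}

#' Write a simulated study to CSV files
#'
#' Writes \code{<prefix>_{train,test}_cells.csv} and
#' \code{<prefix>_{train,test}_outcome.csv} (columns: subject_id, group,
#' then y or time/event).
#'
#' @param study a \code{\link{simulate_study}} result.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_study <- function(study, prefix) {
  stopifnot(inherits(study, "simulated_study"))
  paths <- character(0)
  for (half in c("train", "test")) {
    h <- study[[half]]
    pc <- paste0(prefix, "_", half, "_cells.csv")
    utils::write.csv(h$cells, pc, row.names = FALSE)
    po <- paste0(prefix, "_", half, "_outcome.csv")
    if (study$spec$outcome == "binary") {
      out <- data.frame(subject_id = h$subject_ids, group = unname(h$group),
                        y = as.numeric(h$outcome))
    } else {
      out <- data.frame(subject_id = h$subject_ids, group = unname(h$group),
                        time = h$outcome[, 1L], event = h$outcome[, 2L])
    }
    utils::write.csv(out, po, row.names = FALSE)
    paths <- c(paths, pc, po)
  }
  invisible(paths)
}
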