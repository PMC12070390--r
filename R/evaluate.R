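#' Mann-Whitney AUC
#'
#' Area under the ROC curve as the pairwise U-statistic: the proportion of
#' (case, control) pairs in which the case scores higher, counting ties as
#' 1/2. Equivalent to the trapezoidal ROC area and exact under ties.
#'
#' @param scores numeric biomarker values.
#' @param labels 0/1 (or logical) group labels; both classes must be present.
#' @param direction \code{"higher"} computes the AUC as-is (cases expected
#'   to score higher); \code{"auto"} returns \code{max(a, 1 - a)}, i.e. the
#'   orientation-free discrimination, matching how ROC software picks the
#'   direction automatically.
#' @return AUC in [0, 1].
#' @examples
#' auc_mann_whitney(c(3, 2, 1, 2), c(1, 1, 0, 0))  # 0.875
#' @export
auc_mann_whitney <- function(scores, labels,
                             direction = c("higher", "auto")) {
  direction <- match.arg(direction)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                      # midranks handle ties as 1/2 credit
  a <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (direction == "auto") max(a, 1 - a) else a
}

#' Evaluate one simulated replicate
#'
#' Trains the QI, nlQI and optimal-quantile models on the training half of a
#' simulated study, computes all four biomarkers (nlQI, QI, MSI, OQ) for the
#' test half, and scores each by AUC for discriminating the true high-risk
#' group. Model training uses the simulated outcome (binary or survival);
#' the AUC always targets group membership.
#'
#' @param study a \code{\link{simulate_study}} result.
#' @param grid \code{\link{probability_grid}} on which quantile functions
#'   are tabulated (default 19 points).
#' @param direction AUC orientation passed to
#'   \code{\link{auc_mann_whitney}}; \code{"auto"} (default) mirrors ROC
#'   software that picks the favourable direction.
#' @param lambda_grid smoothing-parameter grid for the index models.
#' @param ... further arguments passed to \code{\link{qindex}}.
#' @return data frame with one row per biomarker: \code{biomarker},
#'   \code{auc}, \code{converged}, \code{note}.
#' @export
evaluate_replicate <- function(study, grid = probability_grid(),
                               direction = c("auto", "higher"),
                               lambda_grid = default_lambda_grid(), ...) {
  direction <- match.arg(direction)
  stopifnot(inherits(study, "simulated_study"))
  Qtr <- tabulate_quantiles(study$train$cells, grid)
  Qte <- tabulate_quantiles(study$test$cells, grid)
  y_te <- as.numeric(study$test$group == "high")

  res <- list()
  add <- function(name, value, converged = TRUE, note = "") {
    res[[length(res) + 1L]] <<- data.frame(
      biomarker = name,
      auc = if (is.null(value)) NA_real_
            else auc_mann_whitney(value, y_te, direction = direction),
      converged = converged, note = note, stringsAsFactors = FALSE)
  }

  for (kind in c("nonlinear", "linear")) {
    name <- if (kind == "nonlinear") "nlQI" else "QI"
    fit <- tryCatch(qindex(Qtr, study$train$outcome, kind = kind,
                           lambda_grid = lambda_grid, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      add(name, NULL, converged = FALSE, note = conditionMessage(fit))
    } else {
      add(name, predict(fit, Qte), converged = fit$converged,
          note = fit$fit_message)
    }
  }
  add("MSI", msi(study$test$cells))
  oq <- tryCatch(suppressWarnings(oq_train(Qtr, study$train$outcome)),
                 error = function(e) e)
  if (inherits(oq, "error")) {
    add("OQ", NULL, converged = FALSE, note = conditionMessage(oq))
  } else {
    add("OQ", oq_apply(oq, Qte))
  }
  do.call(rbind, res)
}

#' Run the simulation benchmark
#'
#' Loops over scenarios, outcome kinds, sample sizes, and grid sizes,
#' simulating independent training/test replicates and scoring all four
#' biomarkers on each. Replicate seeds are derived deterministically from
#' the master seed and recorded in the output, so any replicate can be
#' replayed in isolation.
#'
#' @param scenarios character vector of scenario labels (subset of A-D).
#' @param outcomes \code{"binary"}, \code{"survival"}, or both.
#' @param n_per_group,n_cells vectors of subjects per group / cells per
#'   subject to cross.
#' @param grid_sizes quantile-grid sizes to cross (19 and/or 99).
#' @param n_reps replicates per configuration cell.
#' @param seed master seed.
#' @param lambda_grid smoothing-parameter grid for the index models.
#' @param verbose print progress lines.
#' @return data frame with one row per replicate x biomarker:
#'   configuration columns, \code{replicate}, \code{seed}, \code{biomarker},
#'   \code{auc}, \code{converged}, \code{note}.
#' @seealso \code{\link{summarize_benchmark}}
#' @export
run_benchmark <- function(scenarios = c("A", "B", "C", "D"),
                          outcomes = c("binary", "survival"),
                          n_per_group = 120L, n_cells = 100L,
                          grid_sizes = 19L, n_reps = 50L, seed = 1L,
                          lambda_grid = default_lambda_grid(),
                          verbose = FALSE) {
  rows <- list()
  for (sc in scenarios) for (ok in outcomes)
    for (np in n_per_group) for (nc in n_cells) for (gs in grid_sizes) {
      grid <- probability_grid(gs)
      for (r in seq_len(n_reps)) {
        # grid size is excluded from the replicate seed so that grid-size
        # comparisons see the same simulated studies
        child <- derive_seed(seed, paste(sc, ok, np, nc, r, sep = "|"))
        spec <- scenario_spec(sc, n_per_group = np, n_cells = nc, outcome = ok)
        study <- simulate_study(spec, child)
        rep_res <- evaluate_replicate(study, grid = grid,
                                      lambda_grid = lambda_grid)
        rep_res <- cbind(data.frame(scenario = sc, outcome = ok,
                                    n_per_group = np, n_cells = nc,
                                    grid_size = gs, replicate = r,
                                    seed = child, stringsAsFactors = FALSE),
                         rep_res)
        rows[[length(rows) + 1L]] <- rep_res
      }
      if (verbose)
        message(sprintf("scenario %s / %s: %d x %d cells, grid %d done",
                        sc, ok, np, nc, gs))
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a benchmark table
#'
#' Median and quartiles of the AUC distribution per configuration cell and
#' biomarker; non-converged replicates are excluded from the quantiles but
#' counted.
#'
#' @param results data frame from \code{\link{run_benchmark}}.
#' @return summary data frame.
#' @export
summarize_benchmark <- function(results) {
  key <- interaction(results$scenario, results$outcome, results$n_per_group,
                     results$n_cells, results$grid_size, results$biomarker,
                     drop = TRUE)
  parts <- split(results, key)
  out <- lapply(parts, function(d) {
    ok <- d$converged & is.finite(d$auc)
    qs <- if (any(ok)) stats::quantile(d$auc[ok], c(0.25, 0.5, 0.75), type = 7)
          else rep(NA_real_, 3L)
    data.frame(scenario = d$scenario[1L], outcome = d$outcome[1L],
               n_per_group = d$n_per_group[1L], n_cells = d$n_cells[1L],
               grid_size = d$grid_size[1L], biomarker = d$biomarker[1L],
               n_reps = nrow(d), n_failed = sum(!ok),
               auc_q1 = unname(qs[1L]), auc_median = unname(qs[2L]),
               auc_q3 = unname(qs[3L]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$scenario, out$outcome, out$n_per_group, out$n_cells,
            out$grid_size, out$biomarker), ]
}

#' Univariable and adjusted association models for a biomarker
#'
#' Fits the biomarker (typically standardized) as a continuous predictor of
#' the outcome, univariably and optionally adjusted for scalar covariates,
#' reporting odds/hazard ratios with Wald 95\% intervals.
#'
#' @param biomarker named numeric vector of per-subject values.
#' @param outcome 0/1 vector, numeric vector, or \code{survival::Surv}
#'   aligned with \code{biomarker}.
#' @param covariates optional data frame of scalar adjustment covariates.
#' @return list with \code{univariable} and (if covariates were supplied)
#'   \code{adjusted} coefficient tables (see \code{\link{fit_unpenalized}}).
#' @export
association_report <- function(biomarker, outcome, covariates = NULL) {
  X1 <- cbind(biomarker = as.numeric(biomarker))
  uni <- fit_unpenalized(X1, outcome)
  out <- list(univariable = uni$table, family = uni$family)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    Xa <- cbind(biomarker = as.numeric(biomarker),
                as.matrix(covariates))
    out$adjusted <- fit_unpenalized(Xa, outcome)$table
  }
  out
}
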