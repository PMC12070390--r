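#' Fit a quantile-index biomarker model
#'
#' Trains a scalar-on-function regression of an outcome on per-subject
#' empirical quantile functions and packages the result as a reusable
#' biomarker model. Two kinds are available:
#' \describe{
#'   \item{\code{"nonlinear"} (nlQI)}{the index is
#'     \eqn{\int_0^1 F(p, Q_i(p))\,dp} with a bivariate surface \eqn{F}
#'     represented by a tensor product of P-splines, so the effect of the
#'     quantile function may vary nonlinearly in both the probability and
#'     the quantile value.}
#'   \item{\code{"linear"} (QI)}{the index is
#'     \eqn{\int_0^1 \beta(p)\, Q_i(p)\,dp} with a P-spline weight curve
#'     \eqn{\beta(p)}.}
#' }
#' The functional term is centered so that its training-set contributions
#' sum to zero (identifiability next to the intercept or baseline hazard),
#' the smoothing parameter is chosen by GCV (exponential family) or
#' partial-likelihood AIC (Cox) on a grid, and the fitted coefficients are
#' sign-adjusted so that higher index values correspond to higher median
#' signal intensity.
#'
#' @param Q a \code{\link{quantile_matrix}} of training subjects.
#' @param outcome training outcome aligned with the rows of \code{Q}: a 0/1
#'   vector (logistic), a numeric vector (Gaussian), or a
#'   \code{survival::Surv} object (penalized Cox).
#' @param kind \code{"nonlinear"} (default) or \code{"linear"}.
#' @param family \code{"binomial"}, \code{"gaussian"}, or \code{"cox"};
#'   inferred from the outcome when \code{NULL}.
#' @param n_basis_p number of basis functions on the probability axis
#'   (default 8 for both kinds, so that with heavy q-margin smoothing the
#'   tensor surface degenerates to exactly the linear index family).
#' @param n_basis_q number of basis functions on the quantile-value axis
#'   (tensor surface only, default 5).
#' @param penalty_order difference order of the P-spline penalty (default 2).
#' @param lambda optional fixed smoothing parameter (scalar, or length 2
#'   giving the p- and q-margin parameters of the tensor surface); when
#'   \code{NULL} (default) smoothing is selected on a grid: a 1-D grid for
#'   the linear model, a 2-D (anisotropic, per-margin) grid for the tensor
#'   surface.
#' @param lambda_grid candidate smoothing parameters
#'   (default \code{\link{default_lambda_grid}}); for the tensor surface a
#'   subset of at most 8 values per margin is used to keep the 2-D search
#'   affordable.
#' @param sign_adjust orient the index to increase with median intensity
#'   (default TRUE).
#' @param q_expand fractional widening of the quantile-value domain beyond
#'   the training range (default 0.05); test values outside are clamped.
#' @return An object of class \code{"qindex"}; see
#'   \code{\link{predict.qindex}}, \code{\link{coef.qindex}},
#'   \code{\link{plot.qindex}}.
#' @examples
#' set.seed(1)
#' cells <- data.frame(subject_id = rep(1:40, each = 60),
#'                     csi = exp(rnorm(2400, rep(rnorm(40, 2, 0.5), each = 60), 0.6)))
#' Q <- tabulate_quantiles(cells, probability_grid())
#' y <- rbinom(40, 1, plogis(scale(rowMeans(Q))))
#' fit <- qindex(Q, y, kind = "linear")
#' head(predict(fit, Q))
#' @export
qindex <- function(Q, outcome, kind = c("nonlinear", "linear"), family = NULL,
                   n_basis_p = NULL, n_basis_q = 5L, penalty_order = 2L,
                   lambda = NULL, lambda_grid = default_lambda_grid(),
                   sign_adjust = TRUE, q_expand = 0.05) {
  kind <- match.arg(kind)
  stopifnot(inherits(Q, "quantile_matrix"))
  grid <- attr(Q, "grid")
  M <- nrow(Q)
  if (M < 20L)
    warning("fewer than 20 training subjects; index estimates will be unstable")
  if (diff(range(unclass(Q))) <= 0)
    stop("degenerate functional predictor: all quantile functions identical")
  if (is.null(family)) {
    family <- if (survival::is.Surv(outcome)) "cox"
      else if (all(outcome %in% c(0, 1))) "binomial" else "gaussian"
  }
  family <- match.arg(family, c("binomial", "gaussian", "cox"))
  if (family == "cox" && !survival::is.Surv(outcome))
    stop("cox family requires a survival::Surv outcome")
  n_out <- if (family == "cox") nrow(outcome) else length(outcome)
  if (n_out != M) stop("outcome length does not match the quantile matrix")
  if (is.null(n_basis_p)) n_basis_p <- 8L

  basis_p <- basis_spec(n_basis_p, degree = 3L,
                        domain = range(grid$p) + c(-1, 1) * 1e-8)
  if (kind == "linear") {
    des <- linear_functional_design(Q, basis_p)
    S <- unclass(difference_penalty(n_basis_p, penalty_order))
    S_parts <- NULL
    basis_q <- NULL; q_dom <- NULL
  } else {
    q_dom <- q_domain_from(Q, expand = q_expand)
    basis_q <- basis_spec(n_basis_q, degree = 3L, domain = q_dom)
    des <- tensor_functional_design(Q, basis_p, basis_q)
    S_parts <- tensor_penalty_parts(n_basis_p, n_basis_q, penalty_order)
    S <- S_parts$p + S_parts$q
  }
  cen <- center_columns(des$X)

  # Absorb the identifiability constraint: directions that are annihilated
  # by both the centered design and the penalty (for the tensor term,
  # surfaces constant or linear in p alone, whose contribution to every
  # index is a constant) are removed by reparameterizing onto their
  # orthogonal complement. Otherwise the penalized system is singular.
  Z <- constraint_complement(cen$X, S)
  Xr <- cen$X %*% Z
  reduce <- function(M) {
    R <- t(Z) %*% M %*% Z
    (R + t(R)) / 2
  }

  base_fit <- if (family == "cox") {
    time <- outcome[, 1L]; status <- outcome[, 2L]
    function(S_eff, lam, start)
      fit_penalized_cox(Xr, time, status, S_eff, lam, start = start)
  } else {
    function(S_eff, lam, start)
      fit_penalized_glm(Xr, outcome, S_eff, lam, family = family,
                        start = start)
  }

  if (kind == "linear") {
    Sr <- reduce(S)
    fitter <- function(lam, start) base_fit(Sr, lam, start)
    if (is.null(lambda)) {
      sel <- select_lambda(fitter, lambda_grid)
      fit <- sel$fit; lambda_sel <- sel$fit$lambda; lambda_trace <- sel$trace
    } else {
      fit <- fitter(lambda, NULL); lambda_sel <- lambda; lambda_trace <- NULL
    }
  } else {
    # anisotropic smoothing: each margin gets its own parameter, so the
    # surface can be almost linear in q yet flexible in p (or vice versa)
    SpR <- reduce(S_parts$p); SqR <- reduce(S_parts$q)
    fitter2 <- function(lp, lq, start)
      base_fit(lp * SpR + lq * SqR, 1, start)
    if (is.null(lambda)) {
      mgrid <- marginal_grid(lambda_grid)
      sel <- select_lambda_2d(fitter2, mgrid, mgrid)
      # profile refinement: re-optimize the p-margin on the full candidate
      # grid at the selected q-margin, so the surface search has the same
      # lambda_p resolution as the linear weight-curve fit
      lq_sel <- unname(sel$lambda["q"])
      sel_p <- select_lambda(function(lam, start) fitter2(lam, lq_sel, start),
                             lambda_grid)
      if (sel_p$fit$criterion <= sel$fit$criterion) {
        fit <- sel_p$fit
        lambda_sel <- c(p = sel_p$lambda, q = lq_sel)
      } else {
        fit <- sel$fit
        lambda_sel <- sel$lambda
      }
      lambda_trace <- sel$trace
    } else {
      lam <- rep(as.numeric(lambda), length.out = 2L)
      fit <- fitter2(lam[1L], lam[2L], NULL)
      lambda_sel <- c(p = lam[1L], q = lam[2L]); lambda_trace <- NULL
    }
  }
  fit$coefficients <- drop(Z %*% fit$coefficients)

  model <- structure(list(
    kind = kind, family = family, grid = grid, basis_p = basis_p,
    basis_q = basis_q, q_domain = q_dom, coefficients = fit$coefficients,
    intercept = fit$intercept, centers = cen$centers, sign = 1,
    lambda = lambda_sel, edf = fit$edf, criterion = fit$criterion,
    converged = fit$converged, fit_message = fit$message,
    lambda_trace = lambda_trace, n_train = M,
    scale_tag = attr(Q, "scale_tag"), call = match.call()
  ), class = "qindex")
  if (sign_adjust) model <- sign_adjust(model, Q)
  model
}

# thin a 1-D candidate grid to at most n values for the 2-D tensor search
marginal_grid <- function(lambda_grid, n = 8L) {
  lambda_grid <- sort(as.numeric(lambda_grid))
  if (length(lambda_grid) <= n) return(lambda_grid)
  lambda_grid[round(seq(1L, length(lambda_grid), length.out = n))]
}

#' Orient a quantile-index model by median intensity
#'
#' Flips the sign of all functional coefficients when the Spearman
#' correlation between the training indices and the training median signal
#' (the quantile-matrix column nearest probability 0.5) is negative, so that
#' higher index values always correspond to higher median expression. The
#' centering (identifiability) constraint is preserved, since the negation
#' of a zero-mean quantity has mean zero.
#'
#' @param model a fitted \code{\link{qindex}} model.
#' @param Q_train the training \code{\link{quantile_matrix}}.
#' @return the model, with \code{sign} set to +1 or -1 and coefficients
#'   oriented accordingly.
#' @export
sign_adjust <- function(model, Q_train) {
  stopifnot(inherits(model, "qindex"))
  med_col <- which.min(abs(model$grid$p - 0.5))
  med <- unclass(Q_train)[, med_col]
  if (stats::sd(med) == 0) {
    warning("zero-variance training medians; sign left at +1")
    return(model)
  }
  raw <- compute_index_raw(model, Q_train, apply_sign = FALSE)
  if (stats::sd(raw) == 0) return(model)
  rho <- stats::cor(raw, med, method = "spearman")
  if (!is.na(rho) && rho < 0) {
    model$coefficients <- -model$coefficients
    model$sign <- -model$sign
  }
  model
}

# index values before/after sign, shared by predict() and sign_adjust()
compute_index_raw <- function(model, Q, apply_sign = TRUE) {
  if (!isTRUE(all.equal(attr(Q, "grid")$p, model$grid$p)))
    stop("quantile matrix is not on the model's probability grid; ",
         "re-tabulate the cells on that grid first")
  des <- if (model$kind == "linear") {
    linear_functional_design(Q, model$basis_p)
  } else {
    n_out <- sum(unclass(Q) < model$q_domain[1L] |
                 unclass(Q) > model$q_domain[2L])
    if (n_out > 0)
      message(n_out, " quantile value(s) outside the training domain were clamped")
    tensor_functional_design(Q, model$basis_p, model$basis_q)
  }
  Xc <- center_columns(des$X, centers = model$centers)$X
  # coefficients are stored already oriented; 'sign' records the orientation
  drop(Xc %*% model$coefficients)
}

#' Compute index values for subjects
#'
#' Applies a fitted quantile-index model to new subjects, returning one
#' scalar biomarker value per subject: the quadrature of
#' \eqn{\int \beta(p) Q_i(p) dp} (linear) or \eqn{\int F(p, Q_i(p)) dp}
#' (nonlinear), relative to the model's training centering.
#'
#' @param object a fitted \code{\link{qindex}} model.
#' @param newdata a \code{\link{quantile_matrix}} on the model's probability
#'   grid, or a raw cell table (data frame with \code{subject_id},
#'   \code{csi}), which is tabulated on the model's grid automatically.
#' @param standardize if TRUE, indices are standardized by subtracting the
#'   median and dividing by the interquartile range
#'   (see \code{\link{standardize_index}}).
#' @param ... unused.
#' @return named numeric vector of index values (names = subject ids).
#' @export
predict.qindex <- function(object, newdata, standardize = FALSE, ...) {
  if (is.data.frame(newdata)) {
    newdata <- tabulate_quantiles(newdata, object$grid,
                                  log_transform = identical(object$scale_tag, "log"))
  }
  stopifnot(inherits(newdata, "quantile_matrix"))
  val <- compute_index_raw(object, newdata)
  names(val) <- rownames(newdata)
  if (standardize) val <- standardize_index(val)
  val
}

#' Extract quantile-index model coefficients
#'
#' @param object a fitted \code{\link{qindex}} model.
#' @param ... unused.
#' @return For linear models, the basis coefficients of the weight curve
#'   \eqn{\beta(p)}. For nonlinear models, an \code{n_basis_p x n_basis_q}
#'   matrix of tensor-surface coefficients.
#' @export
coef.qindex <- function(object, ...) {
  if (object$kind == "linear") return(object$coefficients)
  matrix(object$coefficients, object$basis_p$n_basis, object$basis_q$n_basis)
}

#' Evaluate the fitted weight curve or surface
#'
#' @param model a fitted \code{\link{qindex}} model.
#' @param p probabilities at which to evaluate.
#' @param q quantile values (nonlinear models only).
#' @return For linear models, \code{beta(p)} at \code{p}. For nonlinear
#'   models, the matrix \code{F(p, q)} over the grid \code{p x q}.
#' @export
index_surface <- function(model, p = model$grid$p, q = NULL) {
  stopifnot(inherits(model, "qindex"))
  Bp <- bspline_basis(p, model$basis_p)
  if (model$kind == "linear") return(drop(Bp %*% model$coefficients))
  if (is.null(q)) q <- seq(model$q_domain[1L], model$q_domain[2L],
                           length.out = 40L)
  Bq <- bspline_basis(q, model$basis_q)
  Theta <- matrix(model$coefficients, model$basis_p$n_basis,
                  model$basis_q$n_basis)
  Bp %*% Theta %*% t(Bq)
}

#' @export
print.qindex <- function(x, ...) {
  lab <- if (x$kind == "linear") "linear quantile index (QI)"
         else "nonlinear quantile index (nlQI)"
  cat(sprintf("Fitted %s model\n", lab))
  cat(sprintf("  outcome family: %s, trained on %d subjects\n",
              x$family, x$n_train))
  cat(sprintf("  grid: %d probabilities in [%.3g, %.3g]\n",
              length(x$grid$p), min(x$grid$p), max(x$grid$p)))
  if (x$kind == "nonlinear")
    cat(sprintf("  surface basis: %d x %d, q-domain [%.3g, %.3g]\n",
                x$basis_p$n_basis, x$basis_q$n_basis,
                x$q_domain[1L], x$q_domain[2L]))
  else
    cat(sprintf("  weight-curve basis: %d functions\n", x$basis_p$n_basis))
  cat(sprintf("  lambda = %s, edf = %.2f, orientation sign = %+d\n",
              paste(signif(x$lambda, 4), collapse = " / "), x$edf, x$sign))
  if (!x$converged) cat("  WARNING: fit did not converge:", x$fit_message, "\n")
  invisible(x)
}

#' @export
summary.qindex <- function(object, ...) {
  structure(list(model = object), class = "summary.qindex")
}

#' @export
print.summary.qindex <- function(x, ...) {
  print(x$model)
  m <- x$model
  cat(sprintf("  selection criterion (%s): %.5g\n",
              if (m$family == "cox") "partial-likelihood AIC" else "GCV",
              m$criterion))
  if (!is.null(m$lambda_trace)) {
    cat("  smoothing-parameter trace (head):\n")
    print(utils::head(m$lambda_trace, 5L), row.names = FALSE)
  }
  invisible(x)
}

#' Plot a fitted quantile-index model
#'
#' Linear models: the estimated weight curve \eqn{\beta(p)}. Nonlinear
#' models: a filled contour of the estimated surface \eqn{F(p, q)}.
#'
#' @param x a fitted \code{\link{qindex}} model.
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.qindex <- function(x, ...) {
  p <- seq(min(x$grid$p), max(x$grid$p), length.out = 101L)
  if (x$kind == "linear") {
    graphics::plot(p, index_surface(x, p), type = "l",
                   xlab = "p", ylab = expression(beta(p)),
                   main = "Estimated quantile weight curve", ...)
    graphics::abline(h = 0, lty = 3)
  } else {
    q <- seq(x$q_domain[1L], x$q_domain[2L], length.out = 81L)
    Fm <- index_surface(x, p, q)
    graphics::filled.contour(p, q, Fm, xlab = "p", ylab = "q",
                             main = "Estimated index surface F(p, q)",
                             color.palette = grDevices::hcl.colors, ...)
  }
  invisible(x)
}

#' Standardize a biomarker vector
#'
#' Subtracts the median and divides by the interquartile range (quartiles by
#' the usual linear-interpolation convention, type 7), so that indices whose
#' raw units carry no biological meaning become comparable across markers.
#' Constants from a reference set (e.g. the training set) can be supplied to
#' freeze the scaling.
#'
#' @param x numeric biomarker vector.
#' @param constants optional list with elements \code{center} and
#'   \code{scale}; defaults to the median and IQR of \code{x} itself.
#' @return standardized numeric vector with attribute
#'   \code{"constants"} recording the centering used.
#' @export
standardize_index <- function(x, constants = NULL) {
  if (is.null(constants)) {
    constants <- list(center = stats::median(x),
                      scale = stats::IQR(x, type = 7))
  }
  if (!is.finite(constants$scale) || constants$scale <= 0)
    stop("degenerate biomarker: interquartile range is zero")
  out <- (x - constants$center) / constants$scale
  attr(out, "constants") <- constants
  out
}

#' Cross-fitted quantile indices
#'
#' Splits the study into k folds (stratified by event/class status so every
#' training subset retains both outcome classes, or at least one event) and
#' computes each subject's index from a model trained on the other folds.
#'
#' @param Q a \code{\link{quantile_matrix}} for the whole study.
#' @param outcome outcome aligned with \code{Q} (0/1, numeric, or
#'   \code{survival::Surv}).
#' @param k number of folds (>= 2, default 5).
#' @param seed integer seed making the fold assignment reproducible.
#' @param ... passed to \code{\link{qindex}}.
#' @return named numeric vector of out-of-fold index values, in the row
#'   order of \code{Q}.
#' @export
qindex_crossfit <- function(Q, outcome, k = 5L, seed = 1L, ...) {
  stopifnot(inherits(Q, "quantile_matrix"))
  M <- nrow(Q)
  k <- as.integer(k)
  if (k < 2L || k > M) stop("'k' must be between 2 and the number of subjects")
  is_surv <- survival::is.Surv(outcome)
  is_binary <- !is_surv && all(outcome %in% c(0, 1))
  strat <- if (is_surv) outcome[, 2L]
           else if (is_binary) as.numeric(outcome)
           else rep(0, M)
  folds <- integer(M)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  for (s in unique(strat)) {
    idx <- which(strat == s)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  out <- numeric(M); names(out) <- rownames(Q)
  for (f in seq_len(k)) {
    tr <- folds != f
    out_tr <- if (is_surv) outcome[tr, ] else outcome[tr]
    if (is_surv && sum(out_tr[, 2L]) < 1)
      stop("a training remainder has no events; use a smaller k")
    if (is_binary && length(unique(out_tr)) < 2L)
      stop("a training remainder has a single outcome class; use a smaller k")
    m <- qindex(Q[tr, , drop = FALSE], out_tr, ...)
    out[!tr] <- predict(m, Q[!tr, , drop = FALSE])
  }
  out
}
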