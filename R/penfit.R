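# Penalized likelihood fitters for functional design matrices.
#
# Exponential-family models (gaussian, binomial/logit) are fitted by
# penalized iteratively reweighted least squares with an unpenalized
# intercept; right-censored survival by penalized Cox partial likelihood
# (Breslow tie handling) with Newton iterations and step halving.
# Smoothing parameters are selected on a fixed grid by GCV (exponential
# family) or partial-likelihood AIC (Cox).

#' Default smoothing-parameter grid
#'
#' 30 log-spaced values between 1e-4 and 1e6.
#' @return numeric vector, increasing.
#' @export
default_lambda_grid <- function() 10^seq(-4, 6, length.out = 30)

new_penfit <- function(family, coefficients, intercept = NULL, lambda, edf,
                       loglik, deviance = NA_real_, criterion, converged,
                       message = "", vcov = NULL, iterations = NA_integer_,
                       crit_unit = 1) {
  structure(list(family = family, coefficients = coefficients,
                 intercept = intercept, lambda = lambda, edf = edf,
                 loglik = loglik, deviance = deviance, criterion = criterion,
                 converged = converged, message = message, vcov = vcov,
                 iterations = iterations, crit_unit = crit_unit),
            class = "penfit")
}

#' @export
print.penfit <- function(x, ...) {
  cat(sprintf("Penalized %s fit: %d coefficient(s), lambda = %.4g, edf = %.2f\n",
              x$family, length(x$coefficients), x$lambda, x$edf))
  cat(sprintf("  criterion = %.6g, converged = %s\n", x$criterion, x$converged))
  if (nzchar(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

#' Fit a penalized exponential-family model
#'
#' Maximizes \eqn{\ell(\theta) - (\lambda/2)\,\theta^\top S \theta} by
#' iteratively reweighted least squares. The intercept is unpenalized; the
#' penalty applies to the slope coefficients only. Effective degrees of
#' freedom are the trace of the influence matrix at convergence.
#'
#' @param X design matrix (without intercept column).
#' @param y response: numeric for \code{family = "gaussian"}, 0/1 for
#'   \code{"binomial"}.
#' @param penalty symmetric positive semi-definite penalty matrix of size
#'   \code{ncol(X)}.
#' @param lambda smoothing parameter, >= 0.
#' @param family \code{"gaussian"} or \code{"binomial"} (logit link).
#' @param intercept include an unpenalized intercept (default TRUE).
#' @param start optional starting coefficients (intercept first if present).
#' @param control list with \code{maxit} (default 100) and \code{reltol}
#'   (default 1e-8).
#' @param gamma inflation factor applied to the effective degrees of freedom
#'   in the selection criterion (GCV becomes
#'   \code{n dev / (n - gamma edf)^2}). Values around 1.4 guard grid
#'   selection against occasional undersmoothing; \code{gamma = 1} gives the
#'   plain criterion. Default 1.4.
#' @return object of class \code{"penfit"}: coefficients, intercept, edf,
#'   deviance, GCV criterion, convergence flag, and the Wald covariance of
#'   the estimates.
#' @export
fit_penalized_glm <- function(X, y, penalty, lambda,
                              family = c("binomial", "gaussian"),
                              intercept = TRUE, start = NULL,
                              control = list(), gamma = 1.4) {
  family <- match.arg(family)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); K <- ncol(X)
  if (length(y) != n) stop("length of 'y' does not match rows of design")
  if (lambda < 0) stop("'lambda' must be >= 0")
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial response must be 0/1")
  maxit <- control$maxit %||% 100L
  reltol <- control$reltol %||% 1e-8
  Xf <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  p <- ncol(Xf)
  Sf <- matrix(0, p, p)
  idx <- if (intercept) seq_len(K) + 1L else seq_len(K)
  Sf[idx, idx] <- as.matrix(penalty)

  solve_ridge <- function(A, b) {
    out <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(out) && lambda > 0) {
      # tiny-data degeneracies (e.g. quasi-separation deflating the IRLS
      # weights) can leave the system numerically singular even though the
      # penalized problem is well-posed; stabilize with a negligible ridge
      eps <- 1e-8 * (sum(diag(A)) / nrow(A) + 1)
      out <- tryCatch(solve(A + eps * diag(nrow(A)), b),
                      error = function(e) NULL)
    }
    if (is.null(out))
      stop("singular penalized system; increase lambda above 0")
    out
  }

  if (family == "gaussian") {
    A <- crossprod(Xf)
    beta <- solve_ridge(A + lambda * Sf, crossprod(Xf, y))
    mu <- drop(Xf %*% beta)
    dev <- sum((y - mu)^2)
    edf <- sum(diag(solve_ridge(A + lambda * Sf, A)))
    sigma2 <- dev / max(n - edf, 1)
    Ainv <- solve_ridge(A + lambda * Sf, diag(p))
    vcov <- sigma2 * Ainv %*% A %*% Ainv
    ll <- -n / 2 * (log(2 * pi * dev / n) + 1)
    gcv <- n * dev / (max(n - gamma * edf, 1))^2
    conv <- TRUE; msg <- ""; iters <- 1L
  } else {
    beta <- if (!is.null(start)) as.numeric(start) else rep(0, p)
    if (is.null(start) && intercept) {
      pb <- mean(y); pb <- min(max(pb, 1e-3), 1 - 1e-3)
      beta[1L] <- log(pb / (1 - pb))
    }
    dev_old <- Inf; conv <- FALSE; msg <- ""; iters <- 0L
    for (it in seq_len(maxit)) {
      iters <- it
      eta <- drop(Xf %*% beta)
      mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
      w <- mu * (1 - mu)
      z <- eta + (y - mu) / w
      A <- crossprod(Xf * sqrt(w))
      beta <- drop(solve_ridge(A + lambda * Sf, crossprod(Xf, w * z)))
      eta <- drop(Xf %*% beta)
      mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
      dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
      if (is.finite(dev_old) &&
          abs(dev - dev_old) < reltol * (abs(dev) + reltol)) {
        conv <- TRUE
        break
      }
      dev_old <- dev
    }
    eta <- drop(Xf %*% beta)
    mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    A <- crossprod(Xf * sqrt(w))
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    edf <- sum(diag(solve_ridge(A + lambda * Sf, A)))
    Ainv <- solve_ridge(A + lambda * Sf, diag(p))
    vcov <- Ainv %*% A %*% Ainv
    ll <- -dev / 2
    gcv <- n * dev / (max(n - gamma * edf, 1))^2
    if (max(abs(beta)) > 100 && lambda == 0) {
      conv <- FALSE
      msg <- "possible perfect separation: coefficients diverging"
    } else if (!conv) {
      msg <- "IRLS did not converge within iteration cap"
    }
  }
  co <- drop(beta)
  names(co) <- colnames(Xf)
  new_penfit(family = family,
             coefficients = if (intercept) co[-1L] else co,
             intercept = if (intercept) unname(co[1L]) else NULL,
             lambda = lambda, edf = edf, loglik = ll, deviance = dev,
             criterion = gcv, converged = conv, message = msg,
             vcov = vcov, iterations = iters,
             # GCV change corresponding to one deviance unit: used to put
             # the parsimony band of the grid selectors on the GCV scale
             crit_unit = n / (max(n - gamma * edf, 1))^2)
}

#' Fit a penalized Cox proportional-hazards model
#'
#' Maximizes the penalized Cox partial log-likelihood (Breslow handling of
#' tied event times) by Newton iterations with step halving. There is no
#' intercept: it is absorbed into the baseline hazard. Effective degrees of
#' freedom are \code{trace((H + lambda S)^{-1} H)} with \code{H} the negative
#' Hessian of the partial log-likelihood at the optimum.
#'
#' @param X design matrix.
#' @param time positive event/censoring times.
#' @param status event indicators (1 = event, 0 = censored); at least one
#'   event is required.
#' @param penalty symmetric penalty matrix of size \code{ncol(X)}.
#' @param lambda smoothing parameter >= 0.
#' @param start optional starting coefficients.
#' @param control list with \code{maxit}, \code{reltol}, \code{max_halvings}.
#' @param gamma inflation factor on the effective degrees of freedom in the
#'   selection criterion (see \code{\link{fit_penalized_glm}}); default 1.4.
#' @return object of class \code{"penfit"} with the partial-likelihood AIC
#'   (\code{-2 loglik + 2 gamma edf}) as the selection criterion.
#' @export
fit_penalized_cox <- function(X, time, status, penalty, lambda,
                              start = NULL, control = list(), gamma = 1.4) {
  X <- as.matrix(X)
  n <- nrow(X); K <- ncol(X)
  time <- as.numeric(time); status <- as.numeric(status)
  if (length(time) != n || length(status) != n)
    stop("outcome length does not match rows of design")
  if (any(time <= 0)) stop("times must be positive")
  if (sum(status) < 1) stop("no events: cannot fit a Cox model")
  if (lambda < 0) stop("'lambda' must be >= 0")
  maxit <- control$maxit %||% 100L
  reltol <- control$reltol %||% 1e-8
  max_halvings <- control$max_halvings %||% 20L

  ord <- order(time)
  X <- X[ord, , drop = FALSE]; time <- time[ord]; status <- status[ord]
  S <- as.matrix(penalty)

  # unique event times, their risk-set entry point, event multiplicity and
  # per-time sums of covariates over events
  ev <- which(status == 1)
  ut <- unique(time[ev])
  first_idx <- match(ut, time)              # risk set = rows first_idx..n
  d <- vapply(ut, function(t) sum(time[ev] == t), numeric(1))
  Xev_sum <- rowsum(X[ev, , drop = FALSE], group = time[ev])
  Xev_sum <- Xev_sum[match(as.character(ut), rownames(Xev_sum)), , drop = FALSE]
  sum_eta_events <- function(eta) sum(eta[ev])

  revcumsum <- function(v) rev(cumsum(rev(v)))
  E <- length(ut)

  # Risk-set sums via suffix accumulation from the latest event time down:
  # S0, S1, S2 are running sums of w, w*x, w*x*x' over {j: t_j >= t_e}.
  pll_parts <- function(beta, need_deriv = TRUE) {
    eta <- drop(X %*% beta)
    eta_c <- eta - max(eta)           # partial likelihood is shift-invariant
    w <- exp(eta_c)
    if (!need_deriv) {
      S0 <- revcumsum(w)[first_idx]
      return(list(ll = sum_eta_events(eta_c) - sum(d * log(S0))))
    }
    S0 <- 0; S1 <- numeric(K); S2 <- matrix(0, K, K)
    U <- matrix(0, E, K); s0 <- numeric(E)
    H1 <- matrix(0, K, K)
    hi <- n
    for (e in E:1) {
      lo <- first_idx[e]
      idx <- lo:hi
      wb <- w[idx]
      Xb <- X[idx, , drop = FALSE]
      S0 <- S0 + sum(wb)
      S1 <- S1 + drop(crossprod(Xb, wb))
      S2 <- S2 + crossprod(Xb * sqrt(wb))
      s0[e] <- S0
      U[e, ] <- S1 / S0
      H1 <- H1 + (d[e] / S0) * S2
      hi <- lo - 1L
    }
    ll_val <- sum_eta_events(eta_c) - sum(d * log(s0))
    g <- colSums(Xev_sum) - colSums(d * U)
    H <- H1 - crossprod(sqrt(d) * U)
    list(ll = ll_val, g = g, H = H)
  }

  solve_ridge <- function(A, b) {
    out <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(out) && lambda > 0) {
      eps <- 1e-8 * (sum(diag(A)) / nrow(A) + 1)
      out <- tryCatch(solve(A + eps * diag(nrow(A)), b),
                      error = function(e) NULL)
    }
    if (is.null(out))
      stop("singular penalized system; increase lambda above 0")
    out
  }

  beta <- if (!is.null(start)) as.numeric(start) else rep(0, K)
  pen_obj <- function(b, llv) llv - lambda / 2 * drop(crossprod(b, S %*% b))
  parts <- pll_parts(beta)
  obj <- pen_obj(beta, parts$ll)
  conv <- FALSE; msg <- ""; iters <- 0L
  for (it in seq_len(maxit)) {
    iters <- it
    g_pen <- parts$g - lambda * drop(S %*% beta)
    A <- parts$H + lambda * S
    step <- solve_ridge(A, g_pen)
    alpha <- 1
    for (h in seq_len(max_halvings + 1L)) {
      beta_try <- beta + alpha * step
      ll_try <- pll_parts(beta_try, need_deriv = FALSE)$ll
      obj_try <- pen_obj(beta_try, ll_try)
      if (is.finite(obj_try) && obj_try >= obj - 1e-12) break
      alpha <- alpha / 2
    }
    beta_new <- beta + alpha * step
    parts_new <- pll_parts(beta_new)
    obj_new <- pen_obj(beta_new, parts_new$ll)
    done <- abs(obj_new - obj) < reltol * (abs(obj) + reltol)
    beta <- beta_new; parts <- parts_new; obj <- obj_new
    if (done) { conv <- TRUE; break }
  }
  if (max(abs(beta)) > 500) {
    conv <- FALSE
    msg <- "monotone partial likelihood: coefficient diverging"
  } else if (!conv) {
    msg <- "Newton iterations did not converge within iteration cap"
  }
  H <- parts$H
  A <- H + lambda * S
  Ainv <- solve_ridge(A, diag(K))
  edf <- sum(diag(Ainv %*% H))
  vcov <- Ainv %*% H %*% Ainv
  co <- drop(beta); names(co) <- colnames(X)
  new_penfit(family = "cox", coefficients = co, intercept = NULL,
             lambda = lambda, edf = edf, loglik = parts$ll,
             criterion = -2 * parts$ll + 2 * gamma * edf, converged = conv,
             message = msg, vcov = vcov, iterations = iters)
}

# Among converged fits, choose the smoothest (lowest-edf) candidate whose
# criterion lies within `band` units of the minimum; exact ties go to the
# later (larger-lambda) candidate. band units are -2*loglik units for the
# Cox AIC and deviance units for GCV (translated via crit_unit).
pick_parsimonious <- function(fits, band) {
  ok <- vapply(fits, function(f) isTRUE(f$converged) &&
                 is.finite(f$criterion), logical(1))
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  crit <- vapply(fits[idx], `[[`, numeric(1), "criterion")
  i_min <- idx[which.min(crit)]
  tol <- band * fits[[i_min]]$crit_unit
  cand <- idx[crit <= min(crit) + tol]
  edf <- vapply(fits[cand], `[[`, numeric(1), "edf")
  # lowest edf; among near-equal edf take the last (smoothest ordering)
  winners <- cand[edf <= min(edf) + 1e-6]
  fits[[winners[length(winners)]]]
}

#' Select the smoothing parameter on a grid
#'
#' Evaluates a fitter over a grid of smoothing parameters with warm starts
#' (GCV criterion for exponential-family fits, partial-likelihood AIC for
#' Cox). The criterion is minimized over the grid; with a positive
#' \code{band}, the smoothest fit (lowest effective degrees of freedom)
#' within \code{band} criterion units of the minimum is preferred instead.
#' Remaining ties go to the larger lambda.
#'
#' @param fitter function of \code{(lambda, start)} returning a
#'   \code{"penfit"}.
#' @param lambda_grid positive candidate values (default
#'   \code{\link{default_lambda_grid}}).
#' @param band parsimony margin in criterion units (deviance scale);
#'   \code{band = 0} reproduces strict minimization.
#' @return list with \code{lambda}, \code{fit}, and a \code{trace} data frame
#'   of (lambda, criterion, edf, converged).
#' @export
select_lambda <- function(fitter, lambda_grid = default_lambda_grid(),
                          band = 0) {
  lambda_grid <- sort(as.numeric(lambda_grid))
  if (length(lambda_grid) == 0L) stop("empty lambda grid")
  fits <- vector("list", length(lambda_grid))
  trace <- vector("list", length(lambda_grid))
  start <- NULL
  for (k in seq_along(lambda_grid)) {
    lam <- lambda_grid[k]
    fit <- tryCatch(fitter(lam, start), error = function(e) NULL)
    if (is.null(fit)) {
      trace[[k]] <- data.frame(lambda = lam, criterion = NA_real_,
                               edf = NA_real_, converged = FALSE)
      next
    }
    start <- c(fit$intercept, fit$coefficients)
    fits[[k]] <- fit
    trace[[k]] <- data.frame(lambda = lam, criterion = fit$criterion,
                             edf = fit$edf, converged = fit$converged)
  }
  best <- pick_parsimonious(fits[!vapply(fits, is.null, logical(1))], band)
  if (is.null(best))
    stop("no candidate smoothing parameter produced a converged fit")
  list(lambda = best$lambda, fit = best, trace = do.call(rbind, trace))
}

#' Select anisotropic smoothing parameters on a 2-D grid
#'
#' For tensor-product terms the two margins carry separate smoothing
#' parameters (e.g. the fitted surface may be nearly linear along the
#' quantile-value axis while staying flexible along the probability axis).
#' All pairs on the grid are fitted with warm starts and the criterion is
#' minimized; with a positive \code{band} the smoothest fit (lowest
#' effective degrees of freedom) within \code{band} criterion units of the
#' minimum wins instead. Remaining ties go to the later (larger-lambda)
#' pair.
#'
#' @param fitter2 function of \code{(lambda_p, lambda_q, start)} returning a
#'   \code{"penfit"}.
#' @param grid_p,grid_q positive candidate values for the two margins.
#' @param band parsimony margin in criterion units (see
#'   \code{\link{select_lambda}}).
#' @return list with \code{lambda} (named length-2 vector), \code{fit}, and
#'   a \code{trace} data frame.
#' @export
select_lambda_2d <- function(fitter2, grid_p, grid_q = grid_p, band = 0) {
  grid_p <- sort(as.numeric(grid_p)); grid_q <- sort(as.numeric(grid_q))
  if (length(grid_p) == 0L || length(grid_q) == 0L) stop("empty lambda grid")
  fits <- list(); lambdas <- list()
  trace <- vector("list", length(grid_p) * length(grid_q))
  k <- 0L; start <- NULL
  for (lq in grid_q) for (lp in grid_p) {
    k <- k + 1L
    fit <- tryCatch(fitter2(lp, lq, start), error = function(e) NULL)
    if (is.null(fit)) {
      trace[[k]] <- data.frame(lambda_p = lp, lambda_q = lq,
                               criterion = NA_real_, edf = NA_real_,
                               converged = FALSE)
      next
    }
    start <- c(fit$intercept, fit$coefficients)
    fit$lambda2 <- c(p = lp, q = lq)
    fits[[length(fits) + 1L]] <- fit
    trace[[k]] <- data.frame(lambda_p = lp, lambda_q = lq,
                             criterion = fit$criterion, edf = fit$edf,
                             converged = fit$converged)
  }
  best <- pick_parsimonious(fits, band)
  if (is.null(best))
    stop("no candidate smoothing parameter produced a converged fit")
  list(lambda = best$lambda2, fit = best, trace = do.call(rbind, trace))
}

#' Unpenalized association models with Wald intervals
#'
#' Convenience wrapper around \code{stats::glm} and \code{survival::coxph}
#' for one to a few scalar covariates: returns estimates, Wald 95\%
#' confidence intervals and p-values, with effects exponentiated to odds or
#' hazard ratios where applicable.
#'
#' @param X numeric matrix or data frame of covariates.
#' @param outcome numeric response, 0/1 vector, or a \code{survival::Surv}
#'   object.
#' @param family \code{"gaussian"}, \code{"binomial"}, or \code{"cox"};
#'   inferred from the outcome when \code{NULL}.
#' @return list with the underlying fit (\code{fit}) and a coefficient table
#'   (\code{table}) with columns estimate, se, z, p, ratio (exp of estimate
#'   for binomial/cox), lower, upper.
#' @export
fit_unpenalized <- function(X, outcome, family = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  df <- as.data.frame(X)
  if (is.null(family)) {
    family <- if (survival::is.Surv(outcome)) "cox"
      else if (all(outcome %in% c(0, 1))) "binomial" else "gaussian"
  }
  if (family == "cox") {
    if (!survival::is.Surv(outcome)) stop("cox family requires a Surv outcome")
    df$.y <- outcome
    fit <- survival::coxph(.y ~ ., data = df, ties = "breslow")
    sm <- summary(fit)$coefficients
    est <- sm[, "coef"]; se <- sm[, "se(coef)"]
    names(est) <- rownames(sm)
  } else {
    df$.y <- as.numeric(outcome)
    fit <- stats::glm(.y ~ ., data = df,
                      family = if (family == "binomial") stats::binomial()
                               else stats::gaussian())
    sm <- summary(fit)$coefficients
    est <- sm[, 1L]; se <- sm[, 2L]
    names(est) <- rownames(sm)
  }
  # a zero-variance covariate has an arbitrary coefficient; report a null
  # effect rather than NA so downstream tables stay well-defined
  se[is.na(est) | is.na(se)] <- Inf
  est[is.na(est)] <- 0
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(term = names(est), estimate = est, se = se, z = z, p = p,
                    ratio = if (family == "gaussian") NA_real_ else exp(est),
                    lower = if (family == "gaussian") est - 1.96 * se
                            else exp(est - 1.96 * se),
                    upper = if (family == "gaussian") est + 1.96 * se
                            else exp(est + 1.96 * se),
                    row.names = NULL)
  list(fit = fit, family = family, table = tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
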