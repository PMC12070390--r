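# naive Breslow partial log-likelihood, independent of the package's
# cumulative-sum implementation (O(n^2) double loop)
naive_cox_loglik <- function(beta, X, time, status) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

test_that("gaussian fit at lambda 0 is ordinary least squares", {
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2)
  y <- 1 + X %*% c(2, -1) + rnorm(20, sd = 0.3)
  S <- difference_penalty(2, 1)
  f <- fit_penalized_glm(X, y, S, lambda = 0, family = "gaussian")
  ols <- qr.solve(cbind(1, X), y)
  expect_equal(unname(c(f$intercept, f$coefficients)), drop(ols),
               tolerance = 1e-10)
  expect_equal(f$edf, 3, tolerance = 1e-8)
})

test_that("intercept-only logistic recovers the logit of the event rate", {
  y <- c(rep(1, 5), rep(0, 15))           # mean 0.25
  X <- matrix(0, 20, 1)
  f <- fit_penalized_glm(X, y, matrix(1, 1, 1), lambda = 1e8,
                         family = "binomial")
  expect_equal(f$intercept, log(1 / 3), tolerance = 1e-4)
})

test_that("extreme smoothing drives penalized coefficients to zero", {
  set.seed(2)
  X <- matrix(rnorm(60), 30, 2)
  y <- rbinom(30, 1, plogis(X %*% c(1, 1)))
  S <- diag(2)                            # full-rank penalty on slopes
  f <- fit_penalized_glm(X, y, S, lambda = 1e12, family = "binomial")
  expect_lt(max(abs(f$coefficients)), 1e-6)
  expect_equal(f$edf, 1, tolerance = 1e-3)   # intercept only
  tm <- rexp(30) + 0.1
  fc <- fit_penalized_cox(X, tm, rbinom(30, 1, 0.7), S, lambda = 1e12)
  expect_lt(max(abs(fc$coefficients)), 1e-6)
})

test_that("lambda-0 fits match glm and coxph on random small instances", {
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(25:60, 1); k <- sample(1:3, 1)
    X <- matrix(rnorm(n * k), n, k)
    S <- diag(k)
    y <- rbinom(n, 1, plogis(drop(X %*% rnorm(k, sd = 0.7))))
    if (length(unique(y)) < 2) next
    f <- fit_penalized_glm(X, y, S, 0, family = "binomial")
    g <- suppressWarnings(stats::glm(y ~ X, family = stats::binomial()))
    expect_equal(unname(c(f$intercept, f$coefficients)),
                 unname(stats::coef(g)), tolerance = 1e-6)

    tm <- rexp(n, exp(drop(X %*% rep(0.3, k)))) + 1e-3
    st <- rbinom(n, 1, 0.7)
    if (sum(st) < 2) next
    fc <- fit_penalized_cox(X, tm, st, S, 0)
    cp <- survival::coxph(survival::Surv(tm, st) ~ X, ties = "breslow")
    expect_equal(unname(fc$coefficients), unname(stats::coef(cp)),
                 tolerance = 1e-6)
    expect_equal(fc$loglik, cp$loglik[2], tolerance = 1e-6)
  }
})

test_that("penalized optima agree with direct numerical optimization", {
  set.seed(44)
  n <- 40; k <- 4
  X <- matrix(rnorm(n * k), n, k)
  S <- unclass(difference_penalty(k, 2))
  y <- rbinom(n, 1, plogis(drop(X %*% c(1, 0.5, -0.5, 0))))
  lam <- 3
  f <- fit_penalized_glm(X, y, S, lam, family = "binomial")
  obj <- function(b) {
    eta <- b[1] + drop(X %*% b[-1])
    -sum(y * eta - log1p(exp(eta))) + lam / 2 * drop(b[-1] %*% S %*% b[-1])
  }
  o <- optim(rep(0, k + 1), obj, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-14))
  expect_equal(unname(c(f$intercept, f$coefficients)), o$par,
               tolerance = 1e-5)

  tm <- rexp(n) + 0.01; st <- rbinom(n, 1, 0.6)
  fc <- fit_penalized_cox(X, tm, st, S, lam)
  objc <- function(b) -naive_cox_loglik(b, X, tm, st) +
    lam / 2 * drop(b %*% S %*% b)
  oc <- optim(rep(0, k), objc, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-14))
  expect_equal(unname(fc$coefficients), oc$par, tolerance = 1e-5)
})

test_that("three-subject Cox example has the closed-form solution", {
  # events at t = 1, 2, 3 with covariate (1, 0, 1): the partial likelihood
  # maximum is at beta = -log(2)/2
  f <- fit_penalized_cox(matrix(c(1, 0, 1), 3, 1), time = 1:3,
                         status = c(1, 1, 1), penalty = matrix(0, 1, 1),
                         lambda = 0)
  expect_equal(unname(f$coefficients), -0.5 * log(2), tolerance = 1e-6)
  # cross-check by brute-force 1-D search on the naive likelihood
  bf <- optimize(function(b) naive_cox_loglik(b, matrix(c(1, 0, 1), 3, 1),
                                              1:3, rep(1, 3)),
                 c(-3, 3), maximum = TRUE)
  expect_equal(unname(f$coefficients), bf$maximum, tolerance = 1e-4)
})

test_that("a null covariate gets coefficient zero and leaves the likelihood flat", {
  set.seed(5)
  X <- matrix(0, 25, 1)
  tm <- rexp(25); st <- rbinom(25, 1, 0.7)
  f <- fit_penalized_cox(X, tm, st, matrix(1, 1, 1), 0.5)
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-10)
  f0 <- fit_penalized_cox(matrix(rnorm(25), 25, 1) * 0, tm, st,
                          matrix(1, 1, 1), 0.5)
  expect_equal(f$loglik, f0$loglik)
})

test_that("the penalty quadratic form shrinks monotonically in lambda", {
  set.seed(6)
  n <- 50; k <- 6
  X <- matrix(rnorm(n * k), n, k)
  S <- unclass(difference_penalty(k, 2))
  y <- rbinom(n, 1, plogis(drop(X %*% rnorm(k))))
  tm <- rexp(n) + 0.05; st <- rbinom(n, 1, 0.7)
  lams <- 10^seq(-2, 4, length.out = 7)
  pen_glm <- pen_cox <- numeric(length(lams))
  for (i in seq_along(lams)) {
    fg <- fit_penalized_glm(X, y, S, lams[i], family = "binomial")
    fc <- fit_penalized_cox(X, tm, st, S, lams[i])
    pen_glm[i] <- drop(fg$coefficients %*% S %*% fg$coefficients)
    pen_cox[i] <- drop(fc$coefficients %*% S %*% fc$coefficients)
  }
  expect_true(all(diff(pen_glm) <= 1e-8))
  expect_true(all(diff(pen_cox) <= 1e-8))
})

test_that("Cox fits are invariant to monotone transformation of time", {
  set.seed(7)
  n <- 40
  X <- matrix(rnorm(n * 2), n, 2)
  tm <- rexp(n) + 0.01; st <- rbinom(n, 1, 0.6)
  S <- diag(2)
  f1 <- fit_penalized_cox(X, tm, st, S, 2)
  f2 <- fit_penalized_cox(X, tm^3, st, S, 2)          # strictly monotone
  f3 <- fit_penalized_cox(X, exp(tm), st, S, 2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-10)
})

test_that("the penalized score vanishes at reported optima", {
  set.seed(8)
  n <- 45; k <- 5
  X <- matrix(rnorm(n * k), n, k)
  S <- unclass(difference_penalty(k, 2))
  y <- rbinom(n, 1, plogis(drop(X %*% rnorm(k, sd = 0.5))))
  f <- fit_penalized_glm(X, y, S, 1.7, family = "binomial")
  b <- c(f$intercept, f$coefficients)
  mu <- plogis(drop(cbind(1, X) %*% b))
  grad <- drop(crossprod(cbind(1, X), y - mu)) - c(0, 1.7 * S %*% f$coefficients)
  expect_lt(max(abs(grad)) / (1 + max(abs(b))), 1e-6)

  tm <- rexp(n) + 0.01; st <- rbinom(n, 1, 0.7)
  fc <- fit_penalized_cox(X, tm, st, S, 1.7)
  eps <- 1e-6
  ngrad <- vapply(seq_len(k), function(j) {
    e <- rep(0, k); e[j] <- eps
    (naive_cox_loglik(fc$coefficients + e, X, tm, st) -
       naive_cox_loglik(fc$coefficients - e, X, tm, st)) / (2 * eps) -
      1.7 * drop(S[j, ] %*% fc$coefficients)
  }, numeric(1))
  expect_lt(max(abs(ngrad)) / (1 + max(abs(fc$coefficients))), 1e-4)
})

test_that("select_lambda honours its grid and tie-break contracts", {
  set.seed(9)
  X <- matrix(rnorm(80), 40, 2)
  y <- rbinom(40, 1, 0.5)
  S <- diag(2)
  fitter <- function(lam, start)
    fit_penalized_glm(X, y, S, lam, family = "binomial", start = start)
  one <- select_lambda(fitter, lambda_grid = 0.37)
  expect_equal(one$lambda, 0.37)
  # identical criteria at every lambda: the larger one must win
  flat_fitter <- function(lam, start) {
    f <- fitter(1, start); f$lambda <- lam; f$criterion <- 5; f
  }
  tied <- select_lambda(flat_fitter, lambda_grid = c(0.1, 10))
  expect_equal(tied$lambda, 10)
  expect_error(select_lambda(function(lam, start) stop("boom"),
                             lambda_grid = c(1, 2)),
               "no candidate")
})

test_that("pure-noise responses are smoothed at least as hard as strong signals", {
  set.seed(12)
  diffs <- replicate(50, {
    X <- matrix(rnorm(35 * 5), 35, 5)
    S <- unclass(difference_penalty(5, 2))
    fitter <- function(y) select_lambda(function(l, s)
      fit_penalized_glm(X, y, S, l, family = "gaussian", start = s),
      lambda_grid = 10^seq(-3, 5, length.out = 9))$lambda
    y_noise <- rnorm(35)
    y_signal <- drop(X %*% c(3, 2, 1, 2, 3)) + rnorm(35, sd = 0.3)
    log10(fitter(y_noise)) - log10(fitter(y_signal))
  })
  expect_gte(mean(diffs), 0)
})

test_that("fit_unpenalized reproduces closed-form association measures", {
  # 2x2 table (20,30;10,40): OR = (20*40)/(30*10)
  y <- c(rep(1, 20), rep(0, 30), rep(1, 10), rep(0, 40))
  x <- c(rep(1, 50), rep(0, 50))
  f <- fit_unpenalized(cbind(g = x), y, family = "binomial")
  expect_equal(f$table$ratio[f$table$term == "g"], (20 * 40) / (30 * 10),
               tolerance = 1e-6)
  # Cox with a null covariate: HR exactly 1
  set.seed(13)
  sv <- make_surv(30, seed = 13)
  fc <- fit_unpenalized(cbind(z = rep(0, 30) + 0), sv, family = "cox")
  expect_equal(fc$table$ratio, 1, tolerance = 1e-8)
  # exact linear relation
  xg <- rnorm(20)
  fg <- fit_unpenalized(cbind(x = xg), 2 * xg, family = "gaussian")
  expect_equal(fg$table$estimate[fg$table$term == "x"], 2, tolerance = 1e-10)
})
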