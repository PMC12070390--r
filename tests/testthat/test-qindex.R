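# hand-built linear model with beta(p) == 1 and no centering: by partition
# of unity, coefficients all 1 give the plain Riemann mean of the quantiles
constant_beta_model <- function(grid, n_basis = 8) {
  structure(list(
    kind = "linear", family = "binomial", grid = grid,
    basis_p = basis_spec(n_basis, 3, range(grid$p)), basis_q = NULL,
    q_domain = NULL, coefficients = rep(1, n_basis),
    intercept = 0, centers = rep(0, n_basis), sign = 1,
    lambda = 0, edf = NA_real_, criterion = NA_real_, converged = TRUE,
    fit_message = "", lambda_trace = NULL, n_train = 0, scale_tag = "log",
    call = NULL), class = "qindex")
}

test_that("an all-ones weight curve yields the Riemann mean of quantiles", {
  Q <- make_Q(M = 9, seed = 14)
  m <- constant_beta_model(attr(Q, "grid"))
  expect_equal(unname(predict(m, Q)), unname(rowMeans(unclass(Q))),
               tolerance = 1e-12)
})

test_that("zero coefficients give identically zero indices", {
  Q <- make_Q(M = 5, seed = 15)
  m <- constant_beta_model(attr(Q, "grid"))
  m$coefficients <- rep(0, 8)
  expect_equal(unname(predict(m, Q)), rep(0, 5))
})

test_that("a surface projecting q^2 matches direct quadrature", {
  Q <- make_Q(M = 6, seed = 16)
  set.seed(16)
  y <- rbinom(6, 1, 0.5); y[1:2] <- c(0, 1)
  fit <- suppressWarnings(qindex(Q, y, kind = "nonlinear", lambda = 1,
                                 sign_adjust = FALSE, n_basis_q = 8))
  # overwrite the coefficients with a least-squares projection of F(p,q)=q^2
  qdom <- fit$q_domain
  qq <- seq(qdom[1], qdom[2], length.out = 301)
  cq <- qr.solve(bspline_basis(qq, fit$basis_q), qq^2)
  fit$coefficients <- as.vector(outer(rep(1, fit$basis_p$n_basis), cq))
  fit$centers <- rep(0, length(fit$coefficients))
  got <- predict(fit, Q)
  want <- rowMeans(unclass(Q)^2)
  expect_equal(unname(got), unname(want), tolerance = 1e-3)
})

test_that("training contributions average to zero (identifiability)", {
  set.seed(18)
  Q <- make_Q(M = 30, seed = 18)
  y <- rbinom(30, 1, 0.5)
  for (kind in c("linear", "nonlinear")) {
    fit <- qindex(Q, y, kind = kind, lambda = 1)
    expect_lt(abs(mean(predict(fit, Q))), 1e-10)
  }
})

test_that("sign adjustment orients indices along the median and is an involution", {
  set.seed(19)
  Q <- make_Q(M = 40, seed = 19)
  med <- unclass(Q)[, which.min(abs(attr(Q, "grid")$p - 0.5))]
  y <- rbinom(40, 1, plogis(-scale(med)[, 1] * 2))   # outcome against median
  fit <- qindex(Q, y, kind = "linear")
  expect_gte(cor(predict(fit, Q), med, method = "spearman"), 0)

  # construct a negatively-oriented model by negating the coefficients
  neg <- fit; neg$coefficients <- -neg$coefficients; neg$sign <- 1
  expect_lt(cor(predict(neg, Q), med, method = "spearman"), 0)
  fixed <- sign_adjust(neg, Q)
  expect_equal(fixed$coefficients, fit$coefficients)
  expect_gte(cor(predict(fixed, Q), med, method = "spearman"), 0)
  # flipping twice is the identity
  twice <- sign_adjust(sign_adjust(fit, Q), Q)
  expect_equal(twice$coefficients, fit$coefficients)
  expect_equal(twice$sign, fit$sign)
})

test_that("sign adjustment holds across random simulated fits", {
  set.seed(20)
  for (rep in 1:10) {
    Q <- make_Q(M = 35, seed = 100 + rep)
    y <- rbinom(35, 1, 0.5)
    if (length(unique(y)) < 2) next
    fit <- qindex(Q, y, kind = sample(c("linear", "nonlinear"), 1),
                  lambda_grid = 10^seq(-2, 4, length.out = 7))
    med <- unclass(Q)[, which.min(abs(attr(Q, "grid")$p - 0.5))]
    rho <- cor(predict(fit, Q), med, method = "spearman")
    if (!is.na(rho)) expect_gte(rho, 0)
  }
})

test_that("indices are invariant to a constant shift of all quantile functions", {
  set.seed(22)
  Q <- make_Q(M = 30, seed = 22)
  y <- rbinom(30, 1, plogis(scale(rowMeans(unclass(Q)))[, 1]))
  for (kind in c("linear", "nonlinear")) {
    f0 <- qindex(Q, y, kind = kind, lambda = 5)
    Qs <- quantile_matrix(unclass(Q) + 3.7, attr(Q, "grid"))
    fs <- qindex(Qs, y, kind = kind, lambda = 5)
    expect_equal(unname(predict(fs, Qs)), unname(predict(f0, Q)),
                 tolerance = 1e-6)
  }
})

test_that("permuted outcomes give chance-level held-out discrimination", {
  set.seed(23)
  aucs <- replicate(50, {
    Q <- make_Q(M = 60, seed = sample.int(1e6, 1))
    y <- sample(rep(0:1, 30))                        # labels independent of Q
    tr <- 1:40; te <- 41:60
    fit <- qindex(Q[tr, , drop = FALSE], y[tr], kind = "linear",
                  lambda_grid = 10^seq(-2, 4, length.out = 7))
    auc_mann_whitney(predict(fit, Q[te, , drop = FALSE]), y[te])
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("a signal in the row means is recovered with a consistent sign", {
  set.seed(24)
  Q <- make_Q(M = 400, seed = 24)
  lp <- scale(rowMeans(unclass(Q)))[, 1] * 2
  y <- rbinom(400, 1, plogis(lp))
  fit <- qindex(Q, y, kind = "linear")
  beta <- index_surface(fit, seq(0.1, 0.9, length.out = 30))
  # weight curve dominated by one sign (positive after orientation)
  expect_gt(mean(beta > 0), 0.85)
  expect_gt(cor(predict(fit, Q), rowMeans(unclass(Q))), 0.8)
})

test_that("degenerate and misaligned inputs are rejected", {
  g <- probability_grid(9)
  Qc <- quantile_matrix(matrix(1.5, 25, 9), g)
  expect_error(qindex(Qc, rbinom(25, 1, 0.5)), "degenerate")
  Q <- make_Q(M = 25, grid = g, seed = 26)
  expect_error(qindex(Q, rbinom(10, 1, 0.5), kind = "linear"),
               "does not match")
  fit <- qindex(Q, rbinom(25, 1, 0.5), kind = "linear", lambda = 1)
  Qother <- make_Q(M = 5, grid = probability_grid(19), seed = 27)
  expect_error(predict(fit, Qother), "grid")
})

test_that("standardization uses median and IQR with type-7 quartiles", {
  v <- c(1, 2, 3, 4, 5)
  s <- standardize_index(v)
  expect_equal(as.numeric(s), c(-1, -0.5, 0, 0.5, 1))
  # symmetric input has standardized median zero
  set.seed(28)
  x <- c(-rev(rexp(20)), rexp(20))
  expect_equal(median(as.numeric(standardize_index(x))), 0)
  # affine invariance for positive scalings
  y <- rnorm(30)
  expect_equal(as.numeric(standardize_index(3 * y + 7)),
               as.numeric(standardize_index(y)), tolerance = 1e-12)
  expect_error(standardize_index(rep(2, 10)), "degenerate")
  # frozen training constants are honoured
  s2 <- standardize_index(y, constants = list(center = 0, scale = 2))
  expect_equal(as.numeric(s2), y / 2)
})

test_that("cross-fitting is deterministic and never trains on the scored fold", {
  set.seed(29)
  Q <- make_Q(M = 6, seed = 29)
  y <- c(0, 1, 0, 1, 0, 1)
  v1 <- suppressWarnings(
    qindex_crossfit(Q, y, k = 6, seed = 4, kind = "linear", lambda = 2))
  v2 <- suppressWarnings(
    qindex_crossfit(Q, y, k = 6, seed = 4, kind = "linear", lambda = 2))
  expect_identical(v1, v2)
  expect_equal(names(v1), rownames(Q))
  expect_true(all(is.finite(v1)))
  expect_error(qindex_crossfit(Q, y, k = 1), "between 2")
})

test_that("cross-fitted discrimination tracks split-sample discrimination", {
  set.seed(30)
  gap <- replicate(12, {
    Q <- make_Q(M = 80, seed = sample.int(1e6, 1))
    lp <- scale(rowMeans(unclass(Q)))[, 1] * 2.5
    y <- rbinom(80, 1, plogis(lp))
    if (length(unique(y)) < 2) return(NA)
    cf <- qindex_crossfit(Q, y, k = 4, seed = 1, kind = "linear",
                          lambda_grid = 10^seq(-2, 4, length.out = 7))
    tr <- 1:40; te <- 41:80
    if (length(unique(y[tr])) < 2) return(NA)
    fit <- qindex(Q[tr, , drop = FALSE], y[tr], kind = "linear",
                  lambda_grid = 10^seq(-2, 4, length.out = 7))
    auc_mann_whitney(cf[te], y[te]) -
      auc_mann_whitney(predict(fit, Q[te, , drop = FALSE]), y[te])
  })
  expect_lt(abs(mean(gap, na.rm = TRUE)), 0.1)
})

test_that("models survive a serialization round trip bit-exactly", {
  set.seed(31)
  Q <- make_Q(M = 30, seed = 31)
  y <- rbinom(30, 1, 0.5)
  for (kind in c("linear", "nonlinear")) {
    fit <- qindex(Q, y, kind = kind, lambda = 2)
    path <- tempfile(fileext = ".json")
    write_qindex(fit, path)
    back <- read_qindex(path)
    expect_identical(predict(back, Q), predict(fit, Q))
    unlink(path)
  }
  # corrupt files are rejected with a schema error
  bad <- tempfile(fileext = ".json")
  writeLines('{"schema": "something-else"}', bad)
  expect_error(read_qindex(bad), "schema")
  unlink(bad)
})

test_that("survival outcomes train through the penalized Cox path", {
  set.seed(32)
  Q <- make_Q(M = 60, seed = 32)
  risk <- scale(rowMeans(unclass(Q)))[, 1]
  t_lat <- rexp(60, rate = 0.3 * exp(risk))
  sv <- survival::Surv(pmin(t_lat, 4), as.integer(t_lat <= 4))
  fit <- qindex(Q, sv, kind = "nonlinear")
  expect_s3_class(fit, "qindex")
  expect_equal(fit$family, "cox")
  expect_true(fit$converged)
  expect_gt(cor(predict(fit, Q), risk), 0.5)
})
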