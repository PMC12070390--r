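# Shared fixtures: all synthetic, built in code at test time.

# cell table with lognormal intensities, optional subject-level shifts
make_cells <- function(M = 10, n = 50, seed = 1, shift_sd = 0.5) {
  set.seed(seed)
  shifts <- rnorm(M, 0, shift_sd)
  data.frame(
    subject_id = rep(sprintf("s%02d", seq_len(M)), each = n),
    csi = exp(rnorm(M * n, rep(shifts, each = n) + 2, 0.6)))
}

# random valid quantile matrix (rows sorted draws)
make_Q <- function(M = 12, grid = probability_grid(), seed = 1,
                   mean_sd = 0.7, noise_sd = 1) {
  set.seed(seed)
  vals <- t(vapply(seq_len(M), function(i) {
    x <- rnorm(200, rnorm(1, 0, mean_sd), noise_sd)
    empirical_quantile(x, grid$p)
  }, numeric(length(grid$p))))
  rownames(vals) <- sprintf("s%02d", seq_len(M))
  quantile_matrix(vals, grid)
}

# small random survival outcome
make_surv <- function(n, seed = 1, rate = 0.5, censor = 2) {
  set.seed(seed)
  t_lat <- rexp(n, rate)
  survival::Surv(pmin(t_lat, censor), as.integer(t_lat <= censor))
}

# brute-force quadrature of a tensor-product surface along quantile rows
quadrature_tensor_oracle <- function(Q, basis_p, basis_q, theta) {
  grid <- attr(Q, "grid")
  Np <- basis_p$n_basis; Nq <- basis_q$n_basis
  Theta <- matrix(theta, Np, Nq)
  vapply(seq_len(nrow(Q)), function(i) {
    acc <- 0
    for (k in seq_along(grid$p)) {
      bp <- bspline_basis(grid$p[k], basis_p)
      bq <- bspline_basis(unclass(Q)[i, k], basis_q)
      acc <- acc + grid$w[k] * drop(bp %*% Theta %*% t(bq))
    }
    acc
  }, numeric(1))
}
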