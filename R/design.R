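# Functional design matrices discretizing the scalar-on-function terms.
#
# Linear term:  int beta(p) Q_i(p) dp  with beta(p) = sum_j b_j B_j(p)
#   -> X[i, j] = sum_p w_p B_j(p) Q_i(p)
# Tensor term:  int F(p, Q_i(p)) dp with
#   F(p, q) = sum_{j,l} theta_{jl} B^p_j(p) B^q_l(q)
#   -> X[i, (j,l)] = sum_p w_p B^p_j(p) B^q_l(Q_i(p))
# Coefficients are vectorized with the p-index j running fastest, so the
# tensor penalty is I_Nq (x) S_p + S_q (x) I_Np.

#' Functional design matrix for the linear quantile-index term
#'
#' @param Q a \code{\link{quantile_matrix}} (subjects x grid).
#' @param basis_p a \code{\link{basis_spec}} on the probability domain.
#' @return list with \code{X} (subjects x n_basis matrix), \code{basis_p},
#'   \code{grid}, and \code{kind = "linear"}. \code{X \%*\% b} approximates
#'   the integral of \code{beta(p) * Q_i(p)} for \code{beta = sum b_j B_j}.
#' @export
linear_functional_design <- function(Q, basis_p) {
  stopifnot(inherits(Q, "quantile_matrix"), inherits(basis_p, "basis_spec"))
  grid <- attr(Q, "grid")
  B <- bspline_basis(grid$p, basis_p)
  X <- unclass(Q) %*% (grid$w * B)
  list(X = X, kind = "linear", basis_p = basis_p, basis_q = NULL, grid = grid)
}

#' Functional design matrix for the tensor-product surface term
#'
#' Discretizes the integral of a tensor-product P-spline surface evaluated
#' along each subject's quantile function. Quantile values outside
#' \code{basis_q$domain} are clamped to the boundary.
#'
#' @param Q a \code{\link{quantile_matrix}}.
#' @param basis_p basis on the probability domain.
#' @param basis_q basis on the quantile-value domain.
#' @return list with \code{X} (subjects x (Np*Nq)), the two basis specs,
#'   \code{grid}, and \code{kind = "tensor"}.
#' @export
tensor_functional_design <- function(Q, basis_p, basis_q) {
  stopifnot(inherits(Q, "quantile_matrix"),
            inherits(basis_p, "basis_spec"), inherits(basis_q, "basis_spec"))
  grid <- attr(Q, "grid")
  Bp <- bspline_basis(grid$p, basis_p)          # P x Np
  BpW <- grid$w * Bp
  M <- nrow(Q); Np <- basis_p$n_basis; Nq <- basis_q$n_basis
  X <- matrix(0, M, Np * Nq)
  Qm <- unclass(Q)
  for (i in seq_len(M)) {
    Bq <- bspline_basis(Qm[i, ], basis_q)       # P x Nq
    X[i, ] <- as.vector(crossprod(BpW, Bq))     # Np x Nq, j fastest
  }
  rownames(X) <- rownames(Q)
  list(X = X, kind = "tensor", basis_p = basis_p, basis_q = basis_q, grid = grid)
}

#' Tensor-product roughness penalty
#'
#' Marginal difference penalties expanded to the tensor coefficient space
#' (p-index running fastest): \code{I_Nq (x) S_p} penalizes roughness along
#' the probability axis and \code{S_q (x) I_Np} along the quantile-value
#' axis. \code{tensor_penalty} returns their sum (one shared smoothing
#' parameter); \code{tensor_penalty_parts} returns the two pieces so that
#' each margin can carry its own smoothing parameter.
#'
#' @param n_p,n_q marginal basis sizes.
#' @param order difference order for both margins.
#' @return symmetric positive semi-definite matrix of size \code{n_p*n_q}
#'   (for \code{tensor_penalty}), or a list with elements \code{p} and
#'   \code{q} (for \code{tensor_penalty_parts}).
#' @export
tensor_penalty <- function(n_p, n_q, order = 2L) {
  parts <- tensor_penalty_parts(n_p, n_q, order)
  parts$p + parts$q
}

#' @rdname tensor_penalty
#' @export
tensor_penalty_parts <- function(n_p, n_q, order = 2L) {
  Sp <- difference_penalty(n_p, order)
  Sq <- difference_penalty(n_q, order)
  list(p = kronecker(diag(n_q), unclass(Sp)),
       q = kronecker(unclass(Sq), diag(n_p)))
}

#' Center design columns (identifiability constraint)
#'
#' Subtracting training column means makes the training-set sum of the
#' functional contributions \code{X \%*\% theta} exactly zero for every
#' coefficient vector, the standard identifiability constraint for a
#' functional term alongside an intercept (or a Cox baseline hazard).
#'
#' @param X design matrix.
#' @param centers optional stored centers from a training call; when supplied
#'   they are subtracted instead of the matrix's own column means.
#' @return list with \code{X} (centered) and \code{centers}.
#' @export
center_columns <- function(X, centers = NULL) {
  if (is.null(centers)) {
    centers <- colMeans(X)
  } else if (length(centers) != ncol(X)) {
    stop("length of 'centers' does not match the number of columns")
  }
  list(X = sweep(X, 2L, centers, "-"), centers = as.numeric(centers))
}

# Orthonormal basis of the complement of the joint null space of the
# centered design and the penalty. Directions with (near-)zero singular
# value in rbind(X, S) contribute nothing to the fit but make the penalized
# system singular; they are dropped before fitting and the coefficient
# vector is mapped back afterwards.
constraint_complement <- function(X, S, tol = 1e-9) {
  sv <- svd(rbind(X, as.matrix(S)), nu = 0)
  keep <- sv$d > tol * max(sv$d)
  sv$v[, keep, drop = FALSE]
}

# q-domain used for the tensor basis: training range widened by 5% per side
q_domain_from <- function(Q, expand = 0.05) {
  r <- range(unclass(Q))
  w <- diff(r)
  if (w <= 0) stop("degenerate functional predictor: zero-width quantile range")
  r + c(-1, 1) * expand * w
}
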