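#' B-spline basis specification
#'
#' Uniform B-spline basis in the Eilers-Marx P-spline construction: equally
#' spaced knots extending \code{degree} intervals beyond each end of the
#' domain. On such knots the coefficient-difference penalty annihilates
#' exactly the polynomials below its order (a coefficient sequence linear in
#' the index is a function linear in \code{x}), so heavy smoothing shrinks a
#' fitted curve or surface margin to an exact polynomial.
#'
#' @param n_basis number of basis functions (>= degree + 1).
#' @param degree polynomial degree (default 3, cubic).
#' @param domain closed interval \code{c(lower, upper)} covering all
#'   evaluation points; points outside are clamped to the boundary.
#' @return object of class \code{"basis_spec"} with the full knot vector.
#' @export
basis_spec <- function(n_basis, degree = 3L, domain = c(0, 1)) {
  n_basis <- as.integer(n_basis); degree <- as.integer(degree)
  if (degree < 0L) stop("'degree' must be >= 0")
  if (n_basis < degree + 1L) stop("'n_basis' must be at least degree + 1")
  domain <- as.numeric(domain)
  if (length(domain) != 2L || !(domain[2L] > domain[1L]))
    stop("'domain' must be an interval of positive width")
  h <- (domain[2L] - domain[1L]) / (n_basis - degree)
  knots <- domain[1L] + h * ((1L - (degree + 1L)):(n_basis))
  structure(list(n_basis = n_basis, degree = degree, domain = domain,
                 knots = knots),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("B-spline basis: %d functions, degree %d, domain [%.4g, %.4g]\n",
              x$n_basis, x$degree, x$domain[1L], x$domain[2L]))
  invisible(x)
}

#' Evaluate a clamped B-spline basis
#'
#' @param x evaluation points; values outside the spec's domain are clamped
#'   to the boundary.
#' @param spec a \code{\link{basis_spec}}.
#' @return matrix with \code{length(x)} rows and \code{spec$n_basis} columns;
#'   entries are non-negative and every row sums to 1 (partition of unity).
#' @export
bspline_basis <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  ord <- spec$degree + 1L
  # clamp to the knot-derived support (the nominal domain boundary can fall
  # a rounding error outside it)
  lo <- spec$knots[ord]; hi <- spec$knots[spec$n_basis + 1L]
  x <- pmin(pmax(as.numeric(x), lo), hi)
  splines::splineDesign(spec$knots, x, ord = ord, outer.ok = FALSE)
}

#' Difference penalty matrix for P-splines
#'
#' Returns \eqn{D^\top D} where \eqn{D} is the order-th difference operator
#' on coefficient vectors: the discrete roughness penalty of Eilers-Marx
#' P-splines. Its null space is spanned by polynomial coefficient sequences
#' of degree < order.
#'
#' @param n_basis number of basis coefficients.
#' @param order difference order (default 2); must be < \code{n_basis}.
#' @return symmetric positive semi-definite matrix with attribute
#'   \code{"order"}.
#' @export
difference_penalty <- function(n_basis, order = 2L) {
  n_basis <- as.integer(n_basis); order <- as.integer(order)
  if (order < 1L) stop("'order' must be >= 1")
  if (order >= n_basis) stop("'order' must be smaller than 'n_basis'")
  D <- diff(diag(n_basis), differences = order)
  structure(crossprod(D), order = order)
}
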