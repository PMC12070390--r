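#' Probability grid for tabulating quantile functions
#'
#' Builds the common probability grid on which per-subject empirical quantile
#' functions are tabulated, together with the integration weights used to
#' approximate integrals over \eqn{p \in (0,1)} by a Riemann sum.
#'
#' The default is 19 equally spaced probabilities 0.05, 0.10, ..., 0.95; a
#' denser 99-point grid (0.01, ..., 0.99) is obtained with \code{n = 99}.
#' A moderate grid (19-25 points) is recommended: denser grids add
#' computational cost with little change in the resulting indices.
#'
#' @param n number of grid points; \code{n = 19} gives steps of 0.05 from
#'   0.05 to 0.95, \code{n = 99} gives steps of 0.01 from 0.01 to 0.99.
#'   For other \code{n} the grid is \code{n} equally spaced points strictly
#'   inside \code{(trim, 1 - trim)}.
#' @param probs optional explicit vector of strictly increasing probabilities
#'   in (0,1); overrides \code{n}.
#' @param trim symmetric tail fraction to exclude (e.g. \code{trim = 0.1}
#'   drops probabilities below 0.1 and above 0.9), making downstream indices
#'   more robust to outlying cells. Default 0 (no trimming beyond the grid
#'   itself).
#' @return An object of class \code{"probability_grid"}: a list with
#'   \code{p} (probabilities) and \code{w} (positive weights summing to 1).
#' @examples
#' g <- probability_grid()
#' length(g$p)   # 19
#' sum(g$w)      # 1
#' @export
probability_grid <- function(n = 19L, probs = NULL, trim = 0) {
  if (is.null(probs)) {
    if (!is.numeric(n) || length(n) != 1L || n < 2L)
      stop("'n' must be a single integer >= 2")
    n <- as.integer(n)
    if (trim < 0 || trim >= 0.5) stop("'trim' must be in [0, 0.5)")
    if (trim == 0 && n == 19L) {
      probs <- seq(0.05, 0.95, by = 0.05)
    } else if (trim == 0 && n == 99L) {
      probs <- seq(0.01, 0.99, by = 0.01)
    } else {
      lo <- max(trim, 0.005)
      probs <- seq(lo, 1 - lo, length.out = n)
    }
  } else {
    probs <- as.numeric(probs)
    if (trim > 0) probs <- probs[probs >= trim & probs <= 1 - trim]
  }
  if (length(probs) < 1L) stop("empty probability grid")
  if (any(probs <= 0) || any(probs >= 1)) stop("probabilities must be in (0, 1)")
  if (is.unsorted(probs, strictly = TRUE)) stop("probabilities must be strictly increasing")
  structure(list(p = probs, w = rep(1 / length(probs), length(probs))),
            class = "probability_grid")
}

#' @export
print.probability_grid <- function(x, ...) {
  cat(sprintf("Probability grid: %d points in [%.3g, %.3g], uniform weights\n",
              length(x$p), min(x$p), max(x$p)))
  invisible(x)
}

#' Empirical quantile (left-continuous generalized inverse)
#'
#' Returns the k-th order statistic with \eqn{k = \lceil n p \rceil}, the
#' classical type-1 empirical quantile. At a jump point \eqn{p = k/n} the
#' left-continuous convention (value = k-th order statistic) is used.
#'
#' @param x non-empty numeric sample.
#' @param p probabilities in (0, 1); may be a vector.
#' @return numeric vector of quantiles, one per element of \code{p}.
#' @examples
#' empirical_quantile(c(3, 1, 2, 4), 0.5)  # 2
#' @export
empirical_quantile <- function(x, p) {
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x)) stop("no observations (empty or NA sample)")
  if (any(p <= 0) || any(p >= 1)) stop("'p' must be strictly inside (0, 1)")
  xs <- sort(x)
  k <- pmin(pmax(ceiling(length(x) * p), 1L), length(x))
  xs[k]
}

#' Tabulate per-subject empirical quantile functions
#'
#' Converts a cell-level table of signal intensities into a subject-by-
#' probability matrix of empirical quantiles on a common grid. When a
#' \code{roi_id} column is present, quantile functions are first tabulated
#' per region of interest (ROI) and then aggregated pointwise across ROIs.
#'
#' @param cells a data frame with columns \code{subject_id}, \code{csi}
#'   (positive cellular signal intensity), and optionally \code{roi_id}.
#'   Extra columns (e.g. cell coordinates) are ignored.
#' @param grid a \code{\link{probability_grid}}.
#' @param log_transform if \code{TRUE} (default) quantiles are computed on
#'   \code{log(csi)}; intensities must then be strictly positive. Log scale
#'   is the default because raw intensity distributions are typically
#'   right-skewed.
#' @param roi_method pointwise aggregation across ROIs of one subject:
#'   one of \code{"mean"}, \code{"median"}, \code{"min"}, \code{"max"}.
#' @return An object of class \code{"quantile_matrix"}: a numeric matrix with
#'   one row per subject (rownames = subject ids), one column per grid
#'   probability, and attributes \code{grid} and \code{scale_tag}
#'   (\code{"log"} or \code{"raw"}).
#' @examples
#' cells <- data.frame(subject_id = rep(c("a", "b"), each = 50),
#'                     csi = exp(rnorm(100)))
#' Q <- tabulate_quantiles(cells, probability_grid())
#' dim(Q)  # 2 x 19
#' @export
tabulate_quantiles <- function(cells, grid = probability_grid(),
                               log_transform = TRUE,
                               roi_method = c("mean", "median", "min", "max")) {
  roi_method <- match.arg(roi_method)
  stopifnot(inherits(grid, "probability_grid"))
  cells <- as.data.frame(cells)
  if (!all(c("subject_id", "csi") %in% names(cells)))
    stop("'cells' must have columns 'subject_id' and 'csi'")
  if (anyNA(cells$subject_id)) stop("every record needs a subject_id")
  if (anyNA(cells$csi)) stop("missing csi values")
  if (log_transform && any(cells$csi <= 0)) {
    bad <- unique(cells$subject_id[cells$csi <= 0])
    stop("non-positive csi with log transform for subject(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  val <- if (log_transform) log(cells$csi) else cells$csi
  subj <- as.character(cells$subject_id)
  ids <- unique(subj)
  P <- length(grid$p)
  Q <- matrix(NA_real_, length(ids), P, dimnames = list(ids, grid_colnames(grid)))
  has_roi <- "roi_id" %in% names(cells) && length(unique(cells$roi_id)) > 1L
  for (i in seq_along(ids)) {
    sel <- subj == ids[i]
    if (has_roi) {
      rois <- split(val[sel], as.character(cells$roi_id[sel]))
      rows <- t(vapply(rois, empirical_quantile, numeric(P), p = grid$p))
      Q[i, ] <- aggregate_roi(rows, method = roi_method)
    } else {
      Q[i, ] <- empirical_quantile(val[sel], grid$p)
    }
  }
  quantile_matrix(Q, grid, scale_tag = if (log_transform) "log" else "raw")
}

grid_colnames <- function(grid) sprintf("p_%g", grid$p)

#' Construct / validate a quantile matrix
#'
#' @param values numeric matrix, one row per subject, one column per grid
#'   probability; each row must be non-decreasing.
#' @param grid the \code{\link{probability_grid}} of the columns.
#' @param scale_tag \code{"log"} or \code{"raw"}.
#' @return the validated matrix with class \code{"quantile_matrix"}.
#' @export
quantile_matrix <- function(values, grid, scale_tag = "log") {
  values <- as.matrix(values)
  stopifnot(inherits(grid, "probability_grid"))
  if (ncol(values) != length(grid$p))
    stop("column count does not match grid length")
  dec <- values[, -1L, drop = FALSE] - values[, -ncol(values), drop = FALSE]
  if (any(dec < -1e-8))
    stop("quantile-matrix rows must be non-decreasing")
  if (is.null(rownames(values)))
    rownames(values) <- as.character(seq_len(nrow(values)))
  colnames(values) <- grid_colnames(grid)
  structure(values, grid = grid, scale_tag = scale_tag,
            class = c("quantile_matrix", "matrix", "array"))
}

#' @export
print.quantile_matrix <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("Quantile matrix: %d subjects x %d probabilities (%s scale)\n",
              nrow(x), ncol(x), attr(x, "scale_tag")))
  cat(sprintf("  grid: %.3g ... %.3g\n", min(g$p), max(g$p)))
  invisible(x)
}

# subsetting keeps the grid metadata when columns are untouched
#' @export
`[.quantile_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out) && ncol(out) == ncol(unclass(x))) {
    attr(out, "grid") <- attr(x, "grid")
    attr(out, "scale_tag") <- attr(x, "scale_tag")
    class(out) <- class(x)
  }
  out
}

#' Aggregate ROI-level quantile functions to tissue level
#'
#' Pointwise aggregation of several quantile-function rows (tabulated on the
#' same grid) into a single tissue-level quantile function.
#'
#' @param rows numeric matrix: one row per ROI, one column per probability.
#' @param method \code{"mean"}, \code{"median"}, \code{"min"} or \code{"max"}.
#' @return numeric vector, one value per probability; non-decreasing whenever
#'   the input rows are.
#' @export
aggregate_roi <- function(rows, method = c("mean", "median", "min", "max")) {
  method <- match.arg(method)
  rows <- as.matrix(rows)
  if (nrow(rows) < 1L) stop("need at least one ROI")
  switch(method,
         mean = colMeans(rows),
         median = apply(rows, 2L, stats::median),
         min = apply(rows, 2L, min),
         max = apply(rows, 2L, max))
}

#' Read a cell-level intensity table
#'
#' Reads a headered delimited text file with columns \code{subject_id},
#' \code{csi} and optionally \code{roi_id}, \code{x}, \code{y}.
#'
#' @param path file path; comma- or tab-delimited (inferred from extension,
#'   \code{.tsv}/\code{.txt} taken as tab).
#' @return data frame of cells.
#' @export
read_cell_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  cells <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  for (col in c("subject_id", "csi")) {
    if (!col %in% names(cells))
      stop("cell table is missing required column '", col, "'")
  }
  if (!is.numeric(cells$csi)) stop("column 'csi' must be numeric")
  cells
}

#' Write / read a quantile matrix as CSV
#'
#' The first column holds subject ids; remaining columns are named
#' \code{p_<probability>}.
#'
#' @param Q a \code{\link{quantile_matrix}}.
#' @param path output path.
#' @rdname quantile_matrix_io
#' @export
write_quantile_matrix <- function(Q, path) {
  stopifnot(inherits(Q, "quantile_matrix"))
  df <- data.frame(subject_id = rownames(Q), unclass(Q),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param scale_tag scale label to attach when reading (\code{"log"}/\code{"raw"}).
#' @rdname quantile_matrix_io
#' @export
read_quantile_matrix <- function(path, scale_tag = "log") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "subject_id") stop("first column must be 'subject_id'")
  p <- as.numeric(sub("^p_", "", names(df)[-1L]))
  if (anyNA(p)) stop("quantile columns must be named 'p_<probability>'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df$subject_id)
  quantile_matrix(m, probability_grid(probs = p), scale_tag = scale_tag)
}
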