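#' Mean signal intensity (MSI)
#'
#' The conventional quantitative-pathology biomarker: the per-subject
#' arithmetic mean of cellular signal intensities, optionally on the log
#' scale (the default, matching the scale on which skewed intensity
#' distributions are usually analyzed).
#'
#' @param cells data frame with columns \code{subject_id} and \code{csi}.
#' @param log_scale average \code{log(csi)} instead of raw \code{csi}
#'   (default TRUE).
#' @return named numeric vector, one mean per subject.
#' @examples
#' msi(data.frame(subject_id = c(1, 1, 1), csi = c(2, 4, 6)), log_scale = FALSE)
#' @export
msi <- function(cells, log_scale = TRUE) {
  cells <- as.data.frame(cells)
  if (!all(c("subject_id", "csi") %in% names(cells)))
    stop("'cells' must have columns 'subject_id' and 'csi'")
  if (log_scale && any(cells$csi <= 0))
    stop("non-positive csi on the log scale")
  val <- if (log_scale) log(cells$csi) else cells$csi
  out <- tapply(val, as.character(cells$subject_id), mean)
  ids <- unique(as.character(cells$subject_id))
  out <- out[ids]                      # keep first-appearance order
  structure(as.numeric(out), names = ids)
}

#' Train the optimal-quantile (OQ) comparator
#'
#' For every probability on the grid, fits the univariable outcome model
#' (logistic or Cox, unpenalized) on the standardized quantile column
#' \eqn{Q(p)} and selects the probability with the largest absolute Wald z
#' statistic. Ties are broken toward the smaller probability. The selection
#' is frozen at training and then applied unchanged to test subjects.
#'
#' @param Q training \code{\link{quantile_matrix}} (>= 2 grid probabilities).
#' @param outcome 0/1 vector or \code{survival::Surv} aligned with \code{Q}.
#' @return object of class \code{"oq"} with \code{selected_p} and a
#'   \code{trace} data frame (p, z, p.value, converged).
#' @export
oq_train <- function(Q, outcome) {
  stopifnot(inherits(Q, "quantile_matrix"))
  grid <- attr(Q, "grid")
  if (length(grid$p) < 2L) stop("OQ selection needs at least 2 probabilities")
  family <- if (survival::is.Surv(outcome)) "cox" else "binomial"
  z <- rep(NA_real_, length(grid$p)); pv <- rep(NA_real_, length(grid$p))
  ok <- rep(FALSE, length(grid$p))
  for (j in seq_along(grid$p)) {
    x <- unclass(Q)[, j]
    if (stats::sd(x) == 0) next
    x <- (x - mean(x)) / stats::sd(x)
    ft <- tryCatch(suppressWarnings(fit_unpenalized(cbind(q = x), outcome,
                                                    family = family)),
                   error = function(e) NULL)
    if (is.null(ft)) next
    row <- ft$table[ft$table$term != "(Intercept)", ]
    if (!is.finite(row$z)) next
    z[j] <- row$z; pv[j] <- row$p; ok[j] <- TRUE
  }
  if (!any(ok)) stop("no quantile column produced a converged univariable fit")
  if (any(!ok)) warning(sum(!ok), " quantile column(s) skipped (non-converged)")
  best <- which(ok)[which.max(abs(z[ok]))]   # which.max takes first = smaller p
  structure(list(selected_p = grid$p[best], grid = grid, family = family,
                 trace = data.frame(p = grid$p, z = z, p.value = pv,
                                    converged = ok)),
            class = "oq")
}

#' @export
print.oq <- function(x, ...) {
  cat(sprintf("Optimal-quantile biomarker: selected p = %.3g (%s outcome)\n",
              x$selected_p, x$family))
  invisible(x)
}

#' Apply an optimal-quantile selection
#'
#' @param selection an \code{"oq"} object from \code{\link{oq_train}}.
#' @param Q a \code{\link{quantile_matrix}} on the same grid.
#' @return named numeric vector: each subject's quantile at the selected
#'   probability.
#' @export
oq_apply <- function(selection, Q) {
  stopifnot(inherits(selection, "oq"), inherits(Q, "quantile_matrix"))
  grid <- attr(Q, "grid")
  j <- match(selection$selected_p, grid$p)
  if (is.na(j)) stop("selected probability is not on the grid of 'Q'")
  out <- unclass(Q)[, j]
  names(out) <- rownames(Q)
  out
}

#' @export
predict.oq <- function(object, newdata, ...) oq_apply(object, newdata)
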