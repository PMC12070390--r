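# Versioned plain-text (JSON) serialization of fitted index models, so a
# model trained in one session can score subjects in another.

QINDEX_SCHEMA_VERSION <- "1.0"

#' Write / read a fitted quantile-index model
#'
#' Serializes a \code{\link{qindex}} model to a versioned structured text
#' (JSON) file holding the basis specifications, coefficients, centering
#' constants, orientation sign, smoothing parameter, and probability grid.
#' \code{read_qindex} restores a model that reproduces index values exactly.
#'
#' @param model a fitted \code{\link{qindex}} model.
#' @param path file path to write to / read from.
#' @return \code{write_qindex} returns \code{path} invisibly;
#'   \code{read_qindex} returns the restored \code{"qindex"} object.
#' @rdname qindex_io
#' @export
write_qindex <- function(model, path) {
  stopifnot(inherits(model, "qindex"))
  spec_of <- function(b) if (is.null(b)) NULL else
    list(n_basis = b$n_basis, degree = b$degree, domain = b$domain)
  obj <- list(
    schema = "qfindex/qindex-model",
    schema_version = QINDEX_SCHEMA_VERSION,
    kind = model$kind,
    family = model$family,
    grid_p = model$grid$p,
    grid_w = model$grid$w,
    basis_p = spec_of(model$basis_p),
    basis_q = spec_of(model$basis_q),
    q_domain = model$q_domain,
    coefficients = unname(model$coefficients),
    intercept = model$intercept,
    centers = model$centers,
    sign = model$sign,
    lambda = model$lambda,
    edf = model$edf,
    criterion = model$criterion,
    converged = model$converged,
    n_train = model$n_train,
    scale_tag = model$scale_tag
  )
  # I(17) significant digits keep the double -> text -> double trip exact
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname qindex_io
#' @export
read_qindex <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("not a readable model file: ",
                                           conditionMessage(e)))
  if (!identical(obj$schema, "qfindex/qindex-model"))
    stop("file is not a qfindex model (schema mismatch)")
  if (!identical(obj$schema_version, QINDEX_SCHEMA_VERSION))
    stop("unsupported model schema version: ", obj$schema_version)
  mk_spec <- function(s) if (is.null(s) || length(s) == 0L) NULL else
    basis_spec(s$n_basis, s$degree, s$domain)
  grid <- probability_grid(probs = obj$grid_p)
  structure(list(
    kind = obj$kind, family = obj$family, grid = grid,
    basis_p = mk_spec(obj$basis_p), basis_q = mk_spec(obj$basis_q),
    q_domain = obj$q_domain, coefficients = obj$coefficients,
    intercept = obj$intercept, centers = obj$centers, sign = obj$sign,
    lambda = obj$lambda, edf = obj$edf, criterion = obj$criterion,
    converged = isTRUE(obj$converged), fit_message = "",
    lambda_trace = NULL, n_train = obj$n_train, scale_tag = obj$scale_tag,
    call = NULL
  ), class = "qindex")
}

#' Write a biomarker vector as CSV
#'
#' @param x named numeric vector of per-subject biomarker values.
#' @param path output path.
#' @param name biomarker column label (default "index").
#' @export
write_biomarker <- function(x, path, name = "index") {
  df <- data.frame(subject_id = names(x) %||% seq_along(x),
                   value = as.numeric(x))
  names(df)[2L] <- name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
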