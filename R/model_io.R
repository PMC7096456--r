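.MODEL_FORMAT <- "mdwfuse-pls/1"

#' Save a fitted PLS calibration to versioned structured text
#'
#' The file is JSON with a format tag and every model component written at
#' full IEEE precision, so a loaded model reproduces predictions and score
#' projections bit-identically. The calibration score matrix is persisted
#' because Mahalanobis-distance weighting needs it at prediction time.
#'
#' @param model a [fit_pls()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pls_calibration"))
  obj <- list(format = .MODEL_FORMAT,
              scale = model$scaler$scale,
              column_means = model$scaler$column_means,
              column_sds = model$scaler$column_sds,
              y_center = model$y_center,
              x_weights = model$x_weights,
              x_loadings = model$x_loadings,
              y_loadings = model$y_loadings,
              coefficients = model$coefficients,
              n_lv = model$n_lv,
              cal_scores = model$cal_scores,
              rmsecv_curve = model$rmsecv_curve)
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              null = "null", matrix = "rowmajor"),
             path)
  invisible(path)
}

#' Load a PLS calibration saved by [save_model()]
#'
#' @param path path to the model file.
#' @return A `pls_calibration` object.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("cannot parse model file ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(obj$format) || !identical(obj$format, .MODEL_FORMAT))
    stop("unsupported model format tag '", obj$format %||% "<missing>",
         "' in ", path, " (expected '", .MODEL_FORMAT, "')")
  as_mat <- function(x, nc) {
    x <- as.matrix(x)
    if (ncol(x) != nc) x <- matrix(as.numeric(x), ncol = nc)
    x
  }
  n_lv <- as.integer(obj$n_lv)
  structure(list(scaler = structure(list(column_means = as.numeric(obj$column_means),
                                         column_sds = as.numeric(obj$column_sds),
                                         scale = isTRUE(obj$scale)),
                                    class = "scaler"),
                 y_center = as.numeric(obj$y_center),
                 x_weights = as_mat(obj$x_weights, n_lv),
                 x_loadings = as_mat(obj$x_loadings, n_lv),
                 y_loadings = as.numeric(obj$y_loadings),
                 coefficients = as.numeric(obj$coefficients),
                 n_lv = n_lv,
                 cal_scores = as_mat(obj$cal_scores, n_lv),
                 rmsecv_curve = if (is.null(obj$rmsecv_curve)) NULL
                                else as.numeric(obj$rmsecv_curve)),
            class = "pls_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subset a spectra table by sample id
#' @param x a [spectra_table()].
#' @param ids sample ids to keep, in the requested order.
#' @return A [spectra_table()] containing exactly `ids`.
#' @export
subset_spectra <- function(x, ids) {
  stopifnot(inherits(x, "spectra_table"))
  miss <- setdiff(ids, x$sample_ids)
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  idx <- match(ids, x$sample_ids)
  spectra_table(ids, x$wavenumbers, x$absorbance[idx, , drop = FALSE],
                x$sensor_name)
}

#' Subset reference values by sample id
#' @param x a [reference_values()].
#' @param ids sample ids to keep, in the requested order.
#' @return A [reference_values()] containing exactly `ids`.
#' @export
subset_reference <- function(x, ids) {
  stopifnot(inherits(x, "reference_values"))
  miss <- setdiff(ids, x$sample_ids)
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  idx <- match(ids, x$sample_ids)
  reference_values(ids, x$concentration[idx])
}
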