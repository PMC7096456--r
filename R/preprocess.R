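#' Fit an autoscaling transform
#'
#' Autoscaling standardizes every wavenumber column to zero mean and unit
#' variance so that all variables enter the PLS decomposition with equal
#' weight, regardless of absolute absorbance level.
#'
#' @param X numeric matrix (>= 2 rows).
#' @param scale if `FALSE`, only mean-centering is performed (all sds set
#'   to 1); column-variance checks are then skipped.
#' @return An object of class `scaler` with `column_means`, `column_sds`
#'   (sample standard deviation, denominator n-1) and the `scale` flag.
#' @details A column with zero variance makes autoscaling undefined, so it
#'   raises an error naming the column rather than being silently floored.
#' @export
autoscale_fit <- function(X, scale = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows to fit a scaler")
  m <- colMeans(X)
  if (scale) {
    s <- apply(X, 2, stats::sd)
    zero <- which(s <= 0 | !is.finite(s))
    if (length(zero))
      stop("zero-variance column(s): ", paste(zero, collapse = ", "),
           "; autoscaling is undefined for constant columns")
  } else {
    s <- rep(1, ncol(X))
  }
  structure(list(column_means = m, column_sds = s, scale = scale),
            class = "scaler")
}

#' Apply a fitted autoscaling transform
#'
#' Applies the stored calibration means and standard deviations unchanged
#' to new rows: `(x - mean) / sd` columnwise.
#'
#' @param scaler a fitted [autoscale_fit()] object.
#' @param X numeric matrix with the same column count as the scaler.
#' @return The standardized matrix.
#' @export
autoscale_apply <- function(scaler, X) {
  stopifnot(inherits(scaler, "scaler"))
  X <- as.matrix(X)
  if (ncol(X) != length(scaler$column_means))
    stop("X has ", ncol(X), " columns; scaler expects ",
         length(scaler$column_means))
  sweep(sweep(X, 2, scaler$column_means, "-"), 2, scaler$column_sds, "/")
}

#' Invert an autoscaling transform
#' @param scaler a fitted [autoscale_fit()] object.
#' @param X standardized matrix.
#' @return Matrix on the original scale.
#' @export
autoscale_invert <- function(scaler, X) {
  stopifnot(inherits(scaler, "scaler"))
  X <- as.matrix(X)
  if (ncol(X) != length(scaler$column_means))
    stop("X has ", ncol(X), " columns; scaler expects ",
         length(scaler$column_means))
  sweep(sweep(X, 2, scaler$column_sds, "*"), 2, scaler$column_means, "+")
}

#' Concentration-ordered calibration/validation split
#'
#' Sorts the samples by concentration from high to low (ties keep original
#' order) and assigns every k-th sample of the sorted list to the
#' validation set, with k = round(1 / validation_fraction) and the first
#' validation sample at sorted position floor(k/2) + 1. The systematic
#' pattern spreads the validation set evenly across the concentration
#' range while keeping both extremes in the calibration set, so
#' validation is interpolation, never extrapolation.
#'
#' @param y numeric concentration vector (named, or `ids` supplied).
#' @param validation_fraction fraction of samples to hold out, in (0, 0.5);
#'   the validation count is `round(n * validation_fraction)`.
#' @param ids optional character sample ids (defaults to `names(y)` or
#'   `"s1"..."sn"`).
#' @return An object of class `split_plan` with `calibration_ids` and
#'   `validation_ids` (disjoint, union = all ids).
#' @examples
#' plan <- rank_split(runif(78, 0.1, 4.98), 15 / 78)
#' lengths(plan)
#' @export
rank_split <- function(y, validation_fraction, ids = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(ids)) ids <- if (!is.null(names(y))) names(y) else paste0("s", seq_len(n))
  if (length(ids) != n) stop("ids and y differ in length")
  if (n < 5L) stop("need at least 5 samples to split")
  if (!(validation_fraction > 0 && validation_fraction < 0.5))
    stop("validation_fraction must be in (0, 0.5)")
  n_val <- round(n * validation_fraction)
  if (n_val < 1L) stop("validation_fraction too small: no validation samples")
  k <- max(2L, as.integer(round(1 / validation_fraction)))
  ord <- order(-y)                      # high to low; stable on ties
  pos <- as.integer(floor(k / 2)) + 1L + k * (seq_len(n_val) - 1L)
  if (pos[n_val] >= n)                  # keep the minimum in calibration
    pos <- pos[pos < n]
  val <- ids[ord[pos]]
  structure(list(calibration_ids = setdiff(ids, val), validation_ids = val),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d calibration / %d validation samples\n",
              length(x$calibration_ids), length(x$validation_ids)))
  invisible(x)
}
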