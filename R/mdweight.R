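#' Mahalanobis distances in PLS score space
#'
#' Distance of each query score vector from the calibration score cloud:
#' `D(s) = sqrt((s - s_bar)' C^-1 (s - s_bar))` with `s_bar` and `C` the
#' mean and (n-1)-denominator covariance of the calibration scores.
#' Working in score space rather than raw wavenumber space keeps the
#' covariance well-conditioned and collinearity-free.
#'
#' @param S_cal calibration score matrix (n_cal x n_lv).
#' @param S_query query score matrix with the same column count.
#' @return Numeric vector of (non-squared) distances, one per query row.
#' @details A singular covariance falls back to the Moore-Penrose
#'   pseudo-inverse with a warning; fewer calibration rows than score
#'   dimensions + 2 is an error.
#' @export
mahalanobis_distances <- function(S_cal, S_query) {
  S_cal <- as.matrix(S_cal); S_query <- as.matrix(S_query)
  d <- ncol(S_cal)
  if (ncol(S_query) != d)
    stop("score dimension mismatch: ", d, " vs ", ncol(S_query))
  if (nrow(S_cal) < d + 2L)
    stop("need more than n_lv + 1 calibration samples (got ", nrow(S_cal),
         " for ", d, " dimensions)")
  ctr <- colMeans(S_cal)
  C <- stats::cov(S_cal)
  d2 <- tryCatch(
    stats::mahalanobis(S_query, ctr, C),
    error = function(e) {
      warning("singular score covariance; using pseudo-inverse")
      X <- sweep(S_query, 2, ctr)
      rowSums((X %*% MASS::ginv(C)) * X)
    })
  sqrt(pmax(d2, 0))
}

#' Threshold for the fusion applicability domain
#'
#' Three times the arithmetic mean of the calibration samples' own
#' Mahalanobis distances; a validation sample whose distance exceeds this
#' limit is treated as outside the sensor's applicability domain.
#'
#' @param distances_cal non-negative distance vector for the calibration
#'   samples.
#' @return `3 * mean(distances_cal)`.
#' @export
compute_threshold <- function(distances_cal) {
  distances_cal <- as.numeric(distances_cal)
  if (length(distances_cal) == 0L) stop("empty distance vector")
  if (any(distances_cal < 0) || any(!is.finite(distances_cal)))
    stop("distances must be finite and >= 0")
  3 * mean(distances_cal)
}

#' Bundle a sensor's Mahalanobis-distance profile
#'
#' Convenience container pairing a sensor's calibration-set distances (from
#' which the threshold is derived) with the distances of new samples.
#'
#' @param sensor_name sensor tag.
#' @param distances_cal calibration-sample distances (each sample against
#'   the full calibration covariance).
#' @param distances_new distances of the new/validation samples.
#' @return An object of class `md_profile` with a `threshold` field equal
#'   to [compute_threshold()] of `distances_cal`.
#' @export
md_profile <- function(sensor_name, distances_cal, distances_new) {
  structure(list(sensor_name = sensor_name,
                 distances_cal = as.numeric(distances_cal),
                 distances_new = as.numeric(distances_new),
                 threshold = compute_threshold(distances_cal)),
            class = "md_profile")
}

#' @export
print.md_profile <- function(x, ...) {
  cat(sprintf("<md_profile> sensor %s: threshold %.4g; %d/%d new samples inside\n",
              x$sensor_name, x$threshold,
              sum(x$distances_new <= x$threshold), length(x$distances_new)))
  invisible(x)
}

#' Assign reciprocal-distance fusion weights
#'
#' Per validation sample: sensors whose Mahalanobis distance lies within
#' their threshold (inclusive) receive raw weight `1 / max(D, 1e-12)`,
#' sensors beyond it receive exactly 0; raw weights are then normalized so
#' each row sums to 1. When every sensor exceeds its threshold the sample
#' is flagged as extrapolation and the reciprocal weights are normalized
#' over all sensors instead, so a prediction is always produced.
#'
#' @param D distance matrix, n_samples x n_sensors, non-negative.
#' @param thresholds per-sensor threshold vector (length = ncol(D)).
#' @param weight_power exponent on the reciprocal distance (default 1,
#'   i.e. weights proportional to 1/D; 2 gives 1/D^2).
#' @return An object of class `weight_matrix`: `weights` (rows sum to 1),
#'   `extrapolation_flags` (logical, per sample), `distances`,
#'   `thresholds`.
#' @examples
#' w <- assign_weights(rbind(c(2.731, 2.454)), c(8.239, 7.517))
#' round(w$weights, 4)   # 0.4733 0.5267
#' @export
assign_weights <- function(D, thresholds, weight_power = 1) {
  D <- as.matrix(D)
  if (any(D < 0) || any(!is.finite(D))) stop("distances must be finite and >= 0")
  L <- ncol(D)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != L)
    stop("need one threshold per sensor (", L, "), got ", length(thresholds))
  raw <- (1 / pmax(D, 1e-12))^weight_power
  inside <- sweep(D, 2, thresholds, "<=")   # boundary is inclusive
  flags <- rowSums(inside) == 0L
  W <- matrix(0, nrow(D), L)
  for (i in seq_len(nrow(D))) {
    r <- if (flags[i]) raw[i, ] else raw[i, ] * inside[i, ]
    W[i, ] <- r / sum(r)
  }
  structure(list(weights = W, extrapolation_flags = flags,
                 distances = D, thresholds = thresholds),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %d samples x %d sensors, %d flagged as extrapolation\n",
              nrow(x$weights), ncol(x$weights), sum(x$extrapolation_flags)))
  invisible(x)
}
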