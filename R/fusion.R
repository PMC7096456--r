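#' Fuse per-sensor predictions with a weight matrix
#'
#' The fused prediction of a sample is the weighted sum of its per-sensor
#' predictions, `y_p = sum_i y_i w_i` — a convex combination because each
#' weight row is non-negative and sums to 1.
#'
#' @param Y per-sensor prediction matrix (n_samples x n_sensors).
#' @param W a [assign_weights()] `weight_matrix` (or a bare numeric matrix
#'   whose rows sum to 1).
#' @return Numeric vector of fused predictions.
#' @export
fuse <- function(Y, W) {
  Y <- as.matrix(Y)
  Wm <- if (inherits(W, "weight_matrix")) W$weights else as.matrix(W)
  if (!all(dim(Y) == dim(Wm)))
    stop("prediction matrix is ", nrow(Y), "x", ncol(Y),
         " but weights are ", nrow(Wm), "x", ncol(Wm))
  if (any(abs(rowSums(Wm) - 1) > 1e-8))
    stop("weight rows must sum to 1")
  rowSums(Y * Wm)
}

#' Prediction-set evaluation metrics
#'
#' @param y_true reference concentrations (% w/w), length >= 2.
#' @param y_pred predicted concentrations.
#' @return An object of class `evaluation_metrics` with `rmsep`
#'   (`sqrt(mean((pred - true)^2))`), `bias` (`mean(pred - true)`) and
#'   `slope` (ordinary least-squares slope of predicted vs. actual;
#'   ideally 1).
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    stop("y_true and y_pred must have equal length >= 2")
  if (stats::var(y_true) == 0)
    stop("zero variance in y_true: slope undefined")
  e <- y_pred - y_true
  structure(list(rmsep = sqrt(mean(e^2)), bias = mean(e),
                 slope = unname(stats::cov(y_true, y_pred) / stats::var(y_true))),
            class = "evaluation_metrics")
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  cat(sprintf("RMSEP %.4f %%  slope %.4f  bias %+.4f %%\n",
              x$rmsep, x$slope, x$bias))
  invisible(x)
}

# Extract the absorbance rows of `st` in the order of `ids`.
.absorbance_for <- function(st, ids) {
  idx <- .match_ids(st$sample_ids, ids,
                    paste0("sample ids (sensor ", st$sensor_name, ")"))
  st$absorbance[idx, , drop = FALSE]
}

#' Run the full Mahalanobis-distance-weighted fusion pipeline
#'
#' For each sensor: autoscale, choose the latent-variable count by
#' five-fold cross-validation, fit the PLS1 model, predict the validation
#' samples, project both sets into score space, and compute Mahalanobis
#' distances and the 3x-calibration-mean threshold. Reciprocal-distance
#' weights are then assigned per validation sample and the per-sensor
#' predictions fused into one output, which is evaluated alongside the
#' individual sensors.
#'
#' @param sensors list (length >= 2) of per-sensor lists, each with
#'   elements `cal` and `val` ([spectra_table()] objects for the
#'   calibration and validation samples of that sensor).
#' @param y_cal,y_val [reference_values()] for the two sample sets; every
#'   sensor must cover exactly the same sample ids (matching is by id, not
#'   position).
#' @param max_lv largest LV count offered to [select_lv()] (default 12).
#' @param folds CV folds (default 5).
#' @param weight_power reciprocal-distance exponent (default 1).
#' @param scale autoscale spectra (default `TRUE`).
#' @param outlier_check if `TRUE`, run [mc_outlier_detect()] per sensor on
#'   the calibration set first and error when any sample is flagged
#'   (off by default: screening is a pre-modelling step).
#' @return An object of class `fusion_result`: `per_sensor_predictions`
#'   (n_val x L), `fused_predictions`, `weights` (a `weight_matrix`),
#'   `md_profiles` (per sensor), `metrics_per_sensor`, `metrics_fused`,
#'   `models`, `lv_choices`, `sample_ids`, `y_val`.
#' @export
run_mdw_pipeline <- function(sensors, y_cal, y_val, max_lv = 12L,
                             folds = 5L, weight_power = 1, scale = TRUE,
                             outlier_check = FALSE) {
  if (length(sensors) < 2L)
    stop("high-level fusion needs at least 2 sensors, got ", length(sensors))
  stopifnot(inherits(y_cal, "reference_values"),
            inherits(y_val, "reference_values"))
  cal_ids <- y_cal$sample_ids; val_ids <- y_val$sample_ids
  L <- length(sensors)
  sensor_names <- vapply(seq_len(L), function(i) {
    nm <- sensors[[i]]$cal$sensor_name
    if (is.null(nm)) paste0("sensor", i) else nm
  }, character(1))

  models <- vector("list", L)
  lv_choices <- integer(L)
  Yv <- matrix(NA_real_, length(val_ids), L,
               dimnames = list(val_ids, sensor_names))
  Dv <- matrix(NA_real_, length(val_ids), L)
  thresholds <- numeric(L)
  profiles <- vector("list", L)

  for (i in seq_len(L)) {
    Xc <- .absorbance_for(sensors[[i]]$cal, cal_ids)
    Xv <- .absorbance_for(sensors[[i]]$val, val_ids)
    if (outlier_check) {
      rep_i <- mc_outlier_detect(Xc, y_cal$concentration,
                                 n_lv = min(10L, nrow(Xc) %/% 4L), scale = scale)
      if (any(rep_i$flagged))
        stop("sensor ", sensor_names[i], ": calibration outlier(s) flagged: ",
             paste(which(rep_i$flagged), collapse = ", "))
    }
    sel <- select_lv(Xc, y_cal$concentration, max_lv = max_lv,
                     folds = folds, scale = scale)
    m <- fit_pls(Xc, y_cal$concentration, n_lv = sel$n_lv, scale = scale)
    m$rmsecv_curve <- sel$rmsecv_curve
    d_cal <- mahalanobis_distances(m$cal_scores, m$cal_scores)
    S_val <- project_scores(m, Xv)
    d_val <- mahalanobis_distances(m$cal_scores, S_val)
    profiles[[i]] <- md_profile(sensor_names[i], d_cal, d_val)
    models[[i]] <- m
    lv_choices[i] <- sel$n_lv
    Yv[, i] <- predict(m, Xv)
    Dv[, i] <- d_val
    thresholds[i] <- profiles[[i]]$threshold
  }

  W <- assign_weights(Dv, thresholds, weight_power = weight_power)
  fused <- fuse(Yv, W)

  # convexity guard: each fused value must lie inside the span of its
  # per-sensor predictions
  lo <- apply(Yv, 1, min); hi <- apply(Yv, 1, max)
  stopifnot(all(fused >= lo - 1e-9), all(fused <= hi + 1e-9))

  metrics <- lapply(seq_len(L), function(i)
    evaluate_predictions(y_val$concentration, Yv[, i]))
  names(metrics) <- sensor_names

  structure(list(per_sensor_predictions = Yv, fused_predictions = fused,
                 weights = W, md_profiles = profiles,
                 metrics_per_sensor = metrics,
                 metrics_fused = evaluate_predictions(y_val$concentration, fused),
                 models = models,
                 lv_choices = stats::setNames(lv_choices, sensor_names),
                 sample_ids = val_ids, y_val = y_val$concentration),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  L <- ncol(x$per_sensor_predictions)
  cat(sprintf("<fusion_result> %d validation samples, %d sensors\n",
              length(x$fused_predictions), L))
  for (nm in names(x$metrics_per_sensor)) {
    m <- x$metrics_per_sensor[[nm]]
    cat(sprintf("  %-8s (%2d LVs): RMSEP %.4f  slope %.4f  bias %+.4f\n",
                nm, x$lv_choices[[nm]], m$rmsep, m$slope, m$bias))
  }
  m <- x$metrics_fused
  cat(sprintf("  %-8s          RMSEP %.4f  slope %.4f  bias %+.4f\n",
              "fused", m$rmsep, m$slope, m$bias))
  if (any(x$weights$extrapolation_flags))
    cat("  extrapolation-flagged samples:",
        paste(x$sample_ids[x$weights$extrapolation_flags], collapse = ", "), "\n")
  invisible(x)
}
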