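# NIPALS PLS1 with deflation of X only. Deterministic: the weight vector of
# each component is w = E'y / ||E'y||, no random initialization. Returns the
# decomposition up to `a_max` components, stopping early if the residual X
# or the X'y covariance collapses (rank exhausted).
.nipals_pls1 <- function(Xs, yc, a_max) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, a_max); P <- matrix(0, p, a_max)
  q <- numeric(a_max); TT <- matrix(0, n, a_max)
  E <- Xs
  tol <- (sqrt(sum(Xs^2)) * sqrt(sum(yc^2)) + 1e-300) * 1e-12
  a <- 0L
  for (comp in seq_len(a_max)) {
    w <- crossprod(E, yc)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break                       # y-relevant variance exhausted
    w <- w / nw
    tt <- E %*% w
    t2 <- sum(tt^2)
    if (t2 < 1e-24) break
    pp <- crossprod(E, tt) / t2
    q[comp] <- sum(yc * tt) / t2
    E <- E - tt %*% t(pp)
    W[, comp] <- w; P[, comp] <- pp; TT[, comp] <- tt
    a <- comp
  }
  if (a == 0L) stop("degenerate system: X carries no covariance with y")
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       q = q[seq_len(a)], scores = TT[, seq_len(a), drop = FALSE], a = a)
}

# X_new (preprocessed) -> scores: T = X R with R = W (P'W)^-1
.pls_rotation <- function(W, P) {
  W %*% solve(crossprod(P, W))
}

#' Fit a PLS1 calibration model
#'
#' Deterministic NIPALS PLS1: X is autoscaled (or mean-centered when
#' `scale = FALSE`) and y mean-centered before the bilinear decomposition;
#' X alone is deflated between components. The calibration score matrix is
#' retained because the Mahalanobis distances that drive fusion weighting
#' are computed in this score space.
#'
#' @param X calibration absorbance matrix (raw scale; the scaler is fitted
#'   and stored internally).
#' @param y reference concentrations, length `nrow(X)`.
#' @param n_lv number of latent variables, at most `min(nrow(X) - 1, ncol(X))`.
#' @param scale autoscale columns (`TRUE`, default) or mean-center only.
#' @return An object of class `pls_calibration`: `scaler`, `y_center`,
#'   `x_weights`, `x_loadings`, `y_loadings`, `coefficients` (on the
#'   preprocessed scale), `n_lv`, `cal_scores` (n_cal x n_lv), and
#'   `rmsecv_curve` (filled in by [select_lv()], otherwise `NULL`).
#' @export
fit_pls <- function(X, y, n_lv, scale = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("y length does not match nrow(X)")
  if (n_lv < 1L) stop("n_lv must be >= 1")
  if (n_lv > min(n - 1L, p))
    stop("n_lv = ", n_lv, " exceeds min(n - 1, p) = ", min(n - 1L, p))
  if (stats::sd(y) == 0) stop("degenerate y: zero variance")
  scaler <- autoscale_fit(X, scale = scale)
  Xs <- autoscale_apply(scaler, X)
  y_center <- mean(y)
  dec <- .nipals_pls1(Xs, y - y_center, n_lv)
  if (dec$a < n_lv)
    stop("n_lv = ", n_lv, " exceeds the effective rank of X (", dec$a, ")")
  R <- .pls_rotation(dec$W, dec$P)
  structure(list(scaler = scaler, y_center = y_center,
                 x_weights = dec$W, x_loadings = dec$P, y_loadings = dec$q,
                 coefficients = as.numeric(R %*% dec$q),
                 n_lv = dec$a, cal_scores = dec$scores,
                 rmsecv_curve = NULL),
            class = "pls_calibration")
}

#' @export
print.pls_calibration <- function(x, ...) {
  cat(sprintf("<pls_calibration> %d LVs, %d wavenumbers, %d calibration samples\n",
              x$n_lv, length(x$coefficients), nrow(x$cal_scores)))
  invisible(x)
}

#' Predict concentrations from a fitted PLS calibration
#'
#' @param object a [fit_pls()] model.
#' @param X_new absorbance matrix (raw scale) with the training column count.
#' @param ... unused.
#' @return Numeric vector of predicted concentrations (% w/w).
#' @export
predict.pls_calibration <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  Xs <- autoscale_apply(object$scaler, X_new)
  as.numeric(Xs %*% object$coefficients) + object$y_center
}

#' Project new spectra into a model's PLS score space
#'
#' Applies the stored preprocessing, then the PLS rotation
#' `R = W (P'W)^-1`; projecting the calibration matrix reproduces the
#' stored calibration scores.
#'
#' @param model a [fit_pls()] model.
#' @param X_new absorbance matrix (raw scale).
#' @return Score matrix, `nrow(X_new)` x `n_lv`.
#' @export
project_scores <- function(model, X_new) {
  stopifnot(inherits(model, "pls_calibration"))
  Xs <- autoscale_apply(model$scaler, as.matrix(X_new))
  Xs %*% .pls_rotation(model$x_weights, model$x_loadings)
}

# Venetian-blind fold assignment over the concentration-sorted sample list:
# deterministic, and stratifies the concentration range across folds.
.venetian_folds <- function(y, folds) {
  f <- integer(length(y))
  f[order(-y)] <- rep_len(seq_len(folds), length(y))
  f
}

#' Select the number of latent variables by cross-validation
#'
#' Computes RMSECV(k) for k = 1..`max_lv` with a deterministic
#' venetian-blind fold assignment over the concentration-sorted samples,
#' and returns the smallest k attaining the minimum (within 1e-12).
#'
#' @param X calibration matrix (raw scale).
#' @param y reference concentrations.
#' @param max_lv largest LV count to evaluate; silently truncated (with a
#'   warning) when it exceeds the feasible rank of a training fold, in
#'   which case RMSECV is flat beyond the feasible rank.
#' @param folds number of CV folds (default 5; `folds = length(y)` gives
#'   leave-one-out).
#' @param scale autoscale within each fold (default `TRUE`).
#' @return List with `n_lv` (chosen count) and `rmsecv_curve`
#'   (length `max_lv`, RMSECV(k) = sqrt(sum of held-out squared errors / n)).
#' @export
select_lv <- function(X, y, max_lv, folds = 5L, scale = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (folds < 2L || folds > n) stop("folds must be in [2, n]")
  if (max_lv < 1L) stop("max_lv must be >= 1")
  cap <- min(n - ceiling(n / folds) - 1L, ncol(X))
  if (max_lv > cap) {
    warning("max_lv = ", max_lv, " exceeds the feasible rank ", cap,
            "; truncating")
    max_lv <- cap
  }
  fold_id <- .venetian_folds(y, folds)
  sse <- numeric(max_lv)
  rank_short <- FALSE
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    scaler <- autoscale_fit(X[!hold, , drop = FALSE], scale = scale)
    Xtr <- autoscale_apply(scaler, X[!hold, , drop = FALSE])
    Xte <- autoscale_apply(scaler, X[hold, , drop = FALSE])
    yc <- mean(y[!hold])
    dec <- .nipals_pls1(Xtr, y[!hold] - yc, max_lv)
    if (dec$a < max_lv) rank_short <- TRUE
    Tte <- Xte %*% .pls_rotation(dec$W, dec$P)
    for (k in seq_len(max_lv)) {
      kk <- min(k, dec$a)   # beyond the feasible rank the model is frozen
      pred <- Tte[, seq_len(kk), drop = FALSE] %*% dec$q[seq_len(kk)] + yc
      sse[k] <- sse[k] + sum((as.numeric(pred) - y[hold])^2)
    }
  }
  if (rank_short)
    warning("effective rank below max_lv in at least one fold; ",
            "RMSECV is flat beyond it")
  rmsecv <- sqrt(sse / n)
  n_lv <- which(rmsecv <= min(rmsecv) + 1e-12)[1]
  list(n_lv = as.integer(n_lv), rmsecv_curve = rmsecv)
}

#' Monte-Carlo outlier screening
#'
#' Repeatedly holds out a random fraction of the samples, fits a PLS model
#' on the remainder, and records each held-out sample's absolute prediction
#' residual, building one residual distribution per sample.
#'
#' Flagging uses the lower decile of each sample's residual distribution
#' rather than its mean: when a gross outlier sits in the training
#' portion it corrupts the model and inflates *every* held-out residual,
#' so mean residuals mask the culprit, but in the resamples where the
#' outlier itself is held out the model is clean and ordinary samples
#' predict well — their best-decile residual stays small, while a genuine
#' outlier mispredicts in every single resample. A sample is flagged when
#' the z-score of its log lower-decile residual across samples exceeds
#' `threshold_multiplier`. The per-sample residual means and standard
#' deviations are returned as diagnostics (they are the conventional
#' coordinates for inspecting the resampling visually).
#'
#' @param X calibration matrix (raw scale).
#' @param y reference concentrations.
#' @param n_lv latent variables for the screening models.
#' @param n_runs number of Monte-Carlo resamples (>= 100; default 1000).
#' @param holdout_fraction fraction held out per run (default 0.2).
#' @param threshold_multiplier flagging z-score cutoff (default 3).
#' @param scale autoscale (default `TRUE`).
#' @param seed RNG seed for the resampling (default 1; recorded in the
#'   report). The caller's RNG state is left untouched.
#' @return An object of class `outlier_report`: `residual_mean`,
#'   `residual_sd`, `residual_q10` (per sample), `flagged` (logical),
#'   `n_runs`, `seed`.
#' @export
mc_outlier_detect <- function(X, y, n_lv, n_runs = 1000L,
                              holdout_fraction = 0.2,
                              threshold_multiplier = 3, scale = TRUE,
                              seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n_runs < 100L) stop("n_runs must be >= 100")
  if (!(holdout_fraction > 0 && holdout_fraction < 0.5))
    stop("holdout_fraction must be in (0, 0.5)")
  m <- max(1L, as.integer(round(holdout_fraction * n)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  res <- vector("list", n)
  for (run in seq_len(n_runs)) {
    hold <- sample.int(n, m)
    fit <- fit_pls(X[-hold, , drop = FALSE], y[-hold],
                   n_lv = min(n_lv, n - m - 1L), scale = scale)
    r <- abs(predict(fit, X[hold, , drop = FALSE]) - y[hold])
    for (j in seq_along(hold))
      res[[hold[j]]] <- c(res[[hold[j]]], r[j])
  }
  cnt <- lengths(res)
  if (any(cnt < 2L))
    stop("sample(s) ", paste(which(cnt < 2L), collapse = ", "),
         " held out fewer than twice; increase n_runs")
  mu <- vapply(res, mean, numeric(1))
  sd_i <- vapply(res, stats::sd, numeric(1))
  q10 <- vapply(res, stats::quantile, numeric(1), probs = 0.1, names = FALSE)
  lq <- log(pmax(q10, 1e-300))
  spread <- stats::sd(lq)
  flagged <- if (!is.finite(spread) || spread < 1e-12) rep(FALSE, n)
             else (lq - mean(lq)) / spread > threshold_multiplier
  structure(list(residual_mean = mu, residual_sd = sd_i, residual_q10 = q10,
                 flagged = flagged,
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d runs (seed %d): %d of %d samples flagged\n",
              x$n_runs, x$seed, sum(x$flagged), length(x$flagged)))
  if (any(x$flagged))
    cat("  flagged:", paste(which(x$flagged), collapse = ", "), "\n")
  invisible(x)
}
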