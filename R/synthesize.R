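#' Describe one synthetic sensor
#'
#' @param name sensor tag.
#' @param grid wavenumber grid as `c(start, end, step)` (cm^-1).
#' @param analyte_bands matrix/data.frame with columns `center`, `width`,
#'   `height`: Gaussian bands whose amplitude is `height * concentration`
#'   (Beer-Lambert linearity).
#' @param interferent_bands columns `center`, `width`, `amp_max`: bands
#'   whose amplitude is drawn uniformly on `[0, amp_max]` per sample,
#'   independent of concentration (solvent/excipient signal).
#' @param baseline_amplitude scale of a smooth per-sample quadratic
#'   baseline drift (absorbance units).
#' @param noise_sd i.i.d. Gaussian noise standard deviation (absorbance).
#' @param artifact_band `c(center, width)` or `c(center, width, jitter)`
#'   of the spurious band added to artifact-bearing samples; with a jitter
#'   term the realized center is drawn per sample from
#'   `center + U(-jitter, jitter)`, so the artifact is not a single fixed
#'   direction the calibration could learn to cancel.
#' @param artifact_magnitude nominal amplitude of the artifact band; the
#'   realized amplitude is `artifact_magnitude * (0.5 + U(0,1))`.
#' @return A list of class `sensor_config`.
#' @export
sensor_config <- function(name, grid, analyte_bands, interferent_bands,
                          baseline_amplitude, noise_sd,
                          artifact_band, artifact_magnitude) {
  stopifnot(length(grid) == 3L, grid[2] > grid[1], grid[3] > 0,
            baseline_amplitude >= 0, noise_sd >= 0,
            length(artifact_band) %in% c(2L, 3L), artifact_magnitude >= 0)
  if (length(artifact_band) == 2L) artifact_band <- c(artifact_band, 0)
  structure(list(name = name, grid = as.numeric(grid),
                 analyte_bands = as.matrix(analyte_bands),
                 interferent_bands = as.matrix(interferent_bands),
                 baseline_amplitude = baseline_amplitude,
                 noise_sd = noise_sd,
                 artifact_band = as.numeric(artifact_band),
                 artifact_magnitude = artifact_magnitude),
            class = "sensor_config")
}

#' Configuration for the two-sensor synthetic benchmark generator
#'
#' @param n_samples number of samples.
#' @param concentration_range `c(low, high)` analyte content (% w/w);
#'   concentrations are drawn uniformly, emulating a designed calibration
#'   series covering the range.
#' @param sensors list of [sensor_config()] objects.
#' @param artifact_fraction fraction of samples (per sensor) receiving the
#'   sensor's artifact band, in [0, 0.5]; artifact sets are disjoint
#'   between sensors, so every sample is clean on at least one sensor when
#'   `artifact_fraction * n_sensors <= 1`.
#' @param seed master RNG seed; per-sensor streams are derived from it so
#'   adding a sensor leaves the other sensors' data untouched.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples, concentration_range, sensors,
                             artifact_fraction = 0.15, seed = 1L) {
  stopifnot(n_samples >= 5L,
            length(concentration_range) == 2L,
            concentration_range[1] > 0,
            concentration_range[2] > concentration_range[1],
            artifact_fraction >= 0, artifact_fraction <= 0.5,
            length(sensors) >= 1L,
            all(vapply(sensors, inherits, logical(1), "sensor_config")))
  structure(list(n_samples = as.integer(n_samples),
                 concentration_range = as.numeric(concentration_range),
                 sensors = sensors,
                 artifact_fraction = artifact_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.gauss_band <- function(wn, center, width) exp(-0.5 * ((wn - center) / width)^2)

# deterministic derivation of one sub-seed per sensor from the master seed
.sensor_seed <- function(seed, i) (seed %% 1000003L) * 1009L + 7L * i

#' Generate a synthetic multi-sensor spectral dataset
#'
#' Each sensor's spectrum is a sum of concentration-proportional analyte
#' Gaussian bands, interferent bands with random per-sample amplitude, a
#' smooth quadratic baseline drift, and i.i.d. noise. A random subset of
#' samples per sensor additionally receives a large spurious band
#' overlapping the analyte region — those samples are locally unreliable
#' for that sensor and acquire larger Mahalanobis distances, which is the
#' mechanism distance-weighted fusion exploits. Artifact subsets are
#' disjoint between sensors.
#'
#' @param config a [synthetic_config()].
#' @return A list with `spectra` (list of [spectra_table()], one per
#'   sensor), `reference` ([reference_values()]), and `artifact_labels`
#'   (logical matrix, n_samples x n_sensors: `TRUE` where the sample
#'   carries that sensor's artifact).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  L <- length(config$sensors)
  m_art <- round(config$artifact_fraction * n)
  if (m_art * L > n)
    stop("artifact_fraction too large for disjoint per-sensor artifact sets")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  set.seed(config$seed)
  conc <- stats::runif(n, config$concentration_range[1],
                       config$concentration_range[2])
  ids <- sprintf("s%03d", seq_len(n))
  perm <- sample.int(n)           # disjoint artifact pools, one slice per sensor
  labels <- matrix(FALSE, n, L,
                   dimnames = list(ids, vapply(config$sensors, `[[`,
                                               character(1), "name")))
  spectra <- vector("list", L)
  names(spectra) <- colnames(labels)

  for (i in seq_len(L)) {
    sc <- config$sensors[[i]]
    if (m_art > 0)
      labels[perm[((i - 1L) * m_art + 1L):(i * m_art)], i] <- TRUE
    set.seed(.sensor_seed(config$seed, i))
    wn <- seq(sc$grid[1], sc$grid[2], by = sc$grid[3])
    p <- length(wn)
    A <- matrix(0, n, p)
    for (b in seq_len(nrow(sc$analyte_bands))) {
      bb <- sc$analyte_bands[b, ]
      A <- A + outer(conc * bb["height"], .gauss_band(wn, bb["center"], bb["width"]))
    }
    for (b in seq_len(nrow(sc$interferent_bands))) {
      bb <- sc$interferent_bands[b, ]
      amp <- stats::runif(n, 0, bb["amp_max"])
      A <- A + outer(amp, .gauss_band(wn, bb["center"], bb["width"]))
    }
    if (sc$baseline_amplitude > 0) {
      t01 <- (wn - sc$grid[1]) / (sc$grid[2] - sc$grid[1])
      B <- cbind(1, t01, t01^2)
      coef <- matrix(stats::runif(3L * n, -1, 1) * sc$baseline_amplitude, n, 3L)
      A <- A + coef %*% t(B)
    }
    if (sc$noise_sd > 0)
      A <- A + matrix(stats::rnorm(n * p, sd = sc$noise_sd), n, p)
    if (any(labels[, i])) {
      rows <- which(labels[, i])
      amp <- sc$artifact_magnitude * (0.5 + stats::runif(length(rows)))
      ctr <- sc$artifact_band[1] +
        stats::runif(length(rows), -sc$artifact_band[3], sc$artifact_band[3])
      for (j in seq_along(rows))
        A[rows[j], ] <- A[rows[j], ] +
          amp[j] * .gauss_band(wn, ctr[j], sc$artifact_band[2])
    }
    spectra[[i]] <- spectra_table(ids, wn, A, sc$name)
  }
  list(spectra = spectra, reference = reference_values(ids, conc),
       artifact_labels = labels)
}

#' The frozen two-sensor benchmark configuration
#'
#' A 78-sample dataset spanning 0.1-4.98 % w/w analyte, measured by an
#' NIR-like sensor (broad overtone/combination bands, low noise) and a
#' MIR-like sensor (sharp fundamental bands, twice the noise). Each sensor
#' has its own disjoint 15% artifact subset, so for every sample at least
#' one sensor is clean — the regime in which Mahalanobis-distance-weighted
#' fusion is designed to help.
#'
#' @param seed master RNG seed (default 1).
#' @return A [synthetic_config()].
#' @export
default_benchmark <- function(seed = 1L) {
  nir <- sensor_config(
    name = "NIR",
    grid = c(4000, 6000, 8),
    analyte_bands = cbind(center = c(4300, 4600, 5900),
                          width  = c(40, 50, 60),
                          height = c(0.030, 0.022, 0.018)),
    interferent_bands = cbind(center = c(4450, 5200),
                              width  = c(80, 120),
                              amp_max = c(0.05, 0.08)),
    baseline_amplitude = 0.02,
    noise_sd = 0.002,
    artifact_band = c(4550, 45, 120),
    artifact_magnitude = 0.15)
  mir <- sensor_config(
    name = "MIR",
    grid = c(800, 1800, 4),
    analyte_bands = cbind(center = c(1123, 1500, 1610, 1740),
                          width  = c(12, 10, 14, 12),
                          height = c(0.070, 0.050, 0.060, 0.040)),
    interferent_bands = cbind(center = c(1040, 1450),
                              width  = c(25, 30),
                              amp_max = c(0.06, 0.07)),
    baseline_amplitude = 0.02,
    noise_sd = 0.004,
    artifact_band = c(1560, 15, 100),
    artifact_magnitude = 0.15)
  synthetic_config(n_samples = 78L, concentration_range = c(0.1, 4.98),
                   sensors = list(nir, mir), artifact_fraction = 0.15,
                   seed = seed)
}
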