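# Shared fixtures built in code.

# Random spectra table with reproducible content.
random_spectra <- function(n = 5, p = 8, seed = 42, sensor = "NIR") {
  set.seed(seed)
  spectra_table(sprintf("s%02d", seq_len(n)),
                seq(1000, by = 4, length.out = p),
                matrix(rnorm(n * p), n, p), sensor)
}

# Dataset where y is exactly (plus optional noise) a linear function of X:
# the "clean" regime for PLS and outlier-screening tests.
linear_dataset <- function(n = 40, p = 25, noise = 0.05, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p) / sqrt(p)
  y <- as.numeric(X %*% beta) + rnorm(n, sd = noise)
  list(X = X, y = y, beta = beta)
}

# Reported validation-set Mahalanobis distances and thresholds for the
# deltamethrin / emamectin benzoate NIR+MIR calibrations.
reported_md_fixture <- function() {
  md <- utils::read.csv(system.file("extdata", "pesticide_validation_md.csv",
                                    package = "mdwfuse"))
  thr <- utils::read.csv(system.file("extdata", "pesticide_md_thresholds.csv",
                                     package = "mdwfuse"))
  list(md = md, thresholds = thr)
}

# Generate the frozen benchmark, split it 63/15 by concentration rank, and
# run the full fusion pipeline. Returns the fusion_result plus the pieces.
run_benchmark <- function(seed, ...) {
  ds <- generate_dataset(default_benchmark(seed = seed))
  plan <- rank_split(ds$reference$concentration, 15 / 78,
                     ids = ds$reference$sample_ids)
  sensors <- lapply(ds$spectra, function(st)
    list(cal = subset_spectra(st, plan$calibration_ids),
         val = subset_spectra(st, plan$validation_ids)))
  fr <- run_mdw_pipeline(sensors,
                         subset_reference(ds$reference, plan$calibration_ids),
                         subset_reference(ds$reference, plan$validation_ids),
                         ...)
  list(result = fr, dataset = ds, plan = plan)
}

# Brute-force Mahalanobis oracle: solves the covariance system per query.
md_oracle <- function(S_cal, S_query) {
  ctr <- colMeans(S_cal)
  C <- cov(S_cal)
  apply(S_query, 1, function(s) {
    d <- s - ctr
    sqrt(sum(d * solve(C, d)))
  })
}
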