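test_that("fusion is a rowwise convex combination", {
  W <- rbind(c(0.5, 0.5), c(1, 0))
  Y <- rbind(c(2.0, 3.0), c(2.0, 3.0))
  expect_equal(fuse(Y, W), c(2.5, 2.0))

  # worked example with the reciprocal weights of the first deltamethrin
  # validation sample
  expect_equal(fuse(rbind(c(2.5, 2.7)), rbind(c(0.4733, 0.5267))),
               2.60534, tolerance = 1e-9)

  expect_error(fuse(Y, W[1, , drop = FALSE]), "but the weights|weights are")
  expect_error(fuse(Y, rbind(c(0.7, 0.5), c(1, 0))), "sum to 1")
})

test_that("evaluation metrics match hand arithmetic", {
  m <- evaluate_predictions(c(1, 2, 3), c(1.1, 1.9, 3.2))
  expect_equal(m$rmsep, sqrt(0.06 / 3), tolerance = 1e-12)
  expect_equal(m$bias, 0.2 / 3, tolerance = 1e-12)

  perfect <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$rmsep, 0)
  expect_equal(perfect$bias, 0)
  expect_equal(perfect$slope, 1)

  shifted <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3) + 0.3)
  expect_equal(shifted$rmsep, 0.3)
  expect_equal(shifted$bias, 0.3)
  expect_equal(shifted$slope, 1)

  expect_error(evaluate_predictions(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("evaluation metrics agree with direct recomputation", {
  for (s in 1:10) {
    set.seed(400 + s)
    yt <- runif(15, 0.1, 5)
    yp <- yt + rnorm(15, sd = 0.2)
    m <- evaluate_predictions(yt, yp)
    expect_equal(m$rmsep, sqrt(sum((yp - yt)^2) / 15), tolerance = 1e-12)
    expect_equal(m$bias, sum(yp - yt) / 15, tolerance = 1e-12)
    expect_equal(m$slope, unname(coef(lm(yp ~ yt))[2]), tolerance = 1e-9)
    expect_gte(m$rmsep, abs(m$bias))
  }
})

test_that("the pipeline satisfies the convexity error bound per sample", {
  out <- run_benchmark(seed = 101)
  fr <- out$result
  lo <- apply(fr$per_sensor_predictions, 1, min)
  hi <- apply(fr$per_sensor_predictions, 1, max)
  expect_true(all(fr$fused_predictions >= lo - 1e-9))
  expect_true(all(fr$fused_predictions <= hi + 1e-9))
  err_f <- abs(fr$fused_predictions - fr$y_val)
  err_max <- apply(abs(fr$per_sensor_predictions - fr$y_val), 1, max)
  expect_true(all(err_f <= err_max + 1e-9))
  expect_equal(rowSums(fr$weights$weights),
               rep(1, length(fr$fused_predictions)), tolerance = 1e-12)
})

test_that("fused predictions are invariant to sensor order", {
  ds <- generate_dataset(default_benchmark(seed = 55))
  plan <- rank_split(ds$reference$concentration, 15 / 78,
                     ids = ds$reference$sample_ids)
  mk <- function(st) list(cal = subset_spectra(st, plan$calibration_ids),
                          val = subset_spectra(st, plan$validation_ids))
  y_cal <- subset_reference(ds$reference, plan$calibration_ids)
  y_val <- subset_reference(ds$reference, plan$validation_ids)
  f12 <- run_mdw_pipeline(lapply(ds$spectra, mk), y_cal, y_val)
  f21 <- run_mdw_pipeline(lapply(rev(ds$spectra), mk), y_cal, y_val)
  expect_equal(f12$fused_predictions, f21$fused_predictions,
               tolerance = 1e-12)
  expect_equal(f12$weights$weights, f21$weights$weights[, 2:1],
               tolerance = 1e-12)
})

test_that("a pure-noise sensor still yields valid normalized weights", {
  cfg <- default_benchmark(seed = 9)
  noise_sensor <- sensor_config(
    name = "junk", grid = c(2000, 2400, 4),
    analyte_bands = cbind(center = 2200, width = 30, height = 0),
    interferent_bands = cbind(center = 2100, width = 50, amp_max = 0.05),
    baseline_amplitude = 0.01, noise_sd = 0.01,
    artifact_band = c(2300, 20), artifact_magnitude = 0)
  cfg2 <- synthetic_config(n_samples = cfg$n_samples,
                           concentration_range = cfg$concentration_range,
                           sensors = list(cfg$sensors[[1]], noise_sensor),
                           artifact_fraction = 0, seed = 9)
  ds <- generate_dataset(cfg2)
  plan <- rank_split(ds$reference$concentration, 15 / 78,
                     ids = ds$reference$sample_ids)
  sensors <- lapply(ds$spectra, function(st)
    list(cal = subset_spectra(st, plan$calibration_ids),
         val = subset_spectra(st, plan$validation_ids)))
  fr <- run_mdw_pipeline(sensors,
                         subset_reference(ds$reference, plan$calibration_ids),
                         subset_reference(ds$reference, plan$validation_ids),
                         max_lv = 8)
  expect_true(all(fr$weights$weights >= 0))
  expect_equal(rowSums(fr$weights$weights), rep(1, 15), tolerance = 1e-12)
  lo <- apply(fr$per_sensor_predictions, 1, min)
  hi <- apply(fr$per_sensor_predictions, 1, max)
  expect_true(all(fr$fused_predictions >= lo - 1e-9 &
                  fr$fused_predictions <= hi + 1e-9))
})

test_that("the pipeline rejects single sensors and misaligned ids", {
  ds <- generate_dataset(default_benchmark(seed = 2))
  plan <- rank_split(ds$reference$concentration, 15 / 78,
                     ids = ds$reference$sample_ids)
  mk <- function(st) list(cal = subset_spectra(st, plan$calibration_ids),
                          val = subset_spectra(st, plan$validation_ids))
  y_cal <- subset_reference(ds$reference, plan$calibration_ids)
  y_val <- subset_reference(ds$reference, plan$validation_ids)
  expect_error(run_mdw_pipeline(list(mk(ds$spectra[[1]])), y_cal, y_val),
               "at least 2 sensors")

  bad <- mk(ds$spectra[[2]])
  bad$cal$sample_ids[1] <- "rogue"
  expect_error(run_mdw_pipeline(list(mk(ds$spectra[[1]]), bad), y_cal, y_val),
               "mismatched sample ids")
})

test_that("fusing two equal-quality sensors does not degrade accuracy", {
  base <- default_benchmark()$sensors[[1]]
  twin <- sensor_config(name = "NIR2", grid = c(4000, 6000, 8),
                        analyte_bands = base$analyte_bands,
                        interferent_bands = base$interferent_bands,
                        baseline_amplitude = base$baseline_amplitude,
                        noise_sd = base$noise_sd,
                        artifact_band = base$artifact_band,
                        artifact_magnitude = base$artifact_magnitude)
  ratios <- vapply(1:20, function(s) {
    cfg <- synthetic_config(78, c(0.1, 4.98), list(base, twin),
                            artifact_fraction = 0.15, seed = 500 + s)
    ds <- generate_dataset(cfg)
    plan <- rank_split(ds$reference$concentration, 15 / 78,
                       ids = ds$reference$sample_ids)
    sensors <- lapply(ds$spectra, function(st)
      list(cal = subset_spectra(st, plan$calibration_ids),
           val = subset_spectra(st, plan$validation_ids)))
    fr <- run_mdw_pipeline(sensors,
                           subset_reference(ds$reference, plan$calibration_ids),
                           subset_reference(ds$reference, plan$validation_ids))
    best <- min(vapply(fr$metrics_per_sensor, `[[`, numeric(1), "rmsep"))
    c(fr$metrics_fused$rmsep, best)
  }, numeric(2))
  expect_lte(mean(ratios[1, ]), 1.02 * mean(ratios[2, ]))
})
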