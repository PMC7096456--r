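---
title: "Mahalanobis-distance-weighted fusion of multi-sensor calibrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mahalanobis-distance-weighted fusion of multi-sensor calibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdwfuse)
```

## The problem

Quantifying an active ingredient (for example a pesticide in a formulation,
in % w/w) from vibrational spectra is a multivariate calibration problem:
a PLS regression maps an absorbance spectrum to a concentration. Different
sensors see the same chemistry differently — NIR overtone/combination bands
have high signal-to-noise but overlap heavily, MIR fundamentals are sharp
and interpretable but noisier — and, more importantly, each instrument
fails on *different* samples: a bubble at the ATR crystal, a stray
interferent band, a baseline excursion. High-level (decision-level) fusion
keeps one independent model per sensor and combines only their final
predictions, so a sample that one sensor measured badly can still be
predicted well if any other sensor measured it cleanly.

The question is how to weight the sensors per sample. `mdwfuse` implements
a distance-based answer: a sensor deserves weight on a sample to the
degree that the sample looks like that sensor's calibration set.

## The method

For sensor $i$ with calibration spectra $X_i$ (autoscaled) and reference
concentrations $y$:

1. **Autoscaling.** Every wavenumber column is centred and scaled to unit
   variance (sample SD, denominator $n-1$), giving all variables equal
   leverage regardless of absolute absorbance.
2. **PLS1 by NIPALS** with deflation of $X$ only; the latent-variable
   count $k_i$ is chosen as the minimiser of RMSECV under five-fold
   cross-validation with a deterministic venetian-blind fold assignment
   over the concentration-sorted calibration samples.
3. **Score-space Mahalanobis distance.** New spectra are projected through
   the PLS rotation $R = W(P'W)^{-1}$ into the model's score space, and
   each sample's distance from the calibration cloud is
   $D(s) = \sqrt{(s-\bar s)' C^{-1} (s-\bar s)}$, with $\bar s$, $C$ the
   mean and covariance of the calibration scores. Working in score space
   keeps $C$ small ($k_i \times k_i$) and well-conditioned where the raw
   wavenumber covariance would be singular.
4. **Threshold.** Each sensor's applicability limit is three times the
   mean of its own calibration samples' distances. The factor three
   follows the convention that samples of a population lie within about
   three "standard deviations" — which is what a Mahalanobis distance
   measures — of the centroid.
5. **Weights.** For a validation sample with distances $D_1,\dots,D_L$:
   sensors with $D_i$ within their threshold get raw weight $1/D_i$,
   sensors beyond it get $0$, and the row is normalised to sum to one.
   The fused prediction is $y_p = \sum_i w_i\, y_i$ — a convex
   combination, so the fused value always lies between the per-sensor
   predictions and its absolute error never exceeds the worst sensor's.

## Design choices where the method is under-determined

Several details are not fixed by the description above; the package's
choices are:

* **Threshold basis.** The 3×-mean threshold is computed from the
  *calibration* samples' own distances (each sample against the full
  calibration covariance, leave-in). Computing it from validation
  distances would make the applicability domain depend on the prediction
  batch, which is conceptually wrong for an applicability criterion.
* **Boundary inclusive.** $D = $ threshold is still "inside": exclusion
  requires strict exceedance.
* **Reciprocal, not squared-reciprocal.** Weights use $1/D$; the exponent
  is exposed as `weight_power` for users who want sharper discounting.
* **All-excluded fallback.** If every sensor exceeds its threshold the
  sample is a genuine extrapolation; the pipeline still returns the
  normalised $1/D$ combination but flags the sample, because refusing to
  predict silently truncates a batch, whereas a flag lets the user decide.
* **Zero distance.** $D = 0$ (a sample exactly at the centroid) is capped
  at $10^{-12}$ before taking reciprocals; that sensor then dominates with
  weight $\approx 1$, which is the correct limit.
* **Split rule.** The concentration-ordered calibration/validation split
  is made concrete as systematic sampling: sort descending, take every
  $k$-th sample ($k = \mathrm{round}(1/f)$) starting at position
  $\lfloor k/2\rfloor + 1$. This spreads validation samples evenly over
  the range and keeps both extremes in calibration, so validation is
  always interpolation. A contiguous-block rule would satisfy the same
  description but concentrate the validation set in one part of the range.
* **LV tie-break.** The smallest LV count within $10^{-12}$ of the RMSECV
  minimum wins, so noiseless rank-$k$ systems select exactly $k$.

## Monte-Carlo outlier screening

Before modelling, `mc_outlier_detect()` repeatedly (default 1000 runs)
holds out a random 20% of the calibration set, fits a PLS model on the
rest, and collects each sample's absolute held-out residuals. The
conventional summary is the per-sample residual mean and SD, and both are
returned. Flagging, however, uses the **lower decile** of each sample's
residual distribution, on the log scale, with a $z > 3$ cutoff. The
reason is masking: a gross outlier corrupts every model in whose training
portion it sits, inflating *all* samples' mean residuals, and on real and
simulated data the outlier's own mean is then only marginally extreme.
But in the resamples where the outlier itself is held out the model is
clean, so ordinary samples achieve small best-decile residuals while a
genuine outlier — mispredicted under every model — cannot. In simulation
this separates a $+10\cdot\mathrm{SD}(y)$ response outlier from clean
samples by several standard deviations on both sides of the cutoff,
whereas mean-based rules either miss the outlier or flag clean samples.

## The synthetic benchmark

The reference NIR/MIR pesticide spectra behind the method are not
publicly deposited, so the package ships a generator
(`generate_dataset()`, frozen defaults in `default_benchmark()`) that
emulates the data regime rather than the data: 78 samples spanning
0.1–4.98 % w/w, measured by two sensors.

* Spectra are sums of Gaussian bands: analyte bands with amplitude
  proportional to concentration (Beer–Lambert linearity), interferent
  bands with random per-sample amplitude, a smooth random quadratic
  baseline, and i.i.d. noise. Band positions echo reported assignments
  for deltamethrin (NIR combination/overtone features near 4300, 4600 and
  5900 cm⁻¹; MIR fundamentals near 1123, 1500, 1610 and 1740 cm⁻¹).
* The MIR-like sensor carries twice the noise of the NIR-like sensor and
  correspondingly stronger analyte bands, so the two have comparable —
  but not equal — clean-sample accuracy, mirroring the near-equal RMSEPs
  real NIR/MIR pairs produce. With grossly unequal sensors no
  quality-blind per-sample weighting can track the better sensor, and the
  benchmark would misrepresent the regime the method targets.
* 15% of samples per sensor (disjoint sets, so every sample is clean on
  at least one sensor) receive an additive artifact band overlapping the
  analyte region, with random amplitude and a random centre drawn from a
  ±120 cm⁻¹ (NIR) / ±100 cm⁻¹ (MIR) window. The position jitter matters:
  a fixed artifact direction is partially learnable from the calibration
  set and would be orthogonalised away by PLS, weakening both the
  prediction damage and the Mahalanobis signal that the weighting relies
  on.
* One master seed drives everything; per-sensor streams are derived
  deterministically from it, so adding a sensor does not perturb the
  others' data.

What the generator does *not* emulate: instrument line-shape physics,
wavelength drift, multiplicative scatter effects, correlated (pink)
noise, and reference-method error in $y$. Tests passing on this benchmark
therefore demonstrate the fusion mechanism — artifact-bearing samples
acquire larger score-space distances and are down-weighted — not
instrument-grade performance on real formulations.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run the full pipeline on
78-sample, ~250-wavenumber, two-sensor datasets across 20 replicate
seeds, select LVs from a maximum of 12 with five-fold CV, and use 300 or
1000 Monte-Carlo resamples for the outlier checks — sizes chosen to match
the emulated study design while keeping a full run in the order of
seconds. Covariance inversion falls back to the Moore–Penrose
pseudo-inverse (with a warning) only when the score covariance is
singular; autoscaling treats a zero-variance column as a hard error
rather than silently flooring it, because a constant column carries no
information and an $\epsilon$-floored one distorts PLS weights. Model
files are JSON with 17 significant digits, which round-trips doubles
exactly; the calibration score matrix is stored in the model file because
distance computation needs it at prediction time.

## A worked run

```{r pipeline}
ds <- generate_dataset(default_benchmark(seed = 1))
plan <- rank_split(ds$reference$concentration, 15 / 78,
                   ids = ds$reference$sample_ids)
sensors <- lapply(ds$spectra, function(st)
  list(cal = subset_spectra(st, plan$calibration_ids),
       val = subset_spectra(st, plan$validation_ids)))
fit <- run_mdw_pipeline(sensors,
                        subset_reference(ds$reference, plan$calibration_ids),
                        subset_reference(ds$reference, plan$validation_ids))
fit
```

The fused RMSEP sits at or below the better sensor's because the samples
that damage one sensor's RMSEP are exactly those the distance weighting
hands to the other sensor.

## Known limitations

* Weights reflect *representativeness*, not *accuracy*: a sensor that is
  uniformly noisy but whose samples sit nicely inside its calibration
  cloud is not discounted. Fusion therefore helps most when sensors have
  comparable baseline quality and sample-specific failures.
* The Mahalanobis distance assumes an approximately elliptical
  calibration score cloud; strongly clustered or curved calibration
  designs would need a local or robust distance.
* PLS1 only (single analyte); multi-response fusion is out of scope.
* The outlier screen targets gross response outliers; subtle leverage
  outliers in $X$ with consistent $y$ are left for the Mahalanobis
  threshold to handle at prediction time.
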