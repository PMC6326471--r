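# smlmgan

Single-molecule localization microscopy (dSTORM) through a consumer
camera: simulation, calibration, compression modelling, and a learned
localizer.

## The problem

dSTORM reaches sub-diffraction resolution by localizing sparse blinking
fluorophores over thousands of video frames. Consumer cameras (phone
sensors in particular) could make that affordable, but their firmware
compresses the video stream: an H.264-style codec applies a 4×4
exact-match integer transform per block and quantizes the coefficients.
Classical spot detectors then fire on the resulting block edges, littering
reconstructions with a grid of false localizations, and the low photon
budget makes everything worse. `smlmgan` is a research toolkit for exactly
this regime, for people who want to (a) characterize such a camera, (b)
simulate realistic degraded acquisitions with known ground truth, and (c)
compare a classical localizer against a learned one that suppresses the
compression artifacts.

## What is inside

* **Camera model** — the Poisson–Gaussian sensor
  `ADU = round((Poisson(ημ) + N(0, σ_r²))/g + o)`, its inverse
  (photon-transfer-curve calibration: per-pixel mean–variance statistics,
  robust line fit, `gain = 1/slope`, censored-normal dark statistics for
  offset and read noise, saturation-breakpoint detection), and dark-series
  diagnostics (drift slope, periodic intensity dips found by
  autocorrelation).
* **Degradation** — the H.264 4×4 integer transform `Y = C X Cᵀ` with
  uniform coefficient quantization (`quality` 100 = exactly lossless),
  optional pass through a real codec, and injectable temporal artifacts.
* **Blinking simulator** — Poisson emitter counts at a configured
  density, pixel-integrated Gaussian PSF rendering, single-pixel
  localization maps on an upsampled grid, and paired training data for
  the learned localizer.
* **Classical localizer** — difference-of-Gaussians detection with a
  `k·std(frame)` threshold and Levenberg–Marquardt Gaussian fitting.
* **GAN localizer** — a conditional image-to-image network (U-Net
  generator with resize-convolutions, patch discriminator) trained with
  `λ_cGAN·L_cGAN + λ_L1·‖(y − ŷ) ⊗ PSF‖₁ + λ_L1s·‖ŷ‖₁`
  (defaults λ = 3, 100, 100; adversarial term warmed up and gated),
  emitting single-pixel localization maps from degraded frames.
* **Evaluation** — greedy nearest-neighbor matching within a radius
  (200 nm standard), photon × quality accuracy sweeps, event-density
  traces, histogram/Gaussian reconstruction rendering, and Fourier ring
  correlation with the 1/7 threshold.

The methods vignette (`vignettes/methods.Rmd`) documents every model,
default and design decision in detail.

## Worked example: calibrate a simulated phone sensor

```r
library(smlmgan)

p <- sensor_preset("huawei_p9")
p
#> <sensor_params> gain 0.69 e-/ADU, offset 4.1 ADU, read noise 2.5 e- RMS,
#>   12 bit, linear up to 220 ADU, QE 0.75

# ten frames of a static dim ramp, then invert the sensor model
frames <- lapply(1:10, function(i)
  simulate_sensor(calibration_ramp(p), p, seed = 100 + i))
calibrate_mean_variance(frames)
#> <calibration_result> gain 0.7076 e-/ADU, offset 4.098 ADU, read noise 2.578 e- RMS
#>   linear up to 211.4 ADU (53/56 mean bins in fit)
```

The recovered gain, offset and read noise sit within a few percent of the
generating values; `linear_max_est` reports the top of the range the fit
actually used (the ramp here stays below saturation). Saturating the
sensor instead recovers the clip level:

```r
cal <- calibration_experiment(seed = 2, clip = TRUE)$calibration
cal$linear_max_est
#> [1] 219.526
```

Dark-series diagnostics find periodic compression dips — 31 frames at
29 fps is a 1.07 s period:

```r
dark_series_experiment(seed = 1, fps = 29)
#> <dark_series_stats> 320 frames at 29 fps, drift -0.01018 ADU/frame
#>   periodic dip every 31 frames = 1.07 s
```

And the full learned-localizer loop — simulate paired training data, train
the small U-Net GAN, localize held-out frames, match against ground
truth — runs at desk scale in minutes:

```r
res <- endtoend_recovery(seed = 1)
res$match
#> <match_result> 952/996 GT matched (95.6%) of 1667 detections within 200 nm
#>   mean matched distance 41.2 nm
```

Here 95.6% of the held-out ground-truth events were recovered within the
200 nm match radius, with a 41 nm mean error — under half a camera pixel.
The detection surplus (1667 vs 996) reflects occasional splitting of one
event into neighboring components; the matching is one-to-one, so the
surplus does not inflate the matched fraction. Training this small is
seed-sensitive (see the methods vignette); the seeded run above is the
documented experiment.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/smlmgan simulate --config run.yaml --out outdir
Rscript inst/cli/smlmgan calibrate --in frames.tif
Rscript inst/cli/smlmgan localize-classic --in stack.tif --out locs.csv
```

Subcommands: `simulate`, `degrade`, `calibrate`, `darkstats`,
`localize-classic`, `train`, `localize-gan`, `evaluate`, `frc`. Every
output is accompanied by a YAML manifest with the seed and a config hash.

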