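---
title: "Models and methods behind smlmgan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smlmgan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`smlmgan` studies a specific failure regime of single-molecule localization
microscopy (SMLM/dSTORM): recordings made through a consumer camera whose
firmware compresses the video stream. Two degradations dominate there — sensor
noise at low photon counts, and the blocking artifacts of H.264-style
block-transform compression, which classical spot detectors mistake for
blinking events. The package provides the full simulation-to-evaluation chain:
a calibrated sensor model, a compression model, a blinking-emitter simulator,
a classical localizer as the comparison arm, a learned localizer (a
conditional image-to-image GAN emitting single-pixel localization maps), and
quantitative evaluation (nearest-neighbor matching and Fourier ring
correlation).

This vignette records the models, the tunable parameters and their defaults,
and the design decisions taken where more than one reasonable construction
exists. It states no empirical numbers beyond what the package's own test
suite and `scripts/acceptance.R` compute at run time.

## Sensor model and photon-transfer calibration

`simulate_sensor()` uses the standard Poisson–Gaussian camera model:

$$e \sim \mathrm{Poisson}(\eta\,\mu) + \mathcal{N}(0, \sigma_r^2), \qquad
\mathrm{ADU} = \mathrm{round}(e/g + o)$$

with expected photons $\mu$, quantum efficiency $\eta$, gain $g$ (e⁻/ADU),
read noise $\sigma_r$ (e⁻ RMS) and offset $o$ (ADU), clipped to the digitizer
range. This is the model implied whenever a sensor is described as
shot-noise limited and characterized by a mean–variance plot; below
saturation it yields the photon-transfer relation

$$\mathrm{var}(\mathrm{ADU}) = \frac{\overline{\mathrm{ADU}} - o}{g} +
\frac{\sigma_r^2}{g^2},$$

in which $\eta$ cancels — calibration estimates the gain in photo-electrons
regardless of quantum efficiency.

`calibrate_mean_variance()` inverts this: per-pixel temporal means and
variances from repeated frames of a static scene are binned by mean, a line
is fitted robustly (iterative least squares discarding residuals beyond
3σ), and `gain = 1/slope`. Two estimator details are worth recording:

* **Offset.** Slope and intercept alone cannot separate the offset from the
  read noise (two unknowns, one intercept). The offset is therefore read
  from the darkest mean bin, and the read noise follows from
  $\sigma_r^2 = g^2 b + g\,o$ with intercept $b$. This requires the
  calibration scene to include a near-dark region — which a defocused dim
  ramp naturally has, and which `calibration_ramp()` guarantees.
* **Saturation breakpoint.** The end of the linear range is detected as the
  first mean bin whose variance departs from the fitted line by more than
  20% (relative). For a *downward* departure — the signature of clipping —
  the raw rule is systematically early: a Gaussian clipped at level $c$ has
  already lost 20% of its variance when its mean sits $1.151\sigma$ below
  $c$ (the constant solves the clipped-variance equation numerically). The
  estimator therefore adds $1.151\,\hat\sigma$ at the breakpoint bin.
  Upward departures (nonlinear gain rise) are reported uncorrected.

Three sensor presets ship as YAML (`sensor_preset()`): the parameter set
tied to the calibration procedure of the Huawei P9 monochrome chip at
ISO 3200 (gain 0.69 e⁻/ADU, offset 4.1 ADU, read noise 2.5 e⁻ RMS, linear
to 220 ADU, 12 bit), an alternative with a reported 1.23 e⁻ read-noise
figure for the same sensor, and an emCCD reference whose gain and offset
are synthetic typical values (only bit depth, read noise and QE are
reported for that camera; the YAML says so).

`analyze_dark_series()` reduces a dark stack to its per-frame mean trace,
fits the drift slope, and finds a periodic dip as the dominant local
maximum of the detrended trace's autocorrelation. A period is reported
only when that peak exceeds 5× the MAD of off-peak autocorrelation values;
visual inspection is what the threshold replaces, and 5 MADs is a
conventional strong-outlier criterion. The frame rate is an explicit
parameter everywhere — the same 31-frame periodicity is 1.07 s at 29 fps
and 1.55 s at 20 fps, and the module never hard-codes either. The module
measures the dips; it deliberately does not attribute them to a thermal or
codec cause.

## Compression model

`block_transform_degrade()` implements the H.264 4×4 exact-match integer
transform $Y = C X C^\top$ with

$$C = \begin{pmatrix} 1&1&1&1\\ 2&1&-1&-2\\ 1&-1&-1&1\\ 1&-2&2&-1 \end{pmatrix},$$

uniform quantization $\hat Y = \mathrm{round}(Y/q)\,q$, and the exact
inverse. Because $C$ is integer and invertible, quality 100 ($q = 1$) is
exactly lossless on integer frames — the property that makes this an
"exact-match" transform.

The quality-to-step mapping is
$q(\text{quality}) = \max(1, \mathrm{round}(2^{(100-\text{quality})/6.25}))$.
The doubling period mirrors H.264's convention of doubling the quantizer
step every 6 QP. A gentler mapping (doubling every 12.5 points) was
considered and rejected: quantization here acts on the *raw* transform
coefficients, whose DC basis vector has 16× the pixel scale, so gentle
steps produce almost no visible blocking and the package's own
blocking-signature property (boundary gradients exceeding interior
gradients on dim noisy frames at quality ≤ 80) fails. With the 6.25-point
doubling the signature holds robustly at qualities 70 and 80 while
quality 100 remains lossless.

Only intra-frame compression is modelled in the bespoke path. Inter-frame
(GOP) effects appear as what they are measured to be in dark video: a slow
drift and periodic intensity dips, injected by
`inject_temporal_artifacts()` and recovered by `analyze_dark_series()` —
the loop the tests close. `encode_decode_video()` passes a stack through a
real H.264 encoder when `ffmpeg` is available and otherwise raises an
error that names the bespoke mode; intensity-dependent dip depth is known
to exist but unquantified, and is deliberately not guessed.

## Blinking simulator

`sample_emitters()` draws per-frame event counts
$\mathrm{Poisson}(\rho \cdot A)$ at density $\rho$ (emitters/μm², default 6)
over the field area $A$, positions uniform, photons either fixed (for
photon-sweep studies) or log-normal around the configured mean with
$\sigma_{\log} = 0.3$ — a modest brightness spread typical of organic
fluorophores; the studies this package emulates vary only the mean, so the
spread is a realism default, not a fitted value. Switching kinetics are not
modelled: every row is an independent single-frame event, matching
frame-wise training-label generation.

Rendering (`render_frames()`) integrates an isotropic Gaussian PSF over
each pixel with the error-function rule, so photons are conserved to
truncation (±5σ support). Defaults: pixel size 100 nm in the sample plane
and PSF σ 130 nm. Both are mandatory, documented choices — the effective
pixel size of a phone-camera-on-eyepiece system is setup-specific, and
130 nm corresponds to a mid-NA visible-light PSF.

Coordinates: x along columns, y along rows, both in nm, origin at the
outer corner of pixel (1,1), pixel centers at $(i-\tfrac12)\,\Delta$.
Localization maps (`render_location_maps()`) set exactly one upsampled
pixel per event — index $\lfloor \text{coord}/\Delta_{\text{up}} \rfloor$ —
to the event's photon value; collisions sum. The map's "brightness" unit is
therefore photons; since the training loss is normalized by the dataset
maximum, any global scale convention would train identically, which is why
the unit is documented rather than load-bearing.

`make_training_pairs()` chains the stages
(sample → render → sensor → compress → nearest-neighbor upsample) and
randomly offsets the 4×4 compression grid per stack so a learner cannot
memorize one block alignment. `pairs_from_localizations()` builds the
second kind of training data — maps rendered from a localizer's detections
on an existing stack — and `mix_training_pairs()` interleaves the two
50:50.

## Classical baseline localizer

`localize_stack()` is an explicit surrogate for established SMLM software
(difference-of-Gaussians band-pass, local maxima above
$k \cdot \mathrm{std}$ of the filtered frame with $k = 3$ as the
artifact-suppressing setting, and a windowed Levenberg–Marquardt fit of a
pixel-integrated Gaussian plus background). It does not reproduce any
specific program's wavelet or MLE internals; its role is to be a competent
classical localizer that exhibits the classical failure mode on blocking
artifacts. Fits are dropped when the solver fails to converge or the
fitted σ leaves [50, 400] nm; the window is 7 px; only single-emitter fits
are attempted. Because the fit model is the same pixel-integrated Gaussian
the renderer uses, noiseless recovery is exact to solver tolerance — a
deliberate property that lets tests separate solver error from model error.

## The GAN localizer

The generator is a U-Net: per encoder stage a 3×3 convolution (leaky ReLU
0.2) followed by 2×2 average pooling; a bottleneck convolution; per decoder
stage nearest-neighbor ×2 resize followed by a 3×3 convolution
("resize-convolution") and concatenation with the matching encoder skip.
Resize-convolution replaces transposed convolutions because the latter
produce checkerboard artifacts — exactly the high-frequency pattern a
localization map must not contain. The final layer is a 3×3 convolution
with ReLU, so maps are non-negative with *exact* zeros in the background.
Optional decoder dropout acts as the noise input of the conditional-GAN
formulation; it is off by default at inference so the localizer is
deterministic and testable, and can be switched on to sample.

The discriminator is a small fully convolutional patch network (two
stride-2-equivalent stages and a 1×1-style head) scoring overlapping
patches; because nothing in either network depends on the frame size,
inference accepts sizes different from training (odd sizes are
replicate-padded to a multiple of $2^{\text{depth}}$ and cropped back).

The generator objective combines three terms
(`composite_loss()`): the non-saturating conditional adversarial
cross-entropy on the discriminator's fake scores; an L1 distance between
PSF-convolved target and output maps; and an L1 sparsity penalty on the
output. Defaults $\lambda_{cGAN} = 3$, $\lambda_{L1} = 100$,
$\lambda_{L1s} = 100$. The λ weights appear exactly once, in the total —
applying them both inside the terms and in the sum would square them. The
adversarial weight is held at zero for the first 1000 iterations and
afterwards is active every 3rd iteration; the discriminator is likewise
updated only on active iterations. Both cadence and warm-up are config
fields of `loss_weights()`.

Two numerical choices matter enough to record:

* **Unit-peak loss kernel.** The PSF kernel of the smoothed L1 term is a
  Gaussian whose σ comes from the acquisition config (PSF σ divided by the
  upsampled pixel) and whose amplitude is normalized to **unit peak**
  rather than unit sum. With a unit-sum kernel the blurred single-pixel
  targets have peak amplitude $\approx 1/(2\pi\sigma^2)$ — near zero — and
  the all-zero map is almost optimal under L1, so training collapses to an
  empty output. The kernel's radius *and intensity* are free parameters of
  the smoothed comparison; unit peak keeps the blurred images O(1) and the
  reconstruction term competitive with the sparsity term. The radius is
  likewise a training parameter, determined per setup: the desk-scale
  experiments use half the physical PSF width on the map grid (2.6 px),
  because at the benchmark density the full-width kernel blurs neighboring
  emitters into single blobs that the component-based table extraction
  cannot split, which caps recall well below what the narrower kernel
  achieves.
* **ReLU, not softplus, at the output.** A strictly positive activation
  (softplus) can never emit an exact zero, so the sparsity and background
  terms exert a *constant-sign* L1 gradient that Adam renormalizes into a
  relentless drift of the pre-activations toward −∞, where the activation
  saturates and all gradients die irrecoverably. ReLU reaches exact zero,
  at which point the background pressure stops. The collapse mode is real
  — it is reproduced in the package's development history — and the ReLU
  choice is what prevents it.

Training (`train()`) uses minibatch Adam with first-moment decay
$\beta_1 = 0.25$ and default learning rate $10^{-4}$, batch 4, 10 epochs —
the configuration appropriate for full-scale datasets (tens of thousands
of 256×256 pairs). The desk-scale experiments in this package
(`endtoend_recovery()`) use a 16×16-pixel field upsampled 4×, a depth-3
generator with 8 base channels, learning rate $10^{-3}$ and enough epochs
to pass the adversarial warm-up; these sizes were chosen so a single-CPU
run finishes in minutes while still exercising every component (sensor
noise, compression, adversarial schedule, map extraction, matching).
Inputs are normalized by subtracting the dataset median (removing the dark
pedestal, which otherwise feeds border artifacts through zero-padded
convolutions) and dividing by the maximum; targets are normalized to unit
peak. The constants are stored in the model and undone at inference, so
`infer_stack()` returns maps in the training tables' photon units.

`maps_to_table()` converts maps to localization tables: pixels above
0.3 × the frame maximum are grouped into 8-connected components
(`EBImage::bwlabel`), each contributing one event at its
intensity-weighted centroid. Grouping is the right reading of a
threshold-then-convert rule on an upsampled grid, where one event
generally spans several pixels; per-pixel conversion would multiply-count
every peak. For reconstruction images, `sum_maps()` exposes thresholding
either per frame before summation or once on the summed image — both
orders are defensible and the choice is a flag.

Training this small is genuinely stochastic in outcome, not just in
trajectory: with a few hundred frames and ~1300 iterations, an unlucky
initialization can leave the network in a partial collapse (few, weak
peaks) that more data and iterations would escape. The desk-scale
experiment is therefore defined as a *seeded* configuration — the seeded
run is the experiment — and the seed-to-seed spread is a documented
property of the miniature regime, not of the method at scale.

All randomness in data generation, initialization, shuffling and dropout
flows from explicit integer seeds; two `train()` calls with the same seed
give identical loss histories and identical weights, which the tests
assert. Serialization (`export_model()`) writes the full model as RDS with
a YAML sidecar of architecture, seed and normalization metadata; reloading
reproduces inference bit-for-bit on the same platform.

## Evaluation

`match_events()` matches detections to ground truth per frame, greedily in
ascending distance, one-to-one, within a radius (200 nm in the standard
analyses). Greedy was chosen over optimal assignment because the evaluated
procedures do not specify an assignment rule and greedy is the common
choice in SMLM challenge tooling; an exhaustive oracle in the tests pins
the exact semantics. The mean distance is over matched pairs only — the
alternative (all detections) would mix localization error with
false-positive geometry; the matched-only reading keeps
`mean_distance ≤ radius` as an invariant.

`frc()` computes ring-wise normalized cross-correlation of two half-dataset
reconstructions' Fourier transforms, with the fixed 1/7 threshold and
linear interpolation to the crossing; halves are formed by odd/even frame
splits. Resolution is `NA` when the curve never crosses — correlated
identical inputs, for instance. Constant images are an error, not a zero.

`sweep_accuracy()` is the machine-readable photon × quality benchmark
grid: per cell it simulates a fresh stack (same seed, so cells differ only
in the swept parameters), runs each registered localizer, and reports the
match statistics as a data frame.

## Problem sizes and limitations

The test suite and acceptance script run at desk scale by design:
calibration from 10 ramp frames, dark series of a few hundred frames,
density checks at 2000 frames over 100 μm², and GAN training on a few
hundred 64×64 pairs. These sizes are the package's chosen study
conditions; the code paths are identical at larger sizes.

What the synthetic generator does **not** emulate — and what passing tests
therefore do not establish about real phone-camera data: fluorophore
switching kinetics and photobleaching; structured biological backgrounds
and out-of-focus light; the full codec (motion estimation, CABAC, in-loop
deblocking, rate control); intensity-dependent dip depths; and any
firmware image "enhancement" beyond compression. The GAN results here show
that the architecture and training machinery recover simulated emitters
through the modelled degradations; transferring to a real device requires
training data generated from that device's own calibration and codec
behavior, which is exactly the workflow the package automates.
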