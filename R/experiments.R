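# Canned experiments tying the modules together at desk scale. These fix
# the study conditions (sensor parameter set, ramp design, sweep grids,
# training size) in one place so tests, scripts and examples all exercise
# identical configurations.

#' Expected-photon ramp for photon-transfer calibration
#'
#' A smooth horizontal intensity ramp spanning `[0, max_adu]`-equivalent
#' mean levels for the given sensor, with a leading zero-photon margin
#' (`dark_frac` of the columns) so the calibration can anchor the
#' zero-photon variance and hence the offset and read noise.
#'
#' @param params a [sensor_params()].
#' @param nrow,ncol ramp image size in pixels.
#' @param max_adu mean ADU level at the bright edge.
#' @param dark_frac fraction of leading columns held at zero photons.
#' @param min_frac the lit region starts at `min_frac * max_adu` above the
#'   offset, like a defocused object on a dark background; the gap lets
#'   the calibration separate the dark cluster from the lit pixels.
#' @return Matrix of expected photons.
#' @export
calibration_ramp <- function(params, nrow = 120L, ncol = 200L, max_adu = 200,
                             dark_frac = 0.15, min_frac = 0.12) {
  to_photons <- function(adu)
    max(adu - params$offset, 0) * params$gain / params$qe
  n_dark <- round(ncol * dark_frac)
  ramp <- c(rep(0, n_dark),
            seq(to_photons(params$offset + min_frac * max_adu),
                to_photons(max_adu), length.out = ncol - n_dark))
  matrix(rep(ramp, each = nrow), nrow, ncol)
}

#' Photon-transfer calibration recovery experiment
#'
#' Simulates `n_frames` frames of a static intensity ramp with the given
#' sensor parameters and calibrates them back. With `clip = TRUE` the
#' ramp spans well past the linear range and the sensor saturates at
#' `params$linear_max`, exercising breakpoint detection.
#'
#' @param params sensor ground truth (default: the 0.69 e-/ADU, 4.1 ADU,
#'   2.5 e- parameter set).
#' @param seed integer seed.
#' @param n_frames frames in the calibration series.
#' @param clip simulate hard saturation at `params$linear_max`.
#' @return List with `calibration` (a `calibration_result`) and `params`.
#' @export
calibration_experiment <- function(params = sensor_preset("huawei_p9"),
                                   seed = 1L, n_frames = 10L, clip = FALSE) {
  max_adu <- if (clip) 500 else 200
  ph <- calibration_ramp(params, max_adu = max_adu)
  seeds <- derive_seeds(seed, n_frames)
  frames <- lapply(seq_len(n_frames), function(i)
    simulate_sensor(ph, params, seed = seeds[i], clip_to_linear_max = clip))
  list(calibration = calibrate_mean_variance(frames), params = params)
}

#' Dark-series periodicity experiment
#'
#' Builds a synthetic dark video: constant background plus small Gaussian
#' frame noise, a slow negative drift and a fixed dip every
#' `dip_period`-th frame, then measures it back with
#' [analyze_dark_series()].
#'
#' @param seed integer seed.
#' @param n_frames series length.
#' @param fps frame rate (dips every 31 frames at 29 fps give the 1.07 s
#'   signature).
#' @param dip_period,dip_depth dip spacing (frames) and depth (ADU).
#' @param drift_slope background drift in ADU/frame.
#' @return A `dark_series_stats` object.
#' @export
dark_series_experiment <- function(seed = 1L, n_frames = 320L, fps = 29,
                                   dip_period = 31L, dip_depth = 5,
                                   drift_slope = -0.01) {
  set.seed(seed)
  stack <- array(20 + stats::rnorm(32 * 32 * n_frames, 0, 0.5),
                 dim = c(32, 32, n_frames))
  stack <- inject_temporal_artifacts(stack, drift_slope = drift_slope,
                                     dip_depth = dip_depth,
                                     dip_period = dip_period)
  analyze_dark_series(stack, fps = fps)
}

#' The dense test-stack acquisition configuration
#'
#' The simulation benchmark configuration: 2000 frames at 6 emitters/um^2
#' over a 10 x 10 um field (100 x 100 px of 100 nm), fixed photon count,
#' default quality 90.
#'
#' @param photons photons per emitter.
#' @param quality compression quality percent.
#' @param n_frames number of frames.
#' @return An [acquisition_config()].
#' @export
dense_stack_config <- function(photons = 1000, quality = 90,
                               n_frames = 2000L) {
  acquisition_config(fov = 100L, pixel_size = 100, psf_sigma = 130,
                     density = 6, n_frames = n_frames,
                     photons_per_emitter = photons, photon_mode = "fixed",
                     upsample = 5L,
                     compression = compression_config(quality = quality))
}

#' Desk-scale configuration for end-to-end GAN training
#'
#' A small field (16 x 16 px of 100 nm, i.e. 2.56 um^2) at 2 emitters/um^2
#' and 1000 photons/emitter, quality 90, upsampled 4x to a 64 x 64 map
#' grid — small enough to train the localizer on a single CPU in minutes.
#'
#' @param n_frames number of training frames.
#' @return An [acquisition_config()].
#' @export
desk_gan_config <- function(n_frames = 320L) {
  acquisition_config(fov = 16L, pixel_size = 100, psf_sigma = 130,
                     density = 2, n_frames = n_frames,
                     photons_per_emitter = 1000, photon_mode = "fixed",
                     upsample = 4L,
                     compression = compression_config(quality = 90))
}

#' Desk-scale end-to-end localization recovery experiment
#'
#' Trains a small U-Net GAN localizer on synthetic pairs from
#' [desk_gan_config()], then evaluates it on held-out frames: generator
#' maps are converted to a localization table and matched against ground
#' truth within `radius` nm.
#'
#' The loss uses a supervision kernel of 2.6 map pixels — half the
#' physical PSF width on this grid. The narrower kernel keeps nearby
#' emitters separable in the blurred comparison images, which is what
#' limits recovery at this density; the kernel radius (and intensity) is
#' a per-setup training parameter, not a property of the data.
#'
#' @param seed master seed (training data, initialization, held-out data).
#' @param n_train training frames.
#' @param n_eval held-out evaluation frames.
#' @param epochs training epochs (batch 4).
#' @param radius match radius in nm.
#' @param psf_sigma_loss supervision-kernel sigma in map pixels.
#' @return List with `model`, `match` (a `match_result`), `detections`
#'   and `gt`.
#' @export
endtoend_recovery <- function(seed = 1L, n_train = 320L, n_eval = 200L,
                              epochs = 16L, radius = 200,
                              psf_sigma_loss = 2.6) {
  seeds <- derive_seeds(seed, 3)
  cfg <- desk_gan_config(n_train)
  pairs <- make_training_pairs(cfg, seed = seeds[1])
  unit <- psf_kernel(psf_sigma_loss)
  psf <- psf_kernel(psf_sigma_loss, amplitude = 1 / max(unit$kernel))
  model <- train(pairs,
                 gspec = generator_spec(depth = 3L, base_channels = 8L),
                 dspec = discriminator_spec(base_channels = 8L),
                 w = loss_weights(),
                 tc = train_config(learning_rate = 1e-3, batch_size = 4L,
                                   epochs = epochs, seed = seeds[2]),
                 psf = psf)
  eval_cfg <- desk_gan_config(n_eval)
  acq <- simulate_acquisition(eval_cfg, seed = seeds[3])
  maps <- infer_stack(model, acq$adu)
  det <- maps_to_table(maps, threshold_fraction = 0.3,
                       pixel_size = eval_cfg$pixel_size,
                       upsample = eval_cfg$upsample)
  list(model = model, match = match_events(det, acq$table, radius),
       detections = det, gt = acq$table)
}
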