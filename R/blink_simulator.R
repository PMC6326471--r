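#' Acquisition configuration for the blinking simulator
#'
#' Collects everything needed to synthesize a dSTORM acquisition: field of
#' view, camera pixel size, PSF width, per-frame emitter density, photon
#' budget, the map upsampling factor, and the sensor/compression forward
#' models. The coordinate convention is x along columns and y along rows,
#' both in nm, with the origin at the outer corner of pixel (1,1) so pixel
#' `i` spans `[(i-1), i) * pixel_size` and has its center at
#' `(i - 0.5) * pixel_size`.
#'
#' @param fov field of view in camera pixels, `c(rows, cols)` or a scalar
#'   for a square field.
#' @param pixel_size camera pixel size in the sample plane, nm.
#' @param psf_sigma Gaussian PSF standard deviation, nm.
#' @param density expected emitters per square micron per frame.
#' @param n_frames number of frames.
#' @param photons_per_emitter expected photons per blinking event.
#' @param photon_mode `"lognormal"` draws per-event photons log-normally
#'   around the configured mean (sdlog `photon_sdlog`), mimicking the
#'   brightness spread of real fluorophores; `"fixed"` uses the mean for
#'   every event (used for photon-sweep studies).
#' @param photon_sdlog log-scale spread of the log-normal photon draw.
#' @param upsample integer upsampling factor from camera grid to
#'   localization-map grid.
#' @param sensor a [sensor_params()] object, or `NULL` for an ideal
#'   noiseless camera (frames are the quantized expected photons).
#' @param compression a [compression_config()] object.
#' @return Object of class `acquisition_config`.
#' @export
acquisition_config <- function(fov = c(64L, 64L), pixel_size = 100,
                               psf_sigma = 130, density = 6, n_frames = 100L,
                               photons_per_emitter = 1000,
                               photon_mode = c("lognormal", "fixed"),
                               photon_sdlog = 0.3, upsample = 5L,
                               sensor = sensor_preset("huawei_p9"),
                               compression = compression_config(quality = 90)) {
  photon_mode <- match.arg(photon_mode)
  if (length(fov) == 1) fov <- c(fov, fov)
  fov <- as.integer(fov)
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (density < 0) stop("density must be >= 0")
  if (upsample < 1) stop("upsample must be >= 1")
  structure(list(fov = fov, pixel_size = pixel_size, psf_sigma = psf_sigma,
                 density = density, n_frames = as.integer(n_frames),
                 photons_per_emitter = photons_per_emitter,
                 photon_mode = photon_mode, photon_sdlog = photon_sdlog,
                 upsample = as.integer(upsample),
                 sensor = sensor, compression = compression),
            class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  area <- prod(x$fov) * (x$pixel_size / 1000)^2
  cat(sprintf(
    "<acquisition_config> %dx%d px (%.3g um^2), %g nm/px, PSF sigma %g nm\n  %d frames, %g emitters/um^2, %g photons/emitter (%s), upsample %dx\n",
    x$fov[1], x$fov[2], area, x$pixel_size, x$psf_sigma, x$n_frames,
    x$density, x$photons_per_emitter, x$photon_mode, x$upsample))
  invisible(x)
}

fov_area_um2 <- function(config) {
  prod(config$fov) * (config$pixel_size / 1000)^2
}

#' Sample ground-truth blinking events
#'
#' Per frame the event count is Poisson with mean `density * FOV area`;
#' positions are uniform over the field; photons are drawn according to
#' the configured photon model. Each row is an independent single-frame
#' event (on/off switching kinetics are not modelled).
#'
#' @param config an [acquisition_config()].
#' @param seed integer seed; output is deterministic given it.
#' @return An emitter table: `data.frame(id, frame, x, y, photons)` with
#'   `frame` 0-based and `x`, `y` in nm.
#' @export
sample_emitters <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  area <- fov_area_um2(config)
  counts <- stats::rpois(config$n_frames, config$density * area)
  n <- sum(counts)
  ext_y <- config$fov[1] * config$pixel_size
  ext_x <- config$fov[2] * config$pixel_size
  photons <- switch(config$photon_mode,
    fixed = rep(config$photons_per_emitter, n),
    lognormal = stats::rlnorm(
      n, meanlog = log(config$photons_per_emitter) - config$photon_sdlog^2 / 2,
      sdlog = config$photon_sdlog))
  tab <- data.frame(
    id = seq_len(n),
    frame = rep(seq_len(config$n_frames) - 1L, counts),
    x = stats::runif(n, 0, ext_x),
    y = stats::runif(n, 0, ext_y),
    photons = photons)
  class(tab) <- c("emitter_table", "data.frame")
  tab
}

#' Render expected-photon frames from an emitter table
#'
#' Each emitter deposits `photons` times a pixel-integrated isotropic 2-D
#' Gaussian (error-function rule per axis) of standard deviation
#' `psf_sigma`. Contributions are additive and no noise is applied; the
#' result is the expected-photon image passed to [simulate_sensor()].
#'
#' @param table emitter table from [sample_emitters()] (or compatible).
#' @param config an [acquisition_config()].
#' @return Array `c(fov, n_frames)` of expected photons.
#' @export
render_frames <- function(table, config) {
  nr <- config$fov[1]; nc <- config$fov[2]
  px <- config$pixel_size
  if (nrow(table) > 0) {
    if (any(table$x < 0 | table$x >= nc * px | table$y < 0 | table$y >= nr * px))
      stop("emitter outside the field of view")
    if (any(table$frame < 0 | table$frame >= config$n_frames))
      stop("emitter frame index outside [0, n_frames)")
  }
  stack <- array(0, dim = c(nr, nc, config$n_frames))
  sig <- config$psf_sigma
  half <- ceiling(5 * sig / px)
  for (k in seq_len(nrow(table))) {
    x0 <- table$x[k]; y0 <- table$y[k]; ph <- table$photons[k]
    f <- table$frame[k] + 1L
    ci <- floor(x0 / px) + 1L
    ri <- floor(y0 / px) + 1L
    cols <- max(1L, ci - half):min(nc, ci + half)
    rows <- max(1L, ri - half):min(nr, ri + half)
    # pixel-integrated Gaussian: 0.5*(erf(hi) - erf(lo)) per axis
    fx <- gauss_pixel_frac(cols, x0, px, sig)
    fy <- gauss_pixel_frac(rows, y0, px, sig)
    stack[rows, cols, f] <- stack[rows, cols, f] + ph * (fy %o% fx)
  }
  stack
}

# fraction of a unit-mass Gaussian centered at c0 (nm) falling into the
# pixels with 1-based indices idx of width px
gauss_pixel_frac <- function(idx, c0, px, sigma) {
  lo <- (idx - 1) * px
  hi <- idx * px
  s <- sigma * sqrt(2)
  0.5 * (pracma::erf((hi - c0) / s) - pracma::erf((lo - c0) / s))
}

#' Render single-pixel localization maps on the upsampled grid
#'
#' Each emitter sets exactly one pixel of the upsampled grid — the pixel
#' containing its position (`floor(coord / upsampled_pixel)`) — to its
#' photon value; coinciding emitters sum.
#'
#' @param table emitter table.
#' @param config an [acquisition_config()].
#' @return Array `c(fov * upsample, n_frames)` of sparse maps.
#' @export
render_location_maps <- function(table, config) {
  up <- config$upsample
  nr <- config$fov[1] * up; nc <- config$fov[2] * up
  upx <- config$pixel_size / up
  maps <- array(0, dim = c(nr, nc, config$n_frames))
  if (nrow(table) == 0) return(maps)
  ci <- pmin(pmax(floor(table$x / upx) + 1L, 1L), nc)
  ri <- pmin(pmax(floor(table$y / upx) + 1L, 1L), nr)
  fi <- table$frame + 1L
  for (k in seq_len(nrow(table)))
    maps[ri[k], ci[k], fi[k]] <- maps[ri[k], ci[k], fi[k]] + table$photons[k]
  maps
}

#' Simulate a full degraded acquisition on the camera grid
#'
#' Samples ground-truth events, renders expected-photon frames, applies
#' the sensor model and the configured compression. The 4x4 block grid of
#' the bespoke transform is randomly offset per stack so downstream
#' learners cannot memorize one grid alignment.
#'
#' @param config an [acquisition_config()].
#' @param seed master seed; all stage randomness derives from it.
#' @return List with `adu` (degraded camera-grid stack), `photons`
#'   (noise-free expected-photon stack) and `table` (ground truth).
#' @export
simulate_acquisition <- function(config, seed = 1L) {
  seeds <- derive_seeds(seed, 3 + config$n_frames)
  table <- sample_emitters(config, seed = seeds[1])
  photons <- render_frames(table, config)

  set.seed(seeds[2])
  grid_off <- sample(0:(config$compression$block_size - 1), 2, replace = TRUE)

  n <- config$n_frames
  adu_stack <- array(0, dim = c(config$fov, n))
  if (is.null(config$sensor)) {
    # ideal noiseless camera: expected photons, quantized
    adu_stack <- round(photons)
  } else {
    for (i in seq_len(n))
      adu_stack[, , i] <- simulate_sensor(photons[, , i], config$sensor,
                                          seed = seeds[3 + i])
  }
  if (config$compression$mode == "real_codec") {
    adu_stack <- encode_decode_video(adu_stack, config$compression)
  } else {
    bits <- if (is.null(config$sensor)) 16L else config$sensor$bit_depth
    for (i in seq_len(n))
      adu_stack[, , i] <- degrade_with_offset(
        adu_stack[, , i], config$compression, grid_off, bit_depth = bits)
  }
  list(adu = adu_stack, photons = photons, table = table)
}

#' Generate paired training data from the full forward model
#'
#' Runs [simulate_acquisition()] and pairs the degraded frames, upsampled
#' by nearest-neighbor to the map grid, with the ground-truth
#' localization maps from [render_location_maps()].
#'
#' @param config an [acquisition_config()].
#' @param seed master seed; all stage randomness derives from it.
#' @return Object of class `frame_pairs`: list with `x` (degraded
#'   upsampled frames), `y` (localization maps), both
#'   `c(fov * upsample, n_frames)` arrays, plus `table` (ground truth) and
#'   `config`.
#' @export
make_training_pairs <- function(config, seed = 1L) {
  acq <- simulate_acquisition(config, seed)
  maps <- render_location_maps(acq$table, config)
  n <- config$n_frames
  up <- config$upsample
  x <- array(0, dim = c(config$fov[1] * up, config$fov[2] * up, n))
  for (i in seq_len(n)) x[, , i] <- upsample_nearest(acq$adu[, , i], up)
  structure(list(x = x, y = maps, table = acq$table, config = config,
                 seed = seed),
            class = "frame_pairs")
}

# degrade with the block grid shifted by `off` = c(row, col) pixels,
# using replicate padding so output size equals input size
degrade_with_offset <- function(frame, compression, off, bit_depth) {
  if (all(off == 0))
    return(block_transform_degrade(frame, compression, bit_depth))
  nr <- nrow(frame); nc <- ncol(frame)
  padded <- frame[c(rep(1, off[1]), seq_len(nr)),
                  c(rep(1, off[2]), seq_len(nc)), drop = FALSE]
  deg <- block_transform_degrade(padded, compression, bit_depth)
  deg[off[1] + seq_len(nr), off[2] + seq_len(nc), drop = FALSE]
}

#' @export
print.frame_pairs <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<frame_pairs> %d pairs of %dx%d frames (%d ground-truth events)\n",
              d[3], d[1], d[2], nrow(x$table)))
  invisible(x)
}

#' Build training pairs from an existing stack and detections
#'
#' The second dataset-generation route: localization maps are rendered
#' from detections produced by any localizer on the (already degraded)
#' stack, and the stack itself is upsampled to the map grid. Pairing is
#' identical to [make_training_pairs()].
#'
#' @param stack camera-grid frame sequence.
#' @param detections emitter table of localized events on this stack.
#' @param config an [acquisition_config()] (fov/upsample must match).
#' @return A `frame_pairs` object.
#' @export
pairs_from_localizations <- function(stack, detections, config) {
  stack <- as_stack(stack)
  if (dim(stack)[1] != config$fov[1] || dim(stack)[2] != config$fov[2])
    stop("stack shape does not match config fov")
  n <- dim(stack)[3]
  if (n != config$n_frames) {
    config$n_frames <- n
  }
  if (nrow(detections) > 0 && any(detections$frame >= n))
    stop("detection frame indices exceed the stack length")
  maps <- render_location_maps(detections, config)
  up <- config$upsample
  x <- array(0, dim = c(config$fov[1] * up, config$fov[2] * up, n))
  for (i in seq_len(n)) x[, , i] <- upsample_nearest(stack[, , i], up)
  structure(list(x = x, y = maps, table = detections, config = config,
                 seed = NA_integer_),
            class = "frame_pairs")
}

#' Mix two training datasets in equal parts
#'
#' Interleaves pairs from two `frame_pairs` objects (e.g. the
#' simulation-based and the localization-based dataset) 50:50, truncating
#' to twice the shorter length.
#'
#' @param a,b `frame_pairs` objects on identical grids.
#' @return A `frame_pairs` object with alternating provenance.
#' @export
mix_training_pairs <- function(a, b) {
  if (!all(dim(a$x)[1:2] == dim(b$x)[1:2]))
    stop("datasets must share one frame grid")
  n <- min(dim(a$x)[3], dim(b$x)[3])
  idx <- seq_len(n)
  d <- dim(a$x)[1:2]
  x <- array(0, dim = c(d, 2 * n)); y <- array(0, dim = c(d, 2 * n))
  x[, , 2 * idx - 1] <- a$x[, , idx]; x[, , 2 * idx] <- b$x[, , idx]
  y[, , 2 * idx - 1] <- a$y[, , idx]; y[, , 2 * idx] <- b$y[, , idx]
  structure(list(x = x, y = y, table = NULL, config = a$config,
                 seed = NA_integer_),
            class = "frame_pairs")
}
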