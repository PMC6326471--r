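#' Sensor parameter set
#'
#' Describes a camera's photon-to-ADU transfer: gain (electrons per ADU),
#' dark offset (ADU), Gaussian read noise (electrons RMS), digitizer bit
#' depth, the upper bound of the linear mean-variance response and the
#' quantum efficiency. These are the quantities a photon-transfer-curve
#' calibration estimates, so [simulate_sensor()] and
#' [calibrate_mean_variance()] are inverse views of the same model.
#'
#' @param gain electrons per ADU, > 0.
#' @param offset dark level in ADU, >= 0.
#' @param read_noise read noise in electrons RMS, >= 0.
#' @param bit_depth digitizer bits; output is clipped to `[0, 2^bit_depth - 1]`.
#' @param linear_max upper bound of the linear response in ADU.
#' @param qe quantum efficiency in (0, 1].
#' @return An object of class `sensor_params`.
#' @examples
#' sensor_params(gain = 0.69, offset = 4.1, read_noise = 2.5)
#' @export
sensor_params <- function(gain, offset = 0, read_noise = 0,
                          bit_depth = 12L, linear_max = NULL, qe = 1) {
  if (is.null(linear_max)) linear_max <- 2^bit_depth - 1
  p <- structure(
    list(gain = as.numeric(gain), offset = as.numeric(offset),
         read_noise = as.numeric(read_noise), bit_depth = as.integer(bit_depth),
         linear_max = as.numeric(linear_max), qe = as.numeric(qe)),
    class = "sensor_params")
  validate_sensor_params(p)
}

validate_sensor_params <- function(p) {
  stopifnot(inherits(p, "sensor_params"))
  if (!is.finite(p$gain) || p$gain <= 0) stop("sensor gain must be > 0")
  if (p$offset < 0) stop("sensor offset must be >= 0")
  if (p$read_noise < 0) stop("read noise must be >= 0")
  if (p$qe <= 0 || p$qe > 1) stop("quantum efficiency must be in (0, 1]")
  if (p$linear_max <= 0 || p$linear_max > 2^p$bit_depth - 1)
    stop("linear_max must be in (0, 2^bit_depth - 1]")
  p
}

#' @export
print.sensor_params <- function(x, ...) {
  cat(sprintf(
    "<sensor_params> gain %.3g e-/ADU, offset %.3g ADU, read noise %.3g e- RMS,\n  %d bit, linear up to %.4g ADU, QE %.2f\n",
    x$gain, x$offset, x$read_noise, x$bit_depth, x$linear_max, x$qe))
  invisible(x)
}

#' Named sensor presets
#'
#' Presets are stored as plain YAML under `inst/extdata/sensor_presets.yaml`.
#' `"huawei_p9"` carries the values tied to the mean-variance
#' calibration procedure (gain 0.69 e-/ADU, offset 4.1 ADU, read noise
#' 2.5 e- RMS, linear up to 220 ADU); `"huawei_p9_alt_rn"` swaps in the
#' alternative 1.23 e- RMS read-noise figure; `"emccd_ixon"`
#' describes the scientific reference camera (gain and offset there are
#' synthetic typical values, see the YAML comments).
#'
#' @param name preset name; omit to list available presets.
#' @return A `sensor_params` object, or a character vector of names.
#' @export
sensor_preset <- function(name = NULL) {
  path <- system.file("extdata", "sensor_presets.yaml", package = "smlmgan",
                      mustWork = TRUE)
  presets <- yaml::read_yaml(path)
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown sensor preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  sensor_params(gain = p$gain, offset = p$offset, read_noise = p$read_noise,
                bit_depth = p$bit_depth, linear_max = p$linear_max, qe = p$qe)
}

#' Simulate the sensor: expected photons to ADU
#'
#' Applies the standard Poisson-Gaussian camera model: per pixel,
#' `electrons ~ Poisson(qe * photons) + Normal(0, read_noise)`, then
#' `ADU = round(electrons / gain + offset)` clipped to the digitizer range.
#' Below saturation this gives the photon-transfer relation
#' `var(ADU) = (mean(ADU) - offset) / gain + read_noise^2 / gain^2`.
#'
#' @param photon_image non-negative matrix of expected photons per pixel.
#' @param params a [sensor_params()] object.
#' @param seed integer seed; the output is deterministic given it.
#' @param clip_to_linear_max if `TRUE`, additionally saturate the output at
#'   `params$linear_max`, emulating a response that stops being linear at
#'   that level (used when studying saturation-breakpoint detection).
#' @return Integer-valued matrix of ADU, same shape as `photon_image`.
#' @export
simulate_sensor <- function(photon_image, params, seed = NULL,
                            clip_to_linear_max = FALSE) {
  if (!is.matrix(photon_image) && !(is.array(photon_image) && length(dim(photon_image)) == 2))
    stop("photon_image must be a 2-D matrix")
  if (any(!is.finite(photon_image)))
    stop("photon_image contains non-finite values")
  if (any(photon_image < 0))
    stop("photon_image contains negative photon values; expected photon counts must be >= 0")
  validate_sensor_params(params)
  if (!is.null(seed)) set.seed(seed)
  n <- length(photon_image)
  electrons <- stats::rpois(n, params$qe * as.vector(photon_image))
  if (params$read_noise > 0)
    electrons <- electrons + stats::rnorm(n, 0, params$read_noise)
  adu <- round(electrons / params$gain + params$offset)
  top <- if (clip_to_linear_max) params$linear_max else 2^params$bit_depth - 1
  adu <- pmin(pmax(adu, 0), top)
  matrix(adu, nrow = nrow(photon_image), ncol = ncol(photon_image))
}

#' Photon-transfer-curve calibration from repeated frames
#'
#' Computes per-pixel temporal mean and variance from a set of frames of a
#' static scene, bins pixels by mean, fits the variance-vs-mean line
#' robustly over the linear range and inverts the sensor model:
#' `gain = 1/slope`; the darkest bin's variance estimates the zero-photon
#' variance `read_noise^2 / gain^2`, giving the read noise directly and,
#' through the fitted line (`offset = gain * (v_dark - intercept)`), the
#' offset. The end of the
#' linear range is detected as the first mean bin whose variance departs
#' from the fitted line by more than `breakpoint_tol` (relative).
#'
#' The scene must contain an intensity spread and should include a
#' near-dark region, otherwise the offset (and hence the read noise)
#' cannot be separated from the slope/intercept pair.
#'
#' @param frames list of same-shape ADU matrices (>= 2), or a 3-D array
#'   with frames along the third dimension.
#' @param saturation_guard `"auto"` (detect the linear-range end from the
#'   data) or an ADU value above which points are excluded from the fit.
#' @param n_bins number of mean bins.
#' @param breakpoint_tol relative deviation from the fitted line that marks
#'   the end of the linear range.
#' @return An object of class `calibration_result` with `gain_est`,
#'   `offset_est`, `read_noise_est`, `linear_max_est` and `fit_points`
#'   (a data frame of binned mean/variance pairs with a `used` flag).
#' @export
calibrate_mean_variance <- function(frames, saturation_guard = "auto",
                                    n_bins = 60L, breakpoint_tol = 0.2) {
  stack <- as_stack(frames)
  n_frames <- dim(stack)[3]
  if (n_frames < 2) stop("need at least 2 frames for mean-variance calibration")
  px_mean <- apply(stack, c(1, 2), mean)
  px_var <- apply(stack, c(1, 2), stats::var)
  if (all(px_var == 0))
    stop("calibration undefined: zero temporal variance everywhere (noiseless input)")

  m <- as.vector(px_mean); v <- as.vector(px_var)
  brks <- seq(min(m), max(m), length.out = n_bins + 1)
  bin <- cut(m, brks, include.lowest = TRUE, labels = FALSE)
  bm <- tapply(m, bin, mean)
  bv <- tapply(v, bin, mean)
  bn <- tapply(v, bin, length)
  keep <- bn >= 5
  bm <- bm[keep]; bv <- bv[keep]
  if (length(bm) < 3) stop("too few usable mean bins; scene needs an intensity spread")
  ord <- order(bm); bm <- bm[ord]; bv <- bv[ord]

  guard <- if (identical(saturation_guard, "auto")) Inf else as.numeric(saturation_guard)

  # initial fit on the lower half of the usable range, then iterate:
  # robust refit (drop > 3 sigma residuals), re-detect the breakpoint,
  # restrict to bins below it.
  in_range <- bm <= guard
  fit_idx <- which(in_range & bm <= stats::quantile(bm[in_range], 0.5))
  if (length(fit_idx) < 3) fit_idx <- which(in_range)
  linear_max_est <- max(bm[in_range])
  for (iter in 1:8) {
    fit <- robust_line_fit(bm[fit_idx], bv[fit_idx])
    pred <- fit$intercept + fit$slope * bm
    dev_rel <- abs(bv - pred) / pmax(abs(pred), .Machine$double.eps)
    # saturation shows as a PERSISTENT departure at the bright end;
    # isolated blips (e.g. zero-clipped dark bins) are not breakpoints
    over <- dev_rel > breakpoint_tol & seq_along(bm) > min(fit_idx)
    nb <- length(bm)
    persistent <- vapply(seq_len(nb), function(i)
      over[i] && mean(over[i:nb]) >= 0.8, logical(1))
    bp <- if (any(persistent)) min(which(persistent)) else NA_integer_
    new_max <- if (is.na(bp)) max(bm[in_range]) else bm[bp]
    new_idx <- which(in_range & bm < new_max & dev_rel <= breakpoint_tol)
    if (length(new_idx) < 3) new_idx <- fit_idx
    if (identical(new_idx, fit_idx) && isTRUE(all.equal(new_max, linear_max_est))) {
      linear_max_est <- new_max
      break
    }
    fit_idx <- new_idx
    linear_max_est <- new_max
  }
  if (fit$slope <= 0)
    stop("calibration undefined: non-positive mean-variance slope")

  gain_est <- 1 / fit$slope
  # offset and read noise from the zero-photon (darkest) pixels. Their raw
  # ADU distribution is a normal clipped at 0, so the naive moments are
  # biased whenever offset is within a few read-noise widths of 0;
  # inverting the censored-normal moment equations removes that bias.
  # grow the dark-pixel set from the darkest bin to the whole dark
  # cluster, otherwise selecting by (noisy) temporal mean keeps only the
  # cluster's lower tail and biases the moments
  dark_px <- which(bin == as.integer(names(bm)[1]))
  for (it in 1:4) {
    cutoff <- stats::median(m[dark_px]) + 3 * stats::sd(m[dark_px])
    new_px <- which(m <= cutoff)
    if (length(new_px) <= length(dark_px)) break
    dark_px <- new_px
  }
  dark_vals <- as.vector(apply(stack, 3, function(f) as.vector(f)[dark_px]))
  cn <- censored_normal_fit(mean(dark_vals), stats::var(dark_vals))
  offset_est <- cn$mean
  read_noise_est <- gain_est * cn$sd

  # When the departure is a variance DROP (saturation clipping), the 20%
  # deviation is detected while the mean is still below the clip level:
  # for a Gaussian clipped at c, the variance has fallen to 80% when the
  # mean sits 1.151 sigma below c. Correct the breakpoint upward by that
  # amount; upward departures (nonlinear gain rise) are left uncorrected.
  if (!is.na(bp) && bv[bp] < fit$intercept + fit$slope * bm[bp]) {
    sd_bp <- sqrt(max(fit$intercept + fit$slope * bm[bp], 0))
    linear_max_est <- linear_max_est + 1.151 * sd_bp
  }
  linear_max_est <- max(linear_max_est, max(bm[fit_idx]))

  structure(list(
    gain_est = gain_est,
    offset_est = offset_est,
    read_noise_est = read_noise_est,
    linear_max_est = linear_max_est,
    slope = fit$slope, intercept = fit$intercept,
    fit_points = data.frame(mean = bm, variance = bv,
                            used = seq_along(bm) %in% fit_idx)),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> gain %.4g e-/ADU, offset %.4g ADU, read noise %.4g e- RMS\n  linear up to %.4g ADU (%d/%d mean bins in fit)\n",
    x$gain_est, x$offset_est, x$read_noise_est, x$linear_max_est,
    sum(x$fit_points$used), nrow(x$fit_points)))
  invisible(x)
}

# invert the moments of X = max(N(m, s^2), 0) observed as (mu, v) to
# recover (m, s). With a = m/s:
#   E[X]/s  = f1(a) = a*pnorm(a) + dnorm(a)
#   Var[X]/s^2 = f2(a) = (a^2+1)*pnorm(a) + a*dnorm(a) - f1(a)^2
# and mu^2/v = f1^2/f2 is monotone in a, so a is found by root-finding.
censored_normal_fit <- function(mu, v) {
  if (v <= 0 || mu < 0) return(list(mean = max(mu, 0), sd = 0))
  f1 <- function(a) a * stats::pnorm(a) + stats::dnorm(a)
  f2 <- function(a) (a^2 + 1) * stats::pnorm(a) + a * stats::dnorm(a) - f1(a)^2
  ratio <- function(a) f1(a)^2 / f2(a) - mu^2 / v
  # a >= ~6: clipping negligible, moments are the plain normal's
  if (ratio(6) <= 0) return(list(mean = mu, sd = sqrt(v)))
  root <- tryCatch(stats::uniroot(ratio, c(-6, 6))$root,
                   error = function(e) NA_real_)
  if (is.na(root)) return(list(mean = mu, sd = sqrt(v)))
  s <- mu / f1(root)
  list(mean = root * s, sd = s)
}

# iterative least squares, discarding points with residuals > 3 sigma
robust_line_fit <- function(x, y, max_iter = 10L) {
  use <- rep(TRUE, length(x))
  for (i in seq_len(max_iter)) {
    fit <- stats::lm.fit(cbind(1, x[use]), y[use])
    res_all <- y - (fit$coefficients[1] + fit$coefficients[2] * x)
    s <- stats::sd(res_all[use])
    if (!is.finite(s) || s == 0) break
    new_use <- abs(res_all) <= 3 * s
    if (sum(new_use) < 3 || identical(new_use, use)) break
    use <- new_use
  }
  list(intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]), used = use)
}

#' Temporal statistics of a dark series
#'
#' Reduces a dark-frame stack to its per-frame spatial mean trace and
#' characterizes two compression/thermal signatures: a slow linear drift
#' (least-squares slope in ADU/frame) and a periodic dip, found as the
#' dominant peak of the autocorrelation of the detrended trace. A period
#' is only reported when the peak exceeds `peak_factor` times the MAD of
#' the off-peak autocorrelation values; otherwise the series is considered
#' aperiodic.
#'
#' @param stack dark-frame sequence (list of matrices or 3-D array), >= 64
#'   frames.
#' @param fps acquisition frame rate in frames per second.
#' @param peak_factor significance multiple on the off-peak MAD.
#' @return An object of class `dark_series_stats` with `mean_trace`,
#'   `drift_slope` (ADU/frame), `dip_period_frames` and
#'   `dip_period_seconds` (both `NA` when no significant period exists).
#' @export
analyze_dark_series <- function(stack, fps, peak_factor = 5) {
  stack <- as_stack(stack)
  n <- dim(stack)[3]
  if (n < 64) stop("need at least 64 frames for dark-series period estimation")
  if (fps <= 0) stop("fps must be > 0")
  trace <- apply(stack, 3, mean)
  t_idx <- seq_len(n) - 1
  co <- stats::lm.fit(cbind(1, t_idx), trace)$coefficients
  drift_slope <- unname(co[2])
  detrended <- trace - (co[1] + co[2] * t_idx)

  dip_frames <- NA_integer_
  if (stats::sd(detrended) > 0) {
    lag_max <- floor(n / 2)
    ac <- stats::acf(detrended, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
    lags <- seq_along(ac) - 1          # ac[1] is lag 0
    cand <- which(lags >= 2)
    # local maxima only, so harmonics of slow structure do not win
    is_peak <- vapply(cand, function(i) {
      ac[i] >= ac[max(i - 1, 1)] && ac[i] >= ac[min(i + 1, length(ac))]
    }, logical(1))
    cand <- cand[is_peak]
    if (length(cand)) {
      best <- cand[which.max(ac[cand])]
      period <- lags[best]
      off <- ac[lags >= 2 & abs(lags %% period) > 1 &
                  abs(lags %% period - period) > 1]
      thr <- peak_factor * stats::mad(off, center = 0)
      if (length(off) >= 5 && is.finite(thr) && ac[best] > thr)
        dip_frames <- as.integer(period)
    }
  }

  structure(list(
    mean_trace = trace,
    drift_slope = drift_slope,
    dip_period_frames = dip_frames,
    dip_period_seconds = if (is.na(dip_frames)) NA_real_ else dip_frames / fps,
    fps = fps), class = "dark_series_stats")
}

#' @export
print.dark_series_stats <- function(x, ...) {
  cat(sprintf("<dark_series_stats> %d frames at %g fps, drift %.4g ADU/frame\n",
              length(x$mean_trace), x$fps, x$drift_slope))
  if (is.na(x$dip_period_frames)) {
    cat("  no significant periodic dip\n")
  } else {
    cat(sprintf("  periodic dip every %d frames = %.3g s\n",
                x$dip_period_frames, x$dip_period_seconds))
  }
  invisible(x)
}
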