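#' Detection configuration for the classical localizer
#'
#' A surrogate for established SMLM localization software: a
#' difference-of-Gaussians band-pass, a peak threshold expressed in
#' multiples of the filtered frame's standard deviation (the
#' `k * std(frame)` rule commonly used to suppress compression-artifact
#' false positives), and a windowed least-squares Gaussian fit.
#'
#' @param filter_sigma difference-of-Gaussians scale in pixels; the second
#'   Gaussian uses `1.6 * filter_sigma`.
#' @param peak_threshold_k threshold in multiples of the filtered frame's
#'   standard deviation.
#' @param fit_window fit window edge in pixels, odd and >= 5.
#' @param max_iterations Levenberg-Marquardt iteration cap.
#' @param sigma_bounds accepted fitted PSF sigma range in nm; fits outside
#'   are dropped.
#' @return Object of class `detection_config`.
#' @export
detection_config <- function(filter_sigma = 1.3, peak_threshold_k = 3,
                             fit_window = 7L, max_iterations = 50L,
                             sigma_bounds = c(50, 400)) {
  fit_window <- as.integer(fit_window)
  if (fit_window %% 2 == 0 || fit_window < 5)
    stop("fit_window must be odd and >= 5")
  if (peak_threshold_k <= 0) stop("peak_threshold_k must be > 0")
  structure(list(filter_sigma = filter_sigma,
                 peak_threshold_k = peak_threshold_k,
                 fit_window = fit_window,
                 max_iterations = as.integer(max_iterations),
                 sigma_bounds = sigma_bounds),
            class = "detection_config")
}

# separable Gaussian blur with replicate edge padding
gaussian_blur <- function(mat, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {
    nr <- nrow(m)
    mp <- m[c(rep(1, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
    out <- matrix(0, nr, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[(j - 1) + seq_len(nr), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(mat))))
}

#' Detect candidate peaks in a frame
#'
#' Difference-of-Gaussians filtering followed by 8-neighborhood local
#' maximum detection with a `k * std(filtered frame)` threshold.
#' Detections closer than 2 pixels are merged, keeping the brighter one.
#'
#' @param frame 2-D matrix.
#' @param config a [detection_config()].
#' @return Integer matrix with columns `row`, `col` (1-based pixel
#'   indices), zero rows when nothing is found.
#' @export
detect_peaks <- function(frame, config = detection_config()) {
  if (any(!is.finite(frame))) stop("frame must be finite")
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (stats::sd(frame) == 0) return(empty)
  f <- gaussian_blur(frame, config$filter_sigma) -
    gaussian_blur(frame, 1.6 * config$filter_sigma)
  thr <- config$peak_threshold_k * stats::sd(f)
  nr <- nrow(f); nc <- ncol(f)
  is_max <- f > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- f[pmin(pmax(seq_len(nr) + dr, 1), nr),
                 pmin(pmax(seq_len(nc) + dc, 1), nc), drop = FALSE]
    is_max <- is_max & (f >= shifted)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  vals <- f[idx]
  ord <- order(vals, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      later <- (i + 1):nrow(idx)
      d2 <- (idx[later, 1] - idx[i, 1])^2 + (idx[later, 2] - idx[i, 2])^2
      keep[later][d2 <= 4] <- FALSE
    }
  }
  out <- idx[keep, , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

#' Fit an isotropic Gaussian around a detected peak
#'
#' Least-squares fit of a pixel-integrated isotropic 2-D Gaussian plus
#' constant background over the fit window (Levenberg-Marquardt).
#' Non-converged fits and fits with sigma outside the configured bounds
#' are reported as failed.
#'
#' @param frame 2-D matrix.
#' @param peak `c(row, col)` 1-based pixel indices of the candidate.
#' @param config a [detection_config()].
#' @param pixel_size camera pixel size in nm.
#' @return List with `ok` (logical), and on success `x`, `y`, `sigma`
#'   (nm), `photons` (integrated amplitude in frame units) and
#'   `background`.
#' @export
fit_gaussian <- function(frame, peak, config = detection_config(),
                         pixel_size = 100) {
  h <- (config$fit_window - 1L) %/% 2L
  r0 <- peak[1] - h; r1 <- peak[1] + h
  c0 <- peak[2] - h; c1 <- peak[2] + h
  if (r0 < 1 || c0 < 1 || r1 > nrow(frame) || c1 > ncol(frame))
    return(list(ok = FALSE, reason = "window outside frame"))
  win <- frame[r0:r1, c0:c1]
  if (stats::sd(win) == 0) return(list(ok = FALSE, reason = "flat window"))

  rows <- r0:r1; cols <- c0:c1
  bg0 <- min(win)
  amp0 <- sum(win - bg0)
  # parameters: x0, y0 (nm), log sigma (nm), total photons, background
  start <- c(x = (peak[2] - 0.5) * pixel_size,
             y = (peak[1] - 0.5) * pixel_size,
             lsig = log(max(config$filter_sigma * pixel_size, 60)),
             N = max(amp0, 1), b = bg0)
  model <- function(p) {
    fx <- gauss_pixel_frac(cols, p[1], pixel_size, exp(p[3]))
    fy <- gauss_pixel_frac(rows, p[2], pixel_size, exp(p[3]))
    p[4] * (fy %o% fx) + p[5]
  }
  # non-convergence is an expected, handled outcome (the fit is dropped),
  # so the solver's iteration-limit warning is silenced
  res <- try(suppressWarnings(minpack.lm::nls.lm(
    par = start,
    fn = function(p) as.vector(model(p) - win),
    control = minpack.lm::nls.lm.control(maxiter = config$max_iterations))),
    silent = TRUE)
  if (inherits(res, "try-error")) return(list(ok = FALSE, reason = "fit error"))
  p <- unlist(res$par, use.names = FALSE)  # x0, y0, log sigma, N, background
  sigma <- exp(p[3])
  converged <- res$info %in% 1:4
  if (!converged) return(list(ok = FALSE, reason = "not converged"))
  if (!is.finite(sigma) || sigma < config$sigma_bounds[1] ||
      sigma > config$sigma_bounds[2])
    return(list(ok = FALSE, reason = "sigma out of bounds"))
  if (p[4] <= 0) return(list(ok = FALSE, reason = "non-positive amplitude"))
  list(ok = TRUE, x = p[1], y = p[2], sigma = sigma,
       photons = p[4], background = p[5])
}

#' Localize every frame of a stack with the classical pipeline
#'
#' Runs [detect_peaks()] and [fit_gaussian()] per frame and collects
#' accepted fits into an emitter table sorted by frame.
#'
#' @param stack frame sequence.
#' @param config a [detection_config()].
#' @param pixel_size camera pixel size in nm.
#' @return Emitter table `data.frame(id, frame, x, y, photons, sigma,
#'   background)` with `frame` 0-based and coordinates in nm.
#' @export
localize_stack <- function(stack, config = detection_config(),
                           pixel_size = 100) {
  stack <- as_stack(stack)
  n <- dim(stack)[3]
  rows <- list()
  for (i in seq_len(n)) {
    frame <- stack[, , i]
    peaks <- detect_peaks(frame, config)
    for (k in seq_len(nrow(peaks))) {
      fit <- fit_gaussian(frame, peaks[k, ], config, pixel_size)
      if (isTRUE(fit$ok))
        rows[[length(rows) + 1]] <- data.frame(
          frame = i - 1L, x = fit$x, y = fit$y, photons = fit$photons,
          sigma = fit$sigma, background = fit$background)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
               photons = numeric(0), sigma = numeric(0),
               background = numeric(0))
  tab <- tab[order(tab$frame), , drop = FALSE]
  tab <- cbind(id = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  class(tab) <- c("emitter_table", "data.frame")
  tab
}
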