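#' Match detections against ground truth within a radius
#'
#' Per frame, candidate pairs are formed between detections and
#' ground-truth events at Euclidean distance up to `radius` and accepted
#' greedily in ascending distance order, each event matched at most once.
#' The pooled result aggregates all frames; the mean distance is taken
#' over matched pairs only.
#'
#' @param detections,gt emitter tables sharing one frame index space.
#' @param radius match radius in nm (e.g. 200).
#' @return Object of class `match_result`: list with pooled counts
#'   (`n_gt`, `n_detected`, `n_matched`, `mean_distance`, `radius`,
#'   `matched_fraction`) and a `per_frame` data frame.
#' @export
match_events <- function(detections, gt, radius = 200) {
  if (radius < 0) stop("radius must be >= 0")
  frames <- sort(unique(c(detections$frame, gt$frame)))
  per <- lapply(frames, function(f) {
    d <- detections[detections$frame == f, , drop = FALSE]
    g <- gt[gt$frame == f, , drop = FALSE]
    m <- greedy_match_frame(d$x, d$y, g$x, g$y, radius)
    data.frame(frame = f, n_gt = nrow(g), n_detected = nrow(d),
               n_matched = m$n, sum_distance = m$sum_dist)
  })
  per <- do.call(rbind, per)
  if (is.null(per))
    per <- data.frame(frame = integer(0), n_gt = integer(0),
                      n_detected = integer(0), n_matched = integer(0),
                      sum_distance = numeric(0))
  n_matched <- sum(per$n_matched)
  structure(list(
    n_gt = sum(per$n_gt), n_detected = sum(per$n_detected),
    n_matched = n_matched,
    mean_distance = if (n_matched > 0) sum(per$sum_distance) / n_matched
      else NA_real_,
    matched_fraction = if (sum(per$n_gt) > 0) n_matched / sum(per$n_gt)
      else NA_real_,
    radius = radius, per_frame = per), class = "match_result")
}

greedy_match_frame <- function(dx, dy, gx, gy, radius) {
  nd <- length(dx); ng <- length(gx)
  if (nd == 0 || ng == 0) return(list(n = 0L, sum_dist = 0))
  dist <- sqrt(outer(dx, gx, "-")^2 + outer(dy, gy, "-")^2)
  cand <- which(dist <= radius, arr.ind = TRUE)
  if (nrow(cand) == 0) return(list(n = 0L, sum_dist = 0))
  ord <- order(dist[cand])
  cand <- cand[ord, , drop = FALSE]
  used_d <- logical(nd); used_g <- logical(ng)
  n <- 0L; s <- 0
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_d[i] || used_g[j]) next
    used_d[i] <- TRUE; used_g[j] <- TRUE
    n <- n + 1L; s <- s + dist[i, j]
  }
  list(n = n, sum_dist = s)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d/%d GT matched (%.1f%%) of %d detections within %g nm\n",
    x$n_matched, x$n_gt, 100 * x$matched_fraction, x$n_detected, x$radius))
  if (!is.na(x$mean_distance))
    cat(sprintf("  mean matched distance %.1f nm\n", x$mean_distance))
  invisible(x)
}

#' Accuracy sweep over photon counts and compression qualities
#'
#' For every (photons, quality) cell a fresh stack is simulated, each
#' localizer is run on the degraded camera frames, and its detections are
#' matched against the ground truth — the machine-readable version of a
#' photon/compression localization benchmark.
#'
#' @param localizers named list of functions `f(stack, pixel_size)`
#'   returning an emitter table.
#' @param photon_levels photon counts per emitter to sweep (fixed mode).
#' @param qualities compression quality percentages to sweep.
#' @param config base [acquisition_config()]; photons and quality are
#'   overridden per cell.
#' @param seed one seed reused per cell so cells differ only in the swept
#'   parameters; identical seeds give identical grids.
#' @param radius match radius in nm.
#' @return Data frame with one row per (photons, quality, localizer).
#' @export
sweep_accuracy <- function(localizers, photon_levels = c(50, 100, 500, 1000),
                           qualities = c(70, 80, 90, 100), config, seed = 1L,
                           radius = 200) {
  stopifnot(is.list(localizers), length(names(localizers)) == length(localizers))
  rows <- list()
  for (ph in photon_levels) for (qu in qualities) {
    cfg <- config
    cfg$photons_per_emitter <- ph
    cfg$photon_mode <- "fixed"
    cfg$compression$quality <- qu
    acq <- simulate_acquisition(cfg, seed)
    for (nm in names(localizers)) {
      det <- localizers[[nm]](acq$adu, cfg$pixel_size)
      mr <- match_events(det, acq$table, radius)
      rows[[length(rows) + 1]] <- data.frame(
        photons = ph, quality = qu, localizer = nm,
        n_gt = mr$n_gt, n_detected = mr$n_detected, n_matched = mr$n_matched,
        matched_fraction = mr$matched_fraction,
        mean_distance_nm = mr$mean_distance)
    }
  }
  do.call(rbind, rows)
}

#' Per-frame detected-event density trace
#'
#' @param table emitter table.
#' @param fov_area field of view area in square microns.
#' @param n_frames total number of frames (frames without events count 0).
#' @return Numeric vector: events per square micron per frame.
#' @export
events_per_area <- function(table, fov_area, n_frames) {
  if (fov_area <= 0) stop("fov_area must be > 0")
  counts <- tabulate(table$frame + 1L, nbins = n_frames)
  counts / fov_area
}

#' Render a super-resolved image from a localization table
#'
#' @param table emitter table with `x`, `y` in nm.
#' @param pixel_size rendering pixel size in nm.
#' @param mode `"histogram"` (counts per bin) or `"gaussian"` (histogram
#'   blurred per-event by `blur_sigma` nm).
#' @param fov_nm image extent `c(height, width)` in nm; inferred from the
#'   table when omitted.
#' @param blur_sigma Gaussian rendering sigma in nm (gaussian mode).
#' @return 2-D image matrix.
#' @export
render_reconstruction <- function(table, pixel_size = 20,
                                  mode = c("histogram", "gaussian"),
                                  fov_nm = NULL, blur_sigma = 20) {
  mode <- match.arg(mode)
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (is.null(fov_nm)) {
    if (nrow(table) == 0) stop("cannot infer image extent from an empty table")
    fov_nm <- c(max(table$y), max(table$x)) + pixel_size
  }
  nr <- ceiling(fov_nm[1] / pixel_size)
  nc <- ceiling(fov_nm[2] / pixel_size)
  img <- matrix(0, nr, nc)
  if (nrow(table) > 0) {
    ri <- pmin(pmax(floor(table$y / pixel_size) + 1L, 1L), nr)
    ci <- pmin(pmax(floor(table$x / pixel_size) + 1L, 1L), nc)
    for (k in seq_along(ri)) img[ri[k], ci[k]] <- img[ri[k], ci[k]] + 1
  }
  if (mode == "gaussian") img <- gaussian_blur(img, blur_sigma / pixel_size)
  img
}

#' Fourier ring correlation between two images
#'
#' Ring-wise normalized cross-correlation of the two images' Fourier
#' transforms. The resolution is reported as `1 / frequency` at the first
#' crossing below `threshold` (linear interpolation between rings; the
#' standard fixed threshold is 1/7), or `NA` when the curve never drops
#' below it.
#'
#' @param image_a,image_b same-shape square images (e.g. reconstructions
#'   of the odd/even frame halves of one dataset).
#' @param pixel_size image pixel size in nm.
#' @param threshold correlation threshold, default 1/7.
#' @return Object of class `frc_curve` with `spatial_frequencies`
#'   (1/nm ring centers), `correlations`, `resolution` (nm or `NA`) and
#'   `threshold`.
#' @export
frc <- function(image_a, image_b, pixel_size, threshold = 1 / 7) {
  if (!all(dim(image_a) == dim(image_b))) stop("images must share one shape")
  if (nrow(image_a) != ncol(image_a)) stop("FRC expects square images")
  if (stats::sd(image_a) == 0 || stats::sd(image_b) == 0)
    stop("correlation undefined for constant images")
  n <- nrow(image_a)
  fa <- stats::fft(image_a - mean(image_a))
  fb <- stats::fft(image_b - mean(image_b))
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  kr <- round(sqrt(outer(k^2, k^2, "+")))
  qmax <- n %/% 2
  num <- rep(0, qmax); da <- rep(0, qmax); db <- rep(0, qmax)
  sel <- kr >= 1 & kr <= qmax
  ring <- kr[sel]
  num <- as.vector(tapply(Re(fa * Conj(fb))[sel], ring, sum))
  da <- as.vector(tapply(abs(fa[sel])^2, ring, sum))
  db <- as.vector(tapply(abs(fb[sel])^2, ring, sum))
  corr <- num / sqrt(da * db)
  freq <- (seq_len(qmax)) / (n * pixel_size)

  resolution <- NA_real_
  below <- which(corr < threshold)
  if (length(below)) {
    i <- below[1]
    if (i == 1) {
      resolution <- 1 / freq[1]
    } else {
      f0 <- freq[i - 1]; f1 <- freq[i]
      c0 <- corr[i - 1]; c1 <- corr[i]
      fc <- f0 + (c0 - threshold) / (c0 - c1) * (f1 - f0)
      resolution <- 1 / fc
    }
  }
  structure(list(spatial_frequencies = freq, correlations = corr,
                 resolution = resolution, threshold = threshold,
                 pixel_size = pixel_size), class = "frc_curve")
}

#' @export
print.frc_curve <- function(x, ...) {
  cat(sprintf("<frc_curve> %d rings, threshold %.3f, resolution %s\n",
              length(x$correlations), x$threshold,
              if (is.na(x$resolution)) "not reached"
              else sprintf("%.1f nm", x$resolution)))
  invisible(x)
}
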