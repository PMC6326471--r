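# Ground-truth matching, density traces, reconstruction and FRC.

# independent greedy matcher used as the oracle: enumerates ALL pairs,
# sorts by distance, then walks the list accepting free pairs
oracle_greedy <- function(det, gt, radius) {
  pairs <- expand.grid(i = seq_len(nrow(det)), j = seq_len(nrow(gt)))
  if (nrow(pairs) == 0) return(list(n = 0L, dsum = 0))
  pairs$d <- sqrt((det$x[pairs$i] - gt$x[pairs$j])^2 +
                    (det$y[pairs$i] - gt$y[pairs$j])^2)
  pairs <- pairs[pairs$d <= radius, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  ui <- uj <- integer(0); n <- 0L; dsum <- 0
  for (k in seq_len(nrow(pairs))) {
    if (pairs$i[k] %in% ui || pairs$j[k] %in% uj) next
    ui <- c(ui, pairs$i[k]); uj <- c(uj, pairs$j[k])
    n <- n + 1L; dsum <- dsum + pairs$d[k]
  }
  list(n = n, dsum = dsum)
}

rand_table <- function(n, seed, frame = 0L, ext = 2000) {
  set.seed(seed)
  data.frame(id = seq_len(n), frame = rep_len(frame, n),
             x = runif(n, 0, ext), y = runif(n, 0, ext),
             photons = rep_len(1000, n))
}

test_that("identical tables match perfectly, far tables not at all", {
  gt <- rand_table(8, 1)
  mr <- match_events(gt, gt, radius = 200)
  expect_equal(mr$n_matched, 8)
  expect_equal(mr$mean_distance, 0)
  expect_equal(mr$matched_fraction, 1)

  shifted <- gt; shifted$x <- shifted$x + 300
  mr2 <- match_events(shifted, gt, radius = 200)
  expect_equal(mr2$n_matched, 0)
  expect_true(is.na(mr2$mean_distance))
  expect_error(match_events(gt, gt, radius = -1), "radius")
})

test_that("matching equals the exhaustive greedy oracle on small instances", {
  for (s in 1:20) {
    nd <- sample(0:6, 1); ng <- sample(0:6, 1)
    det <- rand_table(nd, 100 + s, ext = 600)
    gt <- rand_table(ng, 200 + s, ext = 600)
    mr <- match_events(det, gt, radius = 250)
    or <- oracle_greedy(det, gt, 250)
    expect_equal(mr$n_matched, or$n)
    if (or$n > 0) expect_equal(mr$mean_distance, or$dsum / or$n)
    expect_lte(mr$n_matched, min(nd, ng))
    if (!is.na(mr$mean_distance)) expect_lte(mr$mean_distance, 250)
  }
})

test_that("matching is symmetric in detections and ground truth", {
  for (s in 1:5) {
    a <- rand_table(7, 300 + s, ext = 800)
    b <- rand_table(5, 400 + s, ext = 800)
    expect_equal(match_events(a, b, 250)$n_matched,
                 match_events(b, a, 250)$n_matched)
  }
})

test_that("matching respects frame boundaries", {
  a <- rand_table(4, 11, frame = 0L)
  b <- a; b$frame <- 1L
  expect_equal(match_events(a, b, 500)$n_matched, 0)
})

test_that("events_per_area computes the density trace", {
  expect_equal(events_per_area(rand_table(0, 1), 100, 5), rep(0, 5))
  tab <- data.frame(frame = rep(0L, 600), x = 0, y = 0)
  expect_equal(events_per_area(tab, 100, 3), c(6, 0, 0))
  cfg <- acquisition_config(fov = 100L, density = 6, n_frames = 2000L)
  gt <- sample_emitters(cfg, seed = 3)
  trace <- events_per_area(gt, 100, 2000)
  expect_lt(abs(mean(trace) - 6) / 6, 0.02)
  expect_error(events_per_area(tab, 0, 3), "fov_area")
})

test_that("histogram reconstruction conserves counts", {
  tab <- rand_table(50, 5, ext = 1900)
  img <- render_reconstruction(tab, pixel_size = 20, fov_nm = c(2000, 2000))
  expect_equal(sum(img), 50)
  one <- render_reconstruction(rand_table(1, 6, ext = 1500), pixel_size = 20,
                               fov_nm = c(2000, 2000))
  expect_equal(sum(one > 0), 1)
  # gaussian mode conserves mass too (blur kernel normalized)
  img2 <- render_reconstruction(tab, pixel_size = 20, mode = "gaussian",
                                fov_nm = c(2000, 2000), blur_sigma = 30)
  expect_equal(sum(img2), 50, tolerance = 0.02)
})

test_that("FRC of identical images is one everywhere with no crossing", {
  set.seed(31)
  img <- matrix(rnorm(64 * 64), 64, 64)
  curve <- frc(img, img, pixel_size = 20)
  expect_true(all(abs(curve$correlations - 1) < 1e-8))
  expect_true(is.na(curve$resolution))
  expect_true(all(diff(curve$spatial_frequencies) > 0))
  expect_error(frc(img, matrix(1, 64, 64), 20), "constant")
  expect_error(frc(img, img[1:32, 1:32], 20), "shape")
})

test_that("independent noise decorrelates beyond the first rings", {
  set.seed(32)
  a <- matrix(rnorm(128 * 128), 128, 128)
  b <- matrix(rnorm(128 * 128), 128, 128)
  curve <- frc(a, b, pixel_size = 20)
  expect_lt(abs(mean(curve$correlations[-1])), 0.05)
  expect_false(is.na(curve$resolution))
  # resolution reported in the first-ring region (all rings are noise)
  expect_gt(curve$resolution, 1 / curve$spatial_frequencies[10])
})

test_that("FRC is invariant to relabeling the two half-datasets", {
  set.seed(33)
  base <- render_reconstruction(rand_table(4000, 8, ext = 1900),
                                pixel_size = 20, fov_nm = c(1280, 1280))
  a <- matrix(rpois(length(base), base * 2 + 0.2), nrow(base))
  b <- matrix(rpois(length(base), base * 2 + 0.2), nrow(base))
  cab <- frc(a, b, 20); cba <- frc(b, a, 20)
  expect_equal(cab$correlations, cba$correlations)
  expect_equal(cab$resolution, cba$resolution)
  # split renderings of one dataset correlate at low frequency
  expect_gt(mean(cab$correlations[1:4]), 1 / 7)
})

test_that("FRC crossing tracks the analytic band limit of a blurred phantom", {
  # Poisson pairs of a common Gaussian-blurred phantom: the expected FRC is
  # S(f) / (S(f) + N) with S the ring-averaged power spectrum of the clean
  # image and N the flat Poisson noise power; solve that curve for the 1/7
  # crossing and compare with the measured crossing
  set.seed(34)
  n <- 128; px <- 20
  pts <- rand_table(3000, 9, ext = n * px - 100)
  clean <- render_reconstruction(pts, pixel_size = px,
                                 fov_nm = c(n * px, n * px))
  sigma_px <- 3
  clean <- smlmgan:::gaussian_blur(clean, sigma_px) * 5
  a <- matrix(rpois(n * n, clean), n)
  b <- matrix(rpois(n * n, clean), n)
  curve <- frc(a, b, px)

  fa <- fft(clean - mean(clean))
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  kr <- round(sqrt(outer(k^2, k^2, "+")))
  qmax <- n %/% 2
  sel <- kr >= 1 & kr <= qmax
  S <- as.vector(tapply(abs(fa[sel])^2, kr[sel], mean))
  N <- sum(clean) # Poisson: flat noise power = total counts
  frc_pred <- S / (S + N)
  freq <- seq_len(qmax) / (n * px)
  i <- which(frc_pred < 1 / 7)[1]
  f_pred <- freq[i - 1] + (frc_pred[i - 1] - 1 / 7) /
    (frc_pred[i - 1] - frc_pred[i]) * (freq[i] - freq[i - 1])
  f_meas <- 1 / curve$resolution
  expect_lt(abs(f_meas - f_pred) / f_pred, 0.15)
})

test_that("accuracy sweep is deterministic and ordered across corners", {
  cfg <- acquisition_config(fov = 24L, pixel_size = 100, psf_sigma = 130,
                            density = 1, n_frames = 15L, upsample = 1L,
                            sensor = p9(),
                            compression = compression_config(quality = 90))
  loc <- list(classic = function(stack, px)
    localize_stack(stack, detection_config(), pixel_size = px))
  grid <- sweep_accuracy(loc, photon_levels = c(50, 1000),
                         qualities = c(70, 100), config = cfg, seed = 6)
  expect_equal(nrow(grid), 4)
  best <- grid$matched_fraction[grid$photons == 1000 & grid$quality == 100]
  worst <- grid$matched_fraction[grid$photons == 50 & grid$quality == 70]
  expect_gt(best, worst)
  grid2 <- sweep_accuracy(loc, photon_levels = c(50, 1000),
                          qualities = c(70, 100), config = cfg, seed = 6)
  expect_identical(grid, grid2)
})
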