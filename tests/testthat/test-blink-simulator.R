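# Ground-truth blinking simulation and training-pair assembly.

test_that("emitter sampling follows the configured density and Poisson law", {
  cfg <- acquisition_config(fov = 100L, pixel_size = 100, density = 6,
                            n_frames = 2000L)
  tab <- sample_emitters(cfg, seed = 3)
  counts <- tabulate(tab$frame + 1L, nbins = 2000)
  expect_lt(abs(mean(counts) / 100 - 6) / 6, 0.02)       # 100 um^2 FOV
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.10)   # Poisson index
  expect_true(all(tab$x >= 0 & tab$x < 100 * 100))
  expect_true(all(tab$photons > 0))
  # determinism
  expect_identical(tab, sample_emitters(cfg, seed = 3))
})

test_that("zero density gives an empty table", {
  tab <- sample_emitters(tiny_config(density = 0, n_frames = 5L), seed = 1)
  expect_equal(nrow(tab), 0)
})

test_that("fixed photon mode uses the configured count exactly", {
  cfg <- acquisition_config(fov = 32L, density = 2, n_frames = 20L,
                            photons_per_emitter = 500, photon_mode = "fixed")
  tab <- sample_emitters(cfg, seed = 2)
  expect_true(all(tab$photons == 500))
})

test_that("rendering conserves photons and centers mass correctly", {
  cfg <- tiny_config()
  tab <- one_emitter(x = 750, y = 750)   # center of the 15x15 field
  stack <- render_frames(tab, cfg)
  expect_lt(abs(sum(stack) - 1000) / 1000, 0.005)
  expect_equal(which.max(stack[, , 1]), 7 * 15 + 8)   # pixel (8, 8)

  # exactly between two pixels: equal split
  tab2 <- one_emitter(x = 700, y = 750)
  s2 <- render_frames(tab2, cfg)[, , 1]
  expect_equal(s2[8, 7], s2[8, 8], tolerance = 1e-12)

  expect_error(render_frames(one_emitter(x = -5, y = 100), cfg), "outside")
})

test_that("the brightest pixel contains the emitter", {
  cfg <- tiny_config()
  set.seed(7)
  for (k in 1:100) {
    # keep away from edges so the PSF is not truncated asymmetrically
    x <- runif(1, 200, 1300); y <- runif(1, 200, 1300)
    fr <- render_frames(one_emitter(x = x, y = y), cfg)[, , 1]
    peak <- arrayInd(which.max(fr), dim(fr))
    expect_equal(peak[1], floor(y / 100) + 1)
    expect_equal(peak[2], floor(x / 100) + 1)
  }
})

test_that("location maps set one pixel per emitter and round-trip", {
  cfg <- tiny_config(upsample = 5L)
  # emitter at an upsampled-pixel center
  tab <- one_emitter(x = 410, y = 210)
  maps <- render_location_maps(tab, cfg)
  expect_equal(sum(maps > 0), 1)
  expect_equal(max(maps), 1000)

  expect_equal(sum(render_location_maps(tab[0, ], cfg)), 0)

  # table -> map -> table recovers positions within half an upsampled pixel
  set.seed(11)
  tabn <- data.frame(id = 1:20, frame = 0L,
                     x = runif(20, 0, 1499), y = runif(20, 0, 1499),
                     photons = runif(20, 500, 1500))
  maps <- render_location_maps(tabn, cfg)
  rec <- maps_to_table(maps, threshold_fraction = 1e-6, pixel_size = 100,
                       upsample = 5L)
  half_px <- 100 / (2 * 5)
  for (k in seq_len(nrow(tabn))) {
    d <- sqrt((rec$x - tabn$x[k])^2 + (rec$y - tabn$y[k])^2)
    expect_lte(min(d), sqrt(2) * half_px)
  }
})

test_that("training pairs are transparent at quality 100 with no noise", {
  cfg <- tiny_config(fov = 16L, upsample = 4L, sensor = NULL,
                     quality = 100, n_frames = 3L, density = 2)
  pairs <- make_training_pairs(cfg, seed = 5)
  acqref <- render_frames(pairs$table, cfg)
  for (i in 1:3) {
    up <- acqref[rep(1:16, each = 4), rep(1:16, each = 4), i]
    expect_equal(pairs$x[, , i], round(up) + 0 * up, tolerance = 0.51)
  }
  expect_equal(dim(pairs$x), dim(pairs$y))
})

test_that("pairs are spatially aligned with the ground-truth maps", {
  cfg <- tiny_config(fov = 16L, upsample = 4L, sensor = NULL,
                     quality = 100, n_frames = 1L, density = 3)
  pairs <- make_training_pairs(cfg, seed = 8)
  # cross-correlation (FFT, circular) between map and rendered frame
  # peaks at zero lag
  a <- pairs$x[, , 1] - mean(pairs$x[, , 1])
  psf <- psf_kernel(130 / 25)
  b <- smlmgan:::psf_conv(pairs$y[, , 1], psf)
  b <- b - mean(b)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc))
  # allow a sub-camera-pixel offset (nearest upsampling quantizes by 4)
  lag <- ((peak - 1 + 32) %% 64) - 32
  expect_true(all(abs(lag) <= 2))
})

test_that("dataset randomness is fully seeded and reproducible", {
  cfg <- tiny_config(fov = 16L, upsample = 2L, sensor = p9(),
                     quality = 90, n_frames = 4L, density = 2)
  a <- make_training_pairs(cfg, seed = 123)
  b <- make_training_pairs(cfg, seed = 123)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$table, b$table)
})

test_that("pairs_from_localizations mirrors the ground-truth pipeline", {
  cfg <- tiny_config(fov = 16L, upsample = 4L, sensor = NULL,
                     quality = 100, n_frames = 3L, density = 2)
  ref <- make_training_pairs(cfg, seed = 5)
  acq <- simulate_acquisition(cfg, seed = 5)
  alt <- pairs_from_localizations(acq$adu, acq$table, cfg)
  expect_equal(alt$y, ref$y)
  expect_equal(alt$x, ref$x)

  # empty detections on a frame give an all-zero map
  det <- acq$table[acq$table$frame != 1L, ]
  alt2 <- pairs_from_localizations(acq$adu, det, cfg)
  expect_equal(sum(alt2$y[, , 2]), 0)
  bad <- acq$table; bad$frame <- bad$frame + 10L
  expect_error(pairs_from_localizations(acq$adu, bad, cfg), "frame ind")
})

test_that("two dataset methods interleave 50:50", {
  cfg <- tiny_config(fov = 16L, upsample = 2L, sensor = NULL,
                     quality = 100, n_frames = 4L, density = 2)
  a <- make_training_pairs(cfg, seed = 1)
  b <- make_training_pairs(cfg, seed = 2)
  mixed <- mix_training_pairs(a, b)
  expect_equal(dim(mixed$x)[3], 8)
  expect_identical(mixed$x[, , 1], a$x[, , 1])
  expect_identical(mixed$x[, , 2], b$x[, , 1])
  expect_identical(mixed$y[, , 7], a$y[, , 4])
  expect_identical(mixed$y[, , 8], b$y[, , 4])
})
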