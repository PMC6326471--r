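# Training loop contracts: determinism, loss decomposition, inference.

small_pairs <- function(seed = 1, n = 16) {
  cfg <- acquisition_config(fov = 8L, pixel_size = 100, psf_sigma = 130,
                            density = 2, n_frames = n,
                            photons_per_emitter = 1000,
                            photon_mode = "fixed", upsample = 2L,
                            sensor = p9(),
                            compression = compression_config(quality = 90))
  make_training_pairs(cfg, seed = seed)
}

quick_train <- function(pairs, epochs, seed = 3, w = NULL) {
  if (is.null(w)) w <- loss_weights(cgan_warmup_iters = 4L,
                                    cgan_active_every = 2L)
  train(pairs,
        gspec = generator_spec(depth = 2L, base_channels = 4L),
        dspec = discriminator_spec(base_channels = 4L),
        w = w,
        tc = train_config(learning_rate = 1e-3, batch_size = 4L,
                          epochs = epochs, seed = seed))
}

test_that("zero epochs return an initialized model with empty history", {
  pairs <- small_pairs()
  m <- quick_train(pairs, epochs = 0L)
  expect_s3_class(m, "gan_model")
  expect_equal(nrow(m$history), 0)
  expect_equal(m$trained_iters, 0)
  # the untrained generator still produces finite non-negative maps
  maps <- infer_stack(m, array(0, dim = c(8, 8, 2)))
  expect_true(all(is.finite(maps)))
  expect_true(all(maps >= 0))
})

test_that("training rejects empty or inconsistent datasets", {
  pairs <- small_pairs()
  broken <- pairs
  broken$y <- broken$y[1:8, 1:8, , drop = FALSE]
  expect_error(train(broken, tc = train_config(epochs = 1L)), "mismatch")
  expect_error(train(list(x = 1)), "frame_pairs")
  # 8 px frames at upsample 2 -> 16 px maps; depth 5 would need 32
  expect_error(quick_train_depth <- train(
    pairs, gspec = generator_spec(depth = 5L, base_channels = 2L),
    tc = train_config(epochs = 1L)), "divisible")
})

test_that("identical seeds give identical loss histories", {
  pairs <- small_pairs()
  m1 <- quick_train(pairs, epochs = 3L, seed = 11)
  m2 <- quick_train(pairs, epochs = 3L, seed = 11)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$G, m2$G)
  m3 <- quick_train(pairs, epochs = 3L, seed = 12)
  expect_false(identical(m3$history$total, m1$history$total))
})

test_that("the recorded total equals the weighted sum of its parts", {
  pairs <- small_pairs()
  w <- loss_weights(cgan_warmup_iters = 4L, cgan_active_every = 2L)
  m <- quick_train(pairs, epochs = 4L, w = w)
  h <- m$history
  expect_gt(nrow(h), 8)
  for (r in seq_len(nrow(h))) {
    lam <- if (cgan_active(w, h$iteration[r])) w$lambda_cgan else 0
    expect_equal(h$total[r],
                 lam * h$l_cgan[r] + w$lambda_l1 * h$l1_psf[r] +
                   w$lambda_l1s * h$l1_sparse[r],
                 tolerance = 1e-10)
    if (lam == 0) expect_equal(h$l_cgan[r], 0)
  }
})

test_that("training reduces the PSF-smoothed reconstruction error", {
  pairs <- small_pairs(seed = 7, n = 24)
  m <- quick_train(pairs, epochs = 8L, seed = 5)
  h <- m$history
  first_epoch <- mean(h$l1_psf[h$iteration <= 6])
  last_epoch <- mean(h$l1_psf[h$iteration > max(h$iteration) - 6])
  expect_lt(last_epoch, first_epoch)
})

test_that("inference accepts frame sizes different from training", {
  pairs <- small_pairs()
  m <- quick_train(pairs, epochs = 1L)
  # trained on 16x16 maps; feed 16x16 camera frames -> 32x32 maps
  maps <- infer_stack(m, array(10, dim = c(16, 16, 2)))
  expect_equal(dim(maps), c(32, 32, 2))
  # odd sizes are padded and cropped back
  maps2 <- infer_stack(m, array(10, dim = c(9, 11, 1)))
  expect_equal(dim(maps2), c(18, 22, 1))
  expect_true(all(maps2 >= 0))
})

test_that("summing maps gives the reconstruction, threshold either side", {
  maps <- array(0, dim = c(8, 8, 3))
  maps[2, 2, 1] <- 1; maps[5, 5, 2] <- 0.4; maps[2, 2, 3] <- 0.8
  img <- sum_maps(maps)
  expect_equal(img[2, 2], 1.8)
  expect_equal(sum(img), 2.2)
  # per-frame thresholding keeps every frame's own maximum, thresholding
  # the summed image drops the weak frame entirely — order matters
  pre <- sum_maps(maps, threshold_fraction = 0.5, threshold_before_sum = TRUE)
  post <- sum_maps(maps, threshold_fraction = 0.5, threshold_before_sum = FALSE)
  expect_equal(sum(pre), 2.2)
  expect_equal(sum(post), 1.8)
})

test_that("export and reload reproduce inference bit-for-bit", {
  pairs <- small_pairs()
  m <- quick_train(pairs, epochs = 1L)
  path <- file.path(tempdir(), "model_roundtrip")
  export_model(m, path)
  m2 <- load_model(path)
  stack <- array(runif(8 * 8 * 2, 0, 50), dim = c(8, 8, 2))
  expect_identical(infer_stack(m, stack), infer_stack(m2, stack))
  # YAML sidecar carries the architecture and seed metadata
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  expect_equal(meta$generator$depth, 2)
  expect_equal(meta$seed, m$tc$seed)
  # a depth-4 generator exports too (64x64 maps support 4 pool levels)
  cfg <- acquisition_config(fov = 16L, density = 1, n_frames = 8L,
                            upsample = 4L, sensor = p9())
  p4 <- make_training_pairs(cfg, seed = 2)
  m4 <- train(p4, gspec = generator_spec(depth = 4L, base_channels = 2L),
              dspec = discriminator_spec(2L),
              tc = train_config(epochs = 0L, seed = 1))
  path4 <- file.path(tempdir(), "model_depth4")
  export_model(m4, path4)
  expect_equal(load_model(path4)$gspec$depth, 4L)
})
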