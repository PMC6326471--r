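# 4x4 exact-match integer-transform compression and temporal artifacts.

test_that("quality 100 is exactly lossless on integer frames", {
  set.seed(1)
  f <- matrix(sample(0:4095, 48 * 48, replace = TRUE), 48, 48)
  out <- block_transform_degrade(f, compression_config(quality = 100))
  expect_equal(out, f)
  # twice through changes nothing either
  expect_equal(block_transform_degrade(out, compression_config(quality = 100)),
               f)
})

test_that("constant blocks carry only DC and stay constant", {
  f <- matrix(16, 4, 4)
  Y <- C4 %*% f %*% t(C4)
  expect_equal(sum(Y != 0), 1)           # DC only
  expect_equal(Y[1, 1], sum(f))
  # DC = 256 is divisible by typical steps, so the block passes unchanged
  for (qual in c(100, 90, 80)) {
    q <- quant_step(qual)
    if ((16 * 16) %% q == 0) {
      out <- block_transform_degrade(f, compression_config(quality = qual))
      expect_equal(out, f)
    }
  }
})

test_that("degradation matches a brute-force per-block matrix oracle", {
  blk <- matrix(c(10, 20, 30, 40,
                  40, 30, 20, 10,
                  10, 20, 30, 40,
                  40, 30, 20, 10), 4, 4, byrow = TRUE)
  for (qual in c(95, 80, 70)) {
    out <- block_transform_degrade(blk, compression_config(quality = qual))
    expect_equal(out, pmin(pmax(block_oracle(blk, quant_step(qual)), 0), 4095),
                 info = paste("quality", qual))
  }
  # multi-block frames agree with the oracle applied block-wise
  set.seed(2)
  f <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
  out <- block_transform_degrade(f, compression_config(quality = 80))
  q <- quant_step(80)
  for (i in seq(1, 16, 4)) for (j in seq(1, 16, 4)) {
    expect_equal(out[i:(i + 3), j:(j + 3)],
                 pmin(pmax(block_oracle(f[i:(i + 3), j:(j + 3)], q), 0), 4095))
  }
})

test_that("idempotence holds when quantized coefficients are preserved", {
  # constant 4x4 tiles: DC = 16 * v; pick v so DC is divisible by the step
  q <- quant_step(90)
  v <- q * 16
  f <- kronecker(matrix(c(v, 2 * v, 3 * v, 4 * v), 2, 2), matrix(1, 4, 4))
  once <- block_transform_degrade(f, compression_config(quality = 90))
  twice <- block_transform_degrade(once, compression_config(quality = 90))
  expect_equal(once, f)
  expect_equal(twice, once)
})

test_that("per-block sums deviate by at most the DC quantization step", {
  set.seed(3)
  f <- matrix(sample(50:200, 32 * 32, replace = TRUE), 32, 32)
  for (qual in c(90, 80, 70)) {
    q <- quant_step(qual)
    out <- block_transform_degrade(f, compression_config(quality = qual),
                                   bit_depth = 16L)
    for (i in seq(1, 32, 4)) for (j in seq(1, 32, 4)) {
      dsum <- abs(sum(out[i:(i + 3), j:(j + 3)]) -
                    sum(f[i:(i + 3), j:(j + 3)]))
      # DC step plus the per-pixel rounding of the exact inverse
      expect_lte(dsum, q + 8)
    }
  }
})

test_that("blocking leaves a gradient signature on block boundaries", {
  # dim noisy frames: low-amplitude noise is exactly what strong
  # quantization flattens inside blocks while block means jump across
  for (qual in c(70, 80)) {
    set.seed(40 + qual)
    nz <- matrix(round(20 + rnorm(128 * 128, 0, 0.5)), 128, 128)
    dg <- block_transform_degrade(nz, compression_config(quality = qual))
    gh <- abs(dg[, 2:128] - dg[, 1:127])
    boundary <- seq(4, 124, 4)
    interior <- setdiff(seq_len(127), boundary)
    expect_gt(mean(gh[, boundary]), mean(gh[, interior]))
  }
})

test_that("degradation rejects invalid inputs", {
  expect_error(block_transform_degrade(array(1, c(2, 2, 2)),
                                       compression_config()), "2-D")
  expect_error(block_transform_degrade(matrix(0.5, 4, 4),
                                       compression_config()),
               "integer-representable")
  expect_error(block_transform_degrade(matrix(1, 4, 4),
                                       compression_config(mode = "real_codec")),
               "bespoke_transform")
  expect_error(compression_config(quality = 0), "quality")
})

test_that("edge blocks are replicate-padded and output keeps the input size", {
  set.seed(4)
  f <- matrix(sample(0:255, 10 * 13, replace = TRUE), 10, 13)
  out <- block_transform_degrade(f, compression_config(quality = 80))
  expect_equal(dim(out), dim(f))
  expect_true(all(out >= 0 & out <= 4095))
})

test_that("real-codec round trip works when a codec exists, errors otherwise", {
  stk <- const_stack(100, 16, 16, 8)
  cfg <- compression_config(quality = 90, mode = "real_codec")
  if (has_h264_codec()) {
    dec <- encode_decode_video(stk, cfg, fps = 20)
    expect_equal(dim(dec), dim(stk))
    expect_true(all(abs(dec - 100) <= 2))
  } else {
    expect_error(encode_decode_video(stk, cfg), "bespoke_transform")
  }
})

test_that("temporal artifacts: identity, dips and drift arithmetic", {
  stk <- const_stack(50, 8, 8, 100)
  expect_equal(inject_temporal_artifacts(stk, 0, 0), stk)

  withdips <- inject_temporal_artifacts(const_stack(50, 16, 16, 320),
                                        dip_depth = 5, dip_period = 31)
  # loop closure: the dark-series analyzer recovers the injected period
  noisy <- withdips + array(rnorm(length(withdips), 0, 0.3), dim(withdips))
  ds <- analyze_dark_series(noisy, fps = 29)
  expect_identical(ds$dip_period_frames, 31L)

  drifted <- inject_temporal_artifacts(const_stack(50, 8, 8, 1000),
                                       drift_slope = -0.02)
  drop <- mean(drifted[, , 1]) - mean(drifted[, , 1000])
  expect_lt(abs(drop - 0.02 * 999), 1)
  # negative values clip at zero
  clipped <- inject_temporal_artifacts(const_stack(1, 4, 4, 40),
                                       dip_depth = 5, dip_period = 2)
  expect_gte(min(clipped), 0)
  expect_error(inject_temporal_artifacts(stk, dip_depth = 2, dip_period = 0),
               "dip_period")
})
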