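# Shared fixtures, all generated in code.

p9 <- function() sensor_preset("huawei_p9")

# constant-valued stack
const_stack <- function(value, nr = 16, nc = 16, n = 64) {
  array(value, dim = c(nr, nc, n))
}

# the 4x4 forward transform matrix, written out independently of the
# package internals so oracle computations do not share code with them
C4 <- matrix(c(1, 1, 1, 1,
               2, 1, -1, -2,
               1, -1, -1, 1,
               1, -2, 2, -1), 4, 4, byrow = TRUE)

# brute-force single-block degrade oracle: explicit matrix arithmetic
block_oracle <- function(X, q) {
  Y <- C4 %*% X %*% t(C4)
  Yq <- round(Y / q) * q
  round(solve(C4) %*% Yq %*% t(solve(C4)))
}

# tiny single-emitter acquisition config (no compression loss, no noise
# unless a sensor is supplied)
tiny_config <- function(fov = 15L, upsample = 4L, sensor = NULL,
                        quality = 100, n_frames = 1L, density = 0) {
  acquisition_config(fov = fov, pixel_size = 100, psf_sigma = 130,
                     density = density, n_frames = n_frames,
                     photons_per_emitter = 1000, photon_mode = "fixed",
                     upsample = upsample, sensor = sensor,
                     compression = compression_config(quality = quality))
}

one_emitter <- function(x, y, photons = 1000, frame = 0L) {
  data.frame(id = 1L, frame = as.integer(frame), x = x, y = y,
             photons = photons)
}
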