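#' Compression configuration
#'
#' Describes the lossy-video forward model. In `bespoke_transform` mode
#' frames pass through the H.264-style 4x4 exact-match integer transform
#' with uniform coefficient quantization ([block_transform_degrade()]);
#' in `real_codec` mode a system H.264 encoder is used
#' ([encode_decode_video()]). `gop_period` parameterizes periodic
#' inter-frame artifacts (intensity dips) for
#' [inject_temporal_artifacts()].
#'
#' The quantization step follows `q(quality) = max(1, round(2^((100 -
#' quality) / 6.25)))`: the step doubles every 6.25 quality points —
#' mirroring the H.264 convention of doubling the quantizer step every 6
#' QP — and quality 100 is exactly lossless (`q = 1`).
#'
#' @param quality percent in `[1, 100]`.
#' @param block_size transform block edge in pixels (4 in bespoke mode).
#' @param mode `"bespoke_transform"` or `"real_codec"`.
#' @param gop_period frames between periodic temporal artifacts, or `NA`.
#' @return Object of class `compression_config`.
#' @export
compression_config <- function(quality = 90, block_size = 4L,
                               mode = c("bespoke_transform", "real_codec"),
                               gop_period = NA_integer_) {
  mode <- match.arg(mode)
  if (quality < 1 || quality > 100) stop("quality must be in [1, 100]")
  if (block_size < 2) stop("block_size must be >= 2")
  structure(list(quality = as.numeric(quality),
                 block_size = as.integer(block_size), mode = mode,
                 gop_period = as.integer(gop_period)),
            class = "compression_config")
}

#' @export
print.compression_config <- function(x, ...) {
  cat(sprintf("<compression_config> %s, quality %g (q step %d), %dx%d blocks\n",
              x$mode, x$quality, quant_step(x$quality), x$block_size, x$block_size))
  invisible(x)
}

#' Quantization step for a quality setting
#'
#' @param quality percent in `[1, 100]`.
#' @return Integer quantization step; 1 at quality 100.
#' @export
quant_step <- function(quality) {
  max(1L, as.integer(round(2^((100 - quality) / 6.25))))
}

# the H.264 4x4 forward integer transform matrix; its inverse reproduces
# integer inputs exactly when no quantization is applied
h264_transform_matrix <- function() {
  matrix(c(1, 1, 1, 1,
           2, 1, -1, -2,
           1, -1, -1, 1,
           1, -2, 2, -1), 4, 4, byrow = TRUE)
}

#' Degrade a frame with the 4x4 exact-match integer transform
#'
#' Partitions the frame into 4x4 blocks (edges padded by replication),
#' applies the forward transform `Y = C X C'`, quantizes uniformly
#' (`round(Y / q) * q` with `q = quant_step(quality)`), inverts exactly and
#' clips to the digitizer range. At quality 100 (`q = 1`) the operation is
#' lossless on integer frames; at lower quality it produces the blocking
#' artifacts characteristic of strongly compressed video.
#'
#' @param frame 2-D matrix with integer-representable values.
#' @param config a [compression_config()] in `bespoke_transform` mode.
#' @param bit_depth output clip range is `[0, 2^bit_depth - 1]`.
#' @return Degraded integer-valued matrix, same shape as the input.
#' @export
block_transform_degrade <- function(frame, config = compression_config(),
                                    bit_depth = 12L) {
  if (!is.matrix(frame)) stop("frame must be a 2-D matrix")
  if (config$mode != "bespoke_transform")
    stop("block_transform_degrade requires mode = 'bespoke_transform'")
  if (config$block_size != 4L)
    stop("bespoke mode implements the 4x4 exact-match transform only")
  if (max(abs(frame - round(frame))) > 1e-6)
    stop("frame values must be integer-representable")

  b <- 4L
  nr <- nrow(frame); nc <- ncol(frame)
  nrp <- ceiling(nr / b) * b; ncp <- ceiling(nc / b) * b
  padded <- frame[c(seq_len(nr), rep(nr, nrp - nr)),
                  c(seq_len(nc), rep(nc, ncp - nc)), drop = FALSE]

  C <- h264_transform_matrix()
  Ci <- solve(C)
  q <- quant_step(config$quality)

  # stack all blocks as a 4 x (4 * nblocks) matrix so both matrix products
  # are applied to every block at once
  nbr <- nrp / b; nbc <- ncp / b
  blocks <- array(padded, dim = c(b, nbr, b, nbc))
  blocks <- aperm(blocks, c(1, 3, 2, 4))            # b x b x nbr x nbc
  big <- matrix(blocks, nrow = b)                   # 4 x (4 * nblocks)

  Y <- apply_both_sides(big, C)
  Yq <- round(Y / q) * q
  Xr <- apply_both_sides(Yq, Ci)

  out_blocks <- array(Xr, dim = c(b, b, nbr, nbc))
  out <- array(aperm(out_blocks, c(1, 3, 2, 4)), dim = c(nrp, ncp))
  out <- round(out[seq_len(nr), seq_len(nc), drop = FALSE])
  pmin(pmax(out, 0), 2^bit_depth - 1)
}

# given blocks stacked as a 4 x (4*nb) matrix, compute M %*% X %*% t(M)
# for every block
apply_both_sides <- function(big, M) {
  b <- nrow(M)
  nb <- ncol(big) / b
  left <- M %*% big                                  # M X per block
  arr <- array(left, dim = c(b, b, nb))
  arrT <- aperm(arr, c(2, 1, 3))                     # (M X)' per block
  right <- M %*% matrix(arrT, nrow = b)              # M (M X)' = (M X M')'
  arr2 <- array(right, dim = c(b, b, nb))
  matrix(aperm(arr2, c(2, 1, 3)), nrow = b)
}

#' Is a real H.264 codec available?
#'
#' @return `TRUE` when an `ffmpeg` binary with H.264 support is on the PATH.
#' @export
has_h264_codec <- function() {
  nzchar(Sys.which("ffmpeg"))
}

#' Round-trip a stack through a real H.264 codec
#'
#' Writes the stack as 8-bit grayscale video through `ffmpeg` (CRF mapped
#' from the quality percentage), decodes it back and returns frames of the
#' original shape. Requires an H.264 encoder on the system.
#'
#' @param stack frame sequence (list of matrices or 3-D array).
#' @param config a [compression_config()] in `real_codec` mode.
#' @param fps frame rate written to the container.
#' @return Decoded stack, same dimensions as the input.
#' @export
encode_decode_video <- function(stack, config, fps = 20) {
  if (config$mode != "real_codec")
    stop("encode_decode_video requires mode = 'real_codec'")
  if (!has_h264_codec())
    stop("no H.264 codec (ffmpeg) available on this system; ",
         "use compression_config(mode = 'bespoke_transform') instead")
  stack <- as_stack(stack)
  lo <- min(stack); hi <- max(stack)
  scale <- if (hi > lo) 255 / (hi - lo) else 1
  tmp <- tempfile("h264"); dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  for (i in seq_len(dim(stack)[3])) {
    g <- (stack[, , i] - lo) * scale / 255
    tiff::writeTIFF(g, file.path(tmp, sprintf("in_%05d.tif", i)),
                    bits.per.sample = 8)
  }
  crf <- round(51 * (1 - config$quality / 100))
  mp4 <- file.path(tmp, "clip.mp4")
  st <- system2("ffmpeg", c("-y", "-loglevel", "error", "-framerate", fps,
                            "-i", file.path(tmp, "in_%05d.tif"),
                            "-c:v", "libx264", "-crf", crf,
                            "-pix_fmt", "yuv420p", mp4))
  if (st != 0 || !file.exists(mp4)) stop("H.264 encoding failed")
  st <- system2("ffmpeg", c("-y", "-loglevel", "error", "-i", mp4,
                            file.path(tmp, "out_%05d.tif")))
  if (st != 0) stop("H.264 decoding failed")
  outs <- sort(list.files(tmp, "^out_", full.names = TRUE))
  dec <- lapply(outs, function(f) {
    img <- tiff::readTIFF(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img * 255 / scale + lo
  })
  as_stack(dec)
}

#' Inject temporal compression artifacts into a stack
#'
#' Adds a global linear intensity ramp (`drift_slope` ADU per frame) and
#' subtracts `dip_depth` ADU from every `dip_period`-th frame, then clips
#' negative values to zero — the drift-plus-periodic-dip signature seen in
#' dark video series from compressing cameras.
#'
#' @param stack frame sequence.
#' @param drift_slope ADU per frame added cumulatively (can be negative).
#' @param dip_depth ADU subtracted on dip frames; 0 disables dips.
#' @param dip_period dip spacing in frames (>= 1), ignored when
#'   `dip_depth = 0`.
#' @param seed unused at present (artifacts are deterministic); kept so
#'   stochastic artifact variants stay call-compatible.
#' @return Stack with artifacts applied, values clipped at zero.
#' @export
inject_temporal_artifacts <- function(stack, drift_slope = 0, dip_depth = 0,
                                      dip_period = NA, seed = NULL) {
  stack <- as_stack(stack)
  n <- dim(stack)[3]
  if (dip_depth != 0) {
    if (is.na(dip_period) || dip_period < 1)
      stop("dip_period must be >= 1 when dips are enabled")
    dip_period <- as.integer(dip_period)
  }
  for (i in seq_len(n)) {
    f <- stack[, , i] + drift_slope * (i - 1)
    if (dip_depth != 0 && i %% dip_period == 0) f <- f - dip_depth
    stack[, , i] <- pmax(f, 0)
  }
  stack
}
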