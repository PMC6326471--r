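#' Generator architecture specification
#'
#' A U-Net that maps an upsampled degraded frame to a localization map of
#' the same size. Decoder stages use nearest-neighbor resize followed by
#' a convolution (resize-convolution) rather than transposed convolutions,
#' which avoids checkerboard artifacts in the emitted maps. The final
#' activation is a softplus, so outputs are non-negative by construction.
#'
#' @param depth number of encoder/decoder stages (>= 2); input sizes must
#'   be divisible by `2^depth`.
#' @param base_channels channels of the first encoder stage; deeper stages
#'   double (capped at 8x).
#' @param noise_mode if `TRUE`, dropout in the decoder acts as the noise
#'   source during training (and optionally at inference); `FALSE` gives a
#'   fully deterministic generator.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(depth = 4L, base_channels = 16L,
                           noise_mode = FALSE) {
  if (depth < 2) stop("generator depth must be >= 2")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 upsampling = "resize_conv",
                 noise_mode = isTRUE(noise_mode)),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' A fully convolutional patch discriminator: it scores overlapping
#' patches rather than whole images, so the adversarial loss is agnostic
#' to frame size.
#'
#' @param base_channels channels of the first stage.
#' @return Object of class `discriminator_spec` (receptive field ~15 px).
#' @export
discriminator_spec <- function(base_channels = 16L) {
  structure(list(base_channels = as.integer(base_channels),
                 patch_receptive_field = 15L),
            class = "discriminator_spec")
}

#' Loss weights and adversarial schedule
#'
#' The composite training objective weights the adversarial term
#' (`lambda_cgan`), the PSF-smoothed L1 term (`lambda_l1`) and the output
#' sparsity term (`lambda_l1s`). The adversarial contribution is held at
#' zero for the first `cgan_warmup_iters` iterations and afterwards is
#' active only every `cgan_active_every`-th iteration, which keeps early
#' training stable.
#'
#' @param lambda_cgan,lambda_l1,lambda_l1s non-negative weights
#'   (defaults 3, 100, 100).
#' @param cgan_warmup_iters adversarial warm-up length in iterations.
#' @param cgan_active_every adversarial cadence after warm-up.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_cgan = 3, lambda_l1 = 100, lambda_l1s = 100,
                         cgan_warmup_iters = 1000L, cgan_active_every = 3L) {
  if (any(c(lambda_cgan, lambda_l1, lambda_l1s) < 0))
    stop("all loss weights must be >= 0")
  structure(list(lambda_cgan = lambda_cgan, lambda_l1 = lambda_l1,
                 lambda_l1s = lambda_l1s,
                 cgan_warmup_iters = as.integer(cgan_warmup_iters),
                 cgan_active_every = as.integer(cgan_active_every)),
            class = "loss_weights")
}

#' Is the adversarial term active at a given iteration?
#'
#' @param w a [loss_weights()].
#' @param iteration 1-based training iteration.
#' @return Logical.
#' @export
cgan_active <- function(w, iteration) {
  iteration > w$cgan_warmup_iters &&
    iteration %% max(w$cgan_active_every, 1L) == 0
}

#' Gaussian PSF kernel for the smoothed L1 loss
#'
#' Both the ground-truth map and the generator output are convolved with
#' this kernel before the L1 comparison; without the smoothing, a map
#' whose peak is off by one pixel would incur the same loss as an empty
#' map, and training would stall.
#'
#' @param sigma kernel standard deviation in map-grid pixels; `0` gives a
#'   1x1 identity (delta) kernel.
#' @param amplitude scale factor applied to the unit-sum kernel.
#' @param support kernel edge in pixels (odd); default `4 * sigma`-ish.
#' @return Object of class `psf_kernel`; the `$kernel` matrix is
#'   non-negative with its peak at the center.
#' @export
psf_kernel <- function(sigma, amplitude = 1, support = NULL) {
  if (sigma <= 0) {
    k <- matrix(amplitude, 1, 1)
    g <- sqrt(amplitude)
  } else {
    if (is.null(support)) support <- 2L * ceiling(2 * sigma) + 1L
    support <- as.integer(support)
    if (support %% 2 == 0) support <- support + 1L
    r <- (support - 1L) %/% 2L
    g <- stats::dnorm(-r:r, sd = sigma)
    g <- sqrt(amplitude) * g / sum(g)
    k <- outer(g, g)
  }
  structure(list(kernel = k, profile = g, sigma = sigma,
                 amplitude = amplitude, support = ncol(k)),
            class = "psf_kernel")
}

# separable convolution with the kernel's 1-D profile (zero padding);
# exactly equals 2-D convolution with psf$kernel since it is rank one
psf_conv <- function(mat, psf) {
  g <- psf$profile
  if (length(g) == 1) return(mat * g^2)
  r <- (length(g) - 1L) %/% 2L
  conv1 <- function(m) {
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (j in seq_along(g)) {
      sh <- j - r - 1L
      src <- seq_len(nr) + sh
      ok <- src >= 1 & src <= nr
      out[ok, ] <- out[ok, ] + g[j] * m[src[ok], , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(mat))))
}

#' Evaluate the composite GAN loss
#'
#' Computes the three loss terms for one frame pair: the non-saturating
#' adversarial cross-entropy on the discriminator's fake scores, the L1
#' distance between PSF-convolved ground-truth and generated maps, and
#' the L1 sparsity of the generated map. The total applies the weights
#' with the adversarial schedule of `w` at the given iteration.
#'
#' @param x input frame (unused by the terms themselves; kept so the
#'   breakdown signature matches the objective's conditioning).
#' @param y ground-truth map.
#' @param y_hat generated map, same grid as `y`.
#' @param d_real,d_fake discriminator patch scores in (0,1) for the real
#'   and generated pair; `NULL` when the discriminator was not evaluated
#'   (the adversarial term is then reported as 0).
#' @param psf a [psf_kernel()].
#' @param w a [loss_weights()].
#' @param iteration 1-based training iteration (drives the schedule).
#' @return Object of class `loss_breakdown` with `l_cgan`, `l1_psf`,
#'   `l1_sparse` and `total`.
#' @export
composite_loss <- function(x, y, y_hat, d_real = NULL, d_fake = NULL,
                           psf = psf_kernel(0), w = loss_weights(),
                           iteration = 1L) {
  if (!all(dim(as_cube(y))[1:2] == dim(as_cube(y_hat))[1:2]))
    stop("y and y_hat must share one grid")
  y <- as.matrix(drop_cube(y)); y_hat <- as.matrix(drop_cube(y_hat))
  l1_psf <- mean(abs(psf_conv(y, psf) - psf_conv(y_hat, psf)))
  l1_sparse <- mean(abs(y_hat))
  eps <- 1e-12
  l_cgan <- if (is.null(d_fake)) 0 else -mean(log(pmax(d_fake, eps)))
  lam_cgan <- if (cgan_active(w, iteration)) w$lambda_cgan else 0
  structure(list(l_cgan = l_cgan, l1_psf = l1_psf, l1_sparse = l1_sparse,
                 lambda_cgan_effective = lam_cgan,
                 total = lam_cgan * l_cgan + w$lambda_l1 * l1_psf +
                   w$lambda_l1s * l1_sparse),
            class = "loss_breakdown")
}

drop_cube <- function(a) {
  a <- as_cube(a)
  a[, , 1]
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param adam_beta1 Adam first-moment decay ("momentum beta", default
#'   0.25); the second-moment decay stays at the conventional 0.999.
#' @param batch_size frames per minibatch.
#' @param epochs passes over the dataset.
#' @param seed integer seed governing initialization, shuffling and
#'   dropout; training is fully reproducible given it.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, adam_beta1 = 0.25,
                         batch_size = 4L, epochs = 10L, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Train the conditional GAN localizer
#'
#' Alternating minibatch updates of the patch discriminator and the U-Net
#' generator with Adam. The generator objective is the weighted sum of
#' the PSF-smoothed L1 term, the sparsity term and (on schedule) the
#' non-saturating adversarial term; the discriminator minimizes the usual
#' real/fake cross-entropy and is updated only on iterations where the
#' adversarial term is active.
#'
#' Inputs and targets are normalized internally by the dataset maxima;
#' the normalization constants are stored in the model and undone by
#' [infer_stack()], so training is invariant to the global scale of the
#' localization maps.
#'
#' @param pairs a `frame_pairs` dataset (see [make_training_pairs()]).
#' @param gspec a [generator_spec()].
#' @param dspec a [discriminator_spec()].
#' @param w a [loss_weights()].
#' @param tc a [train_config()].
#' @param psf optional [psf_kernel()]; default derives sigma from the
#'   dataset's acquisition config (`psf_sigma` / upsampled pixel).
#' @param verbose print a line every 50 iterations.
#' @return Object of class `gan_model` containing the trained parameters,
#'   the normalization constants, the PSF kernel and a per-iteration loss
#'   history (`$history`).
#' @export
train <- function(pairs, gspec = generator_spec(),
                  dspec = discriminator_spec(), w = loss_weights(),
                  tc = train_config(), psf = NULL, verbose = FALSE) {
  if (!inherits(pairs, "frame_pairs")) stop("pairs must be a frame_pairs object")
  n <- dim(pairs$x)[3]
  if (n < 1) stop("empty training dataset")
  d <- dim(pairs$x)[1:2]
  if (!all(dim(pairs$y)[1:2] == d)) stop("x/y grid mismatch within dataset")
  if (any(d %% 2^gspec$depth != 0))
    stop("frame size must be divisible by 2^depth = ", 2^gspec$depth)

  set.seed(tc$seed)
  G <- generator_init(gspec)
  D <- discriminator_init(dspec)
  optG <- adam_init(G)
  optD <- adam_init(D)

  # input normalization: remove the dark pedestal, scale to [~0, 1];
  # target normalization: unit peak
  x0 <- stats::median(pairs$x)
  sx <- max(pairs$x) - x0; if (sx <= 0) sx <- 1
  sy <- max(pairs$y); if (sy <= 0) sy <- 1
  if (is.null(psf)) {
    cfg <- pairs$config
    sig_px <- if (!is.null(cfg)) cfg$psf_sigma / (cfg$pixel_size / cfg$upsample)
      else 2
    # unit-peak kernel: the blurred comparison images keep O(1) amplitude,
    # fixing the balance against the sparsity term
    unit <- psf_kernel(sig_px)
    psf <- psf_kernel(sig_px, amplitude = 1 / max(unit$kernel))
  }

  npix <- prod(d)
  hist_rows <- list()
  it <- 0L
  n_batches <- max(1L, floor(n / tc$batch_size))

  for (epoch in seq_len(tc$epochs)) {
    perm <- sample.int(n)
    for (bi in seq_len(n_batches)) {
      it <- it + 1L
      idx <- perm[((bi - 1) * tc$batch_size + 1):min(bi * tc$batch_size, n)]
      adv <- cgan_active(w, it) && w$lambda_cgan > 0

      gG <- NULL; gD <- NULL
      acc <- c(l_cgan = 0, l1_psf = 0, l1_sparse = 0, total = 0, d_loss = 0)
      for (s in idx) {
        xs <- (pairs$x[, , s] - x0) / sx
        ys <- pairs$y[, , s] / sy
        fw <- generator_forward(G, gspec, xs, training = TRUE)
        yh <- fw$y[, , 1]

        # L1 terms and their gradient on the generator output
        r <- psf_conv(yh - ys, psf)
        dyh <- (w$lambda_l1 / npix) * psf_conv(sign(r), psf) +
          (w$lambda_l1s / npix) * sign(yh)

        d_fake_scores <- NULL
        if (adv) {
          fr <- discriminator_forward(D, xs, ys)
          ff <- discriminator_forward(D, xs, yh)
          np <- length(ff$logits)
          d_fake_scores <- as.vector(ff$scores)
          # discriminator: -log D(real) - log(1 - D(fake))
          bwr <- discriminator_backward(D, fr$cache,
                                        (fr$scores - 1) / np)
          bwf <- discriminator_backward(D, ff$cache, ff$scores / np)
          gDs <- tree_map2(bwr$grads, bwf$grads, `+`)
          gD <- if (is.null(gD)) gDs else tree_map2(gD, gDs, `+`)
          acc["d_loss"] <- acc["d_loss"] +
            (-mean(log(pmax(fr$scores, 1e-12))) -
               mean(log(pmax(1 - ff$scores, 1e-12))))
          # generator adversarial pull: -log D(fake), through D into y_hat
          bwg <- discriminator_backward(D, ff$cache,
                                        w$lambda_cgan * (ff$scores - 1) / np)
          dyh <- dyh + bwg$dy[, , 1]
        }

        gGs <- generator_backward(G, gspec, fw$cache,
                                  array(dyh, dim = c(d, 1L)))
        gG <- if (is.null(gG)) gGs else tree_map2(gG, gGs, `+`)

        lb <- composite_loss(xs, ys, yh, d_fake = d_fake_scores,
                             psf = psf, w = w, iteration = it)
        acc["l_cgan"] <- acc["l_cgan"] + lb$l_cgan
        acc["l1_psf"] <- acc["l1_psf"] + lb$l1_psf
        acc["l1_sparse"] <- acc["l1_sparse"] + lb$l1_sparse
        acc["total"] <- acc["total"] + lb$total
      }
      nb <- length(idx)
      gG <- tree_map2(gG, gG, function(g, .) g / nb)
      up <- adam_step(G, gG, optG, tc$learning_rate, tc$adam_beta1)
      G <- up$params; optG <- up$state
      if (adv) {
        gD <- tree_map2(gD, gD, function(g, .) g / nb)
        upd <- adam_step(D, gD, optD, tc$learning_rate, tc$adam_beta1)
        D <- upd$params; optD <- upd$state
      }
      hist_rows[[it]] <- c(iteration = it, acc / nb)
      if (verbose && it %% 50 == 0)
        message(sprintf("iter %d: total %.4f (l1_psf %.4f)", it,
                        acc["total"] / nb, acc["l1_psf"] / nb))
    }
  }

  history <- if (length(hist_rows))
    as.data.frame(do.call(rbind, hist_rows))
  else data.frame(iteration = numeric(0), l_cgan = numeric(0),
                  l1_psf = numeric(0), l1_sparse = numeric(0),
                  total = numeric(0), d_loss = numeric(0))
  names(history) <- c("iteration", "l_cgan", "l1_psf", "l1_sparse",
                      "total", "d_loss")

  structure(list(gspec = gspec, dspec = dspec, w = w, tc = tc,
                 G = G, D = D, norm = list(x0 = x0, sx = sx, sy = sy),
                 psf = psf,
                 config = pairs$config, history = history,
                 trained_iters = it),
            class = "gan_model")
}

#' @export
print.gan_model <- function(x, ...) {
  cat(sprintf(
    "<gan_model> U-Net depth %d (base %d ch), %d training iterations\n",
    x$gspec$depth, x$gspec$base_channels, x$trained_iters))
  if (nrow(x$history) > 0)
    cat(sprintf("  final losses: l1_psf %.4g, l1_sparse %.4g, total %.4g\n",
                utils::tail(x$history$l1_psf, 1),
                utils::tail(x$history$l1_sparse, 1),
                utils::tail(x$history$total, 1)))
  invisible(x)
}

#' Run the trained generator over a stack
#'
#' Frames are upsampled by nearest-neighbor to the map grid, normalized
#' with the constants stored at training time, padded (replicate) to a
#' size divisible by `2^depth`, passed through the generator and cropped
#' back. Because the networks are fully convolutional, frame sizes may
#' differ from the training size. Outputs are non-negative by the final
#' activation.
#'
#' @param model a trained `gan_model`.
#' @param stack camera-grid frame sequence.
#' @param upsample upsampling factor; defaults to the training config's.
#' @param dropout if `TRUE` and the generator was specified with
#'   `noise_mode`, dropout stays active at inference (stochastic outputs);
#'   default `FALSE` for deterministic inference.
#' @return Map stack array, `c(fov * upsample, n_frames)`.
#' @export
infer_stack <- function(model, stack, upsample = NULL, dropout = FALSE) {
  stack <- as_stack(stack)
  if (is.null(upsample))
    upsample <- if (!is.null(model$config)) model$config$upsample else 1L
  n <- dim(stack)[3]
  mult <- 2^model$gspec$depth
  out <- NULL
  for (i in seq_len(n)) {
    xs <- (upsample_nearest(stack[, , i], upsample) - model$norm$x0) /
      model$norm$sx
    d0 <- dim(xs)
    pr <- (mult - d0[1] %% mult) %% mult
    pc <- (mult - d0[2] %% mult) %% mult
    if (pr > 0 || pc > 0)
      xs <- xs[c(seq_len(d0[1]), rep(d0[1], pr)),
               c(seq_len(d0[2]), rep(d0[2], pc)), drop = FALSE]
    fw <- generator_forward(model$G, model$gspec, xs,
                            training = isTRUE(dropout))
    ym <- fw$y[seq_len(d0[1]), seq_len(d0[2]), 1] * model$norm$sy
    if (is.null(out)) out <- array(0, dim = c(d0, n))
    out[, , i] <- ym
  }
  out
}

#' Sum per-frame maps into a reconstruction image
#'
#' @param maps map stack from [infer_stack()].
#' @param threshold_fraction optional per-frame relative threshold; pixels
#'   below `threshold_fraction * max(frame)` are zeroed.
#' @param threshold_before_sum apply the threshold per frame before
#'   summation (`TRUE`) or once on the summed image (`FALSE`).
#' @return 2-D reconstruction image.
#' @export
sum_maps <- function(maps, threshold_fraction = NULL,
                     threshold_before_sum = TRUE) {
  maps <- as_stack(maps)
  thr_fun <- function(m) {
    m[m <= threshold_fraction * max(m)] <- 0
    m
  }
  if (!is.null(threshold_fraction) && threshold_before_sum) {
    for (i in seq_len(dim(maps)[3])) maps[, , i] <- thr_fun(maps[, , i])
  }
  img <- apply(maps, c(1, 2), sum)
  if (!is.null(threshold_fraction) && !threshold_before_sum) img <- thr_fun(img)
  img
}

#' Extract a localization table from map frames
#'
#' Per frame, pixels above `threshold_fraction * max(frame)` are grouped
#' into 8-connected components; each component contributes one event at
#' its intensity-weighted centroid, converted to nm on the upsampled grid
#' (`pixel_size / upsample` nm per map pixel, center-of-pixel convention).
#'
#' @param maps map stack.
#' @param threshold_fraction relative threshold in (0,1), default 0.3.
#' @param pixel_size camera pixel size in nm.
#' @param upsample map upsampling factor.
#' @return Emitter table `data.frame(id, frame, x, y, photons)` with
#'   `frame` 0-based; empty frames contribute no rows.
#' @export
maps_to_table <- function(maps, threshold_fraction = 0.3, pixel_size = 100,
                          upsample = 1L) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  maps <- as_stack(maps)
  upx <- pixel_size / upsample
  rows <- list()
  for (i in seq_len(dim(maps)[3])) {
    m <- maps[, , i]
    mx <- max(m)
    if (mx <= 0) next
    mask <- m > threshold_fraction * mx
    if (!any(mask)) next
    lbl <- EBImage::bwlabel(mask)
    for (l in seq_len(max(lbl))) {
      sel <- which(lbl == l, arr.ind = TRUE)
      wts <- m[sel]
      cy <- sum((sel[, 1] - 0.5) * wts) / sum(wts) * upx
      cx <- sum((sel[, 2] - 0.5) * wts) / sum(wts) * upx
      rows[[length(rows) + 1]] <- data.frame(frame = i - 1L, x = cx, y = cy,
                                             photons = sum(wts))
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
               photons = numeric(0))
  tab <- cbind(id = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  class(tab) <- c("emitter_table", "data.frame")
  tab
}

#' Export a trained model to disk
#'
#' Writes the full model object (weights, specs, normalization, seed) as
#' an RDS file plus a human-readable YAML sidecar with the architecture
#' and training metadata.
#'
#' @param model a `gan_model`.
#' @param path output path (`.rds` appended if missing).
#' @return The path, invisibly.
#' @export
export_model <- function(model, path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  saveRDS(model, path)
  meta <- list(generator = unclass(model$gspec),
               discriminator = unclass(model$dspec),
               loss_weights = unclass(model$w),
               training = unclass(model$tc),
               seed = model$tc$seed,
               trained_iters = model$trained_iters,
               norm = model$norm)
  yaml::write_yaml(meta, sub("\\.rds$", ".yaml", path))
  invisible(path)
}

#' Reload an exported model
#'
#' @param path path written by [export_model()].
#' @return The `gan_model`, reproducing [infer_stack()] outputs
#'   bit-compatibly on the same platform.
#' @export
load_model <- function(path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  readRDS(path)
}
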