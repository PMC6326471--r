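# Internal neural-network machinery: tensor helpers, the U-Net generator
# and patch discriminator forward/backward passes, and Adam. Tensors are
# H x W x C arrays; batches are handled by looping samples and averaging
# gradients. All parameters live in plain nested lists of arrays so the
# optimizer can tree-walk them.

as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

conv_layer_init <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  list(W = array(stats::rnorm(k * k * cin * cout, 0, sd),
                 dim = c(k, k, cin, cout)),
       b = numeric(cout))
}

conv_f <- function(layer, x) conv2d_fwd(as_cube(x), layer$W, layer$b)

lrelu_f <- function(x, alpha = 0.2) ifelse(x > 0, x, alpha * x)
lrelu_b <- function(x, dy, alpha = 0.2) dy * ifelse(x > 0, 1, alpha)
softplus_f <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
softplus_b <- function(x, dy) dy * stats::plogis(x)

avgpool2_f <- function(x) {
  d <- dim(x)
  ro <- seq(1, d[1], 2); co <- seq(1, d[2], 2)
  0.25 * (x[ro, co, , drop = FALSE] + x[ro + 1, co, , drop = FALSE] +
            x[ro, co + 1, , drop = FALSE] + x[ro + 1, co + 1, , drop = FALSE])
}

avgpool2_b <- function(dy) {
  d <- dim(dy)
  dy[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
     drop = FALSE] * 0.25
}

upsample2_f <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

upsample2_b <- function(dy) {
  d <- dim(dy)
  ro <- seq(1, d[1], 2); co <- seq(1, d[2], 2)
  dy[ro, co, , drop = FALSE] + dy[ro + 1, co, , drop = FALSE] +
    dy[ro, co + 1, , drop = FALSE] + dy[ro + 1, co + 1, , drop = FALSE]
}

gen_channels <- function(depth, base) {
  pmin(base * 2^(seq_len(depth) - 1), 8L * base)
}

# ---- generator ----

generator_init <- function(gspec) {
  ch <- gen_channels(gspec$depth, gspec$base_channels)
  d <- gspec$depth
  enc <- vector("list", d)
  cin <- 1L
  for (i in seq_len(d)) {
    enc[[i]] <- conv_layer_init(3L, cin, ch[i])
    cin <- ch[i]
  }
  bott <- conv_layer_init(3L, ch[d], ch[d])
  dec <- vector("list", d)
  prev <- ch[d]
  for (i in rev(seq_len(d))) {
    dec[[i]] <- conv_layer_init(3L, prev, ch[i])
    prev <- 2L * ch[i]   # after skip concat
  }
  final <- conv_layer_init(3L, prev, 1L)
  list(enc = enc, bott = bott, dec = dec, final = final)
}

generator_forward <- function(params, gspec, x, training = FALSE,
                              dropout_rate = 0.5) {
  d <- gspec$depth
  cache <- list(conv_in = list(), pre = list(), skips = list(), drop = list())
  h <- as_cube(x)
  for (i in seq_len(d)) {
    cache$conv_in[[paste0("enc", i)]] <- h
    z <- conv_f(params$enc[[i]], h)
    cache$pre[[paste0("enc", i)]] <- z
    h <- lrelu_f(z)
    cache$skips[[i]] <- h
    h <- avgpool2_f(h)
  }
  cache$conv_in[["bott"]] <- h
  z <- conv_f(params$bott, h)
  cache$pre[["bott"]] <- z
  h <- lrelu_f(z)
  for (i in rev(seq_len(d))) {
    h <- upsample2_f(h)
    cache$conv_in[[paste0("dec", i)]] <- h
    z <- conv_f(params$dec[[i]], h)
    cache$pre[[paste0("dec", i)]] <- z
    h <- lrelu_f(z)
    use_drop <- isTRUE(gspec$noise_mode) && training
    if (use_drop) {
      mask <- array(stats::rbinom(length(h), 1, 1 - dropout_rate) /
                      (1 - dropout_rate), dim = dim(h))
      cache$drop[[paste0("dec", i)]] <- mask
      h <- h * mask
    }
    skip <- cache$skips[[i]]
    h <- array(c(h, skip), dim = c(dim(h)[1:2], dim(h)[3] + dim(skip)[3]))
  }
  cache$conv_in[["final"]] <- h
  z <- conv_f(params$final, h)
  cache$pre[["final"]] <- z
  y <- pmax(z, 0)   # ReLU: exact zeros in the (sparse) background
  list(y = y, cache = cache)
}

generator_backward <- function(params, gspec, cache, dy) {
  d <- gspec$depth
  g <- list(enc = vector("list", d), bott = NULL,
            dec = vector("list", d), final = NULL)
  dskip <- vector("list", d)

  dz <- dy * (cache$pre[["final"]] > 0)
  bw <- conv2d_bwd(cache$conv_in[["final"]], params$final$W, as_cube(dz))
  g$final <- list(W = bw$dw, b = bw$db)
  dh <- bw$dx
  for (i in seq_len(d)) {
    # split concat: first block is the decoder path, rest is the skip
    cdec <- dim(cache$pre[[paste0("dec", i)]])[3]
    dmain <- dh[, , seq_len(cdec), drop = FALSE]
    dskip[[i]] <- dh[, , cdec + seq_len(dim(dh)[3] - cdec), drop = FALSE]
    mask <- cache$drop[[paste0("dec", i)]]
    if (!is.null(mask)) dmain <- dmain * mask
    dz <- lrelu_b(cache$pre[[paste0("dec", i)]], dmain)
    bw <- conv2d_bwd(cache$conv_in[[paste0("dec", i)]], params$dec[[i]]$W,
                     as_cube(dz))
    g$dec[[i]] <- list(W = bw$dw, b = bw$db)
    dh <- upsample2_b(bw$dx)
  }
  dz <- lrelu_b(cache$pre[["bott"]], dh)
  bw <- conv2d_bwd(cache$conv_in[["bott"]], params$bott$W, as_cube(dz))
  g$bott <- list(W = bw$dw, b = bw$db)
  dh <- bw$dx
  for (i in rev(seq_len(d))) {
    dh <- avgpool2_b(dh) + dskip[[i]]
    dz <- lrelu_b(cache$pre[[paste0("enc", i)]], dh)
    bw <- conv2d_bwd(cache$conv_in[[paste0("enc", i)]], params$enc[[i]]$W,
                     as_cube(dz))
    g$enc[[i]] <- list(W = bw$dw, b = bw$db)
    dh <- bw$dx
  }
  g
}

# ---- discriminator (patch scores) ----

discriminator_init <- function(dspec) {
  c1 <- dspec$base_channels
  list(l1 = conv_layer_init(3L, 2L, c1),
       l2 = conv_layer_init(3L, c1, 2L * c1),
       l3 = conv_layer_init(3L, 2L * c1, 1L))
}

discriminator_forward <- function(params, x, y) {
  h0 <- array(c(x, y), dim = c(dim(as_cube(x))[1:2], 2L))
  cache <- list(in1 = h0)
  z1 <- conv_f(params$l1, h0); cache$z1 <- z1
  h <- avgpool2_f(lrelu_f(z1)); cache$in2 <- h
  z2 <- conv_f(params$l2, h); cache$z2 <- z2
  h <- avgpool2_f(lrelu_f(z2)); cache$in3 <- h
  logits <- conv_f(params$l3, h)
  list(logits = logits, scores = stats::plogis(logits), cache = cache)
}

# dlogits: gradient wrt patch logits; returns param grads and gradient wrt
# the y input channel (for the generator's adversarial term)
discriminator_backward <- function(params, cache, dlogits) {
  bw3 <- conv2d_bwd(cache$in3, params$l3$W, as_cube(dlogits))
  dh <- avgpool2_b(bw3$dx)
  dz2 <- lrelu_b(cache$z2, dh)
  bw2 <- conv2d_bwd(cache$in2, params$l2$W, as_cube(dz2))
  dh <- avgpool2_b(bw2$dx)
  dz1 <- lrelu_b(cache$z1, dh)
  bw1 <- conv2d_bwd(cache$in1, params$l1$W, as_cube(dz1))
  list(grads = list(l1 = list(W = bw1$dw, b = bw1$db),
                    l2 = list(W = bw2$dw, b = bw2$db),
                    l3 = list(W = bw3$dw, b = bw3$db)),
       dy = bw1$dx[, , 2, drop = FALSE])
}

# ---- parameter-tree utilities and Adam ----

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

tree_zeros <- function(a) {
  if (is.list(a)) lapply(a, tree_zeros) else a * 0
}

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.25, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map2(state$m, state$m, function(m, .) m / bc1)
  vhat <- tree_map2(state$v, state$v, function(v, .) v / bc2)
  step <- tree_map2(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  params <- tree_map2(params, step, function(p, s) p - s)
  list(params = params, state = state)
}
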