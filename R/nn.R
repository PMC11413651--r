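# Internal neural-network engine: forward passes, manual backpropagation and
# Adam updates for the SFCN-style encoder and its two heads.  Activations are
# 5-d arrays (X, Y, Z, C, N); feature matrices are N x F.  Convolution and
# pooling kernels live in src/layers.cpp; batch norm and bookkeeping are here.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# ---- batch normalization ----------------------------------------------------

# mode: "train"    = batch statistics, returns updated running stats;
#       "frozen"   = batch statistics, running stats untouched;
#       "finetune" = running statistics (no update), gradients flow;
#       "eval"     = running statistics, deterministic.
# With batch statistics the backward pass includes the mean/variance terms;
# with running statistics the normalization is a fixed affine map.
# Per-channel moments and affine maps run in C (channel_sums /
# channel_affine): the flattened array is a sequence of V-length blocks
# whose channel cycles with period C.
nn_bn_fw <- function(x, gamma, beta, run_mean, run_var, mode) {
  d <- dim(x)
  C <- d[4]; N <- d[5]
  V <- prod(d[1:3])
  S <- V * N  # elements per channel
  batch_stats <- mode %in% c("train", "frozen")
  if (batch_stats) {
    cs <- channel_sums(x, x, V, C)
    mu <- cs$sum / S
    va <- cs$sum_prod / S - mu * mu
    va[va < 0] <- 0
  } else {
    mu <- run_mean; va <- run_var
  }
  ivar <- 1 / sqrt(va + BN_EPS)
  xhat <- channel_affine(x, ivar, -mu * ivar, V, C)
  y <- channel_affine(xhat, gamma, beta, V, C)
  stats <- NULL
  if (mode == "train") {
    stats <- list(
      run_mean = (1 - BN_MOMENTUM) * run_mean + BN_MOMENTUM * mu,
      run_var = (1 - BN_MOMENTUM) * run_var + BN_MOMENTUM * va
    )
  }
  list(y = y, stats = stats,
       cache = list(xhat = xhat, ivar = ivar, gamma = gamma, d = d,
                    batch_stats = batch_stats))
}

nn_bn_bw <- function(gy, cache) {
  d <- cache$d
  C <- d[4]; N <- d[5]
  V <- prod(d[1:3])
  S <- V * N
  xhat <- cache$xhat
  zero <- numeric(C)
  cs <- channel_sums(gy, xhat, V, C)
  dbeta <- as.vector(cs$sum)
  dgamma <- as.vector(cs$sum_prod)
  dxhat <- channel_affine(gy, cache$gamma, zero, V, C)
  if (!cache$batch_stats) {
    gx <- channel_affine(dxhat, cache$ivar, zero, V, C)
    dim(gx) <- d
    return(list(gx = gx, dgamma = dgamma, dbeta = dbeta))
  }
  csd <- channel_sums(dxhat, xhat, V, C)
  m1 <- csd$sum / S
  m2 <- csd$sum_prod / S
  gx <- channel_affine(dxhat, cache$ivar, -m1 * cache$ivar, V, C) -
    channel_affine(xhat, m2 * cache$ivar, zero, V, C)
  dim(gx) <- d
  list(gx = gx, dgamma = dgamma, dbeta = dbeta)
}

# ---- encoder ----------------------------------------------------------------

nn_encoder_init <- function(config) {
  widths <- config$channel_widths
  cins <- c(1L, widths[1:5])
  blocks <- vector("list", 6)
  for (b in 1:6) {
    K <- if (b <= 5) 3L else 1L
    ci <- cins[b]; co <- widths[b]
    fan_in <- K^3 * ci
    w <- array(rnorm(K^3 * ci * co, sd = sqrt(2 / fan_in)), dim = c(K, K, K, ci, co))
    blocks[[b]] <- list(
      w = w, b = numeric(co),
      gamma = rep(1, co), beta = numeric(co),
      run_mean = numeric(co), run_var = rep(1, co)
    )
  }
  blocks
}

# Forward pass through the seven-block encoder.  Returns the N x F feature
# matrix, per-block updated running stats (train mode only) and, on request,
# the caches needed for backpropagation.  Dropout (block 7) is active in the
# batch-statistics modes ("train"/"frozen") and draws from the current RNG
# stream; "finetune" and "eval" are deterministic, so the adversarial game
# and the audit probes see the same representation geometry.
nn_encoder_forward <- function(encoder, config, x, mode = "eval", want_cache = FALSE) {
  blocks <- encoder
  cache <- list(blocks = vector("list", 6))
  new_stats <- vector("list", 6)
  h <- x
  for (b in 1:5) {
    blk <- blocks[[b]]
    xin <- h
    cv <- conv3d_fw(xin, blk$w, blk$b)
    bn <- nn_bn_fw(cv, blk$gamma, blk$beta, blk$run_mean, blk$run_var, mode)
    mp <- maxpool3d_fw(bn$y)
    relu <- mp$y > 0
    h <- mp$y * relu
    new_stats[[b]] <- bn$stats
    if (want_cache) {
      cache$blocks[[b]] <- list(xin = xin, bn = bn$cache, idx = mp$idx,
                                bndim = dim(bn$y), relu = relu)
    }
  }
  blk <- blocks[[6]]
  xin <- h
  cv <- conv3d_fw(xin, blk$w, blk$b)
  bn <- nn_bn_fw(cv, blk$gamma, blk$beta, blk$run_mean, blk$run_var, mode)
  relu <- bn$y > 0
  h <- bn$y * relu
  new_stats[[6]] <- bn$stats
  if (want_cache) cache$blocks[[6]] <- list(xin = xin, bn = bn$cache, relu = relu)

  sp <- dim(h)[1:3]
  use_avg <- all(sp >= 2)
  avg_in_dim <- dim(h)
  if (use_avg) h <- avgpool3d_fw(h)
  dmask <- NULL
  if (mode %in% c("train", "frozen") && config$dropout_rate > 0) {
    dmask <- (runif(length(h)) >= config$dropout_rate) / (1 - config$dropout_rate)
    dim(dmask) <- dim(h)
    h <- h * dmask
  }
  d <- dim(h)
  N <- d[5]
  feats <- t(matrix(h, ncol = N))
  cache$use_avg <- use_avg
  cache$avg_in_dim <- avg_in_dim
  cache$dmask <- dmask
  cache$out_dim <- d
  list(features = feats, stats = new_stats, cache = if (want_cache) cache)
}

# Backpropagate d(loss)/d(features) through the encoder; returns per-block
# gradients for w, b, gamma, beta (running stats carry no gradient).
nn_encoder_backward <- function(encoder, cache, gfeat) {
  d <- cache$out_dim
  gh <- array(t(gfeat), dim = d)
  if (!is.null(cache$dmask)) gh <- gh * cache$dmask
  if (cache$use_avg) gh <- avgpool3d_bw(gh, as.integer(cache$avg_in_dim))

  grads <- vector("list", 6)
  cb <- cache$blocks[[6]]
  gh <- gh * cb$relu
  bnb <- nn_bn_bw(gh, cb$bn)
  cvb <- conv3d_bw(cb$xin, encoder[[6]]$w, bnb$gx)
  grads[[6]] <- list(w = cvb$gw, b = cvb$gb, gamma = bnb$dgamma, beta = bnb$dbeta)
  gh <- cvb$gx
  for (b in 5:1) {
    cb <- cache$blocks[[b]]
    gh <- gh * cb$relu
    gh <- maxpool3d_bw(gh, cb$idx, as.integer(cb$bndim))
    bnb <- nn_bn_bw(gh, cb$bn)
    cvb <- conv3d_bw(cb$xin, encoder[[b]]$w, bnb$gx)
    grads[[b]] <- list(w = cvb$gw, b = cvb$gb, gamma = bnb$dgamma, beta = bnb$dbeta)
    gh <- cvb$gx
  }
  grads
}

# Extract/assign the trainable encoder tensors (excludes running stats).
enc_trainable <- function(blocks) {
  lapply(blocks, function(b) b[c("w", "b", "gamma", "beta")])
}

enc_set_trainable <- function(blocks, tr) {
  for (i in seq_along(blocks)) {
    blocks[[i]][c("w", "b", "gamma", "beta")] <- tr[[i]][c("w", "b", "gamma", "beta")]
  }
  blocks
}

enc_commit_stats <- function(blocks, stats) {
  for (i in seq_along(blocks)) {
    if (!is.null(stats[[i]])) {
      blocks[[i]]$run_mean <- stats[[i]]$run_mean
      blocks[[i]]$run_var <- stats[[i]]$run_var
    }
  }
  blocks
}

# ---- heads ------------------------------------------------------------------

nn_sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -40), 40)))

nn_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function() list(t = 0L, m = NULL, v = NULL)

.zeros_like <- function(x) {
  if (is.list(x)) return(lapply(x, .zeros_like))
  z <- x
  z[] <- 0
  z
}

.adam_rec <- function(p, g, m, v, lr, t, b1, b2, eps) {
  if (!is.list(g)) {
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g * g
    mhat <- m2 / (1 - b1^t)
    vhat <- v2 / (1 - b2^t)
    return(list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2))
  }
  ix <- if (is.null(names(g))) seq_along(g) else names(g)
  for (k in ix) {
    r <- .adam_rec(p[[k]], g[[k]], m[[k]], v[[k]], lr, t, b1, b2, eps)
    p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
  }
  list(p = p, m = m, v = v)
}

# One Adam update over a nested list of tensors.  Entries of `params` absent
# from `grads` are left untouched, which is how freeze contracts are enforced.
adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(state$m)) {
    state$m <- .zeros_like(grads)
    state$v <- .zeros_like(grads)
  }
  state$t <- state$t + 1L
  r <- .adam_rec(params, grads, state$m, state$v, lr, state$t, b1, b2, eps)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}

# Plain gradient-descent update over a nested list of tensors with a
# per-tensor trust-ratio cap: each tensor moves at most `max_rel` of its own
# norm per step.  Used for the adversarial confusion update: its pressure
# vanishes as the scanner head approaches chance level (unlike an
# adaptively rescaled update, which keeps pushing the encoder toward the
# degenerate all-zero representation), and the cap keeps the
# frozen-normalization backward pass from amplifying single steps enough to
# kill ReLU units outright.
sgd_step <- function(params, grads, lr, max_rel = 0.01) {
  rec <- function(p, g) {
    if (!is.list(g)) {
      step <- lr * g
      sn <- sqrt(sum(step^2))
      cap <- max_rel * (sqrt(sum(p^2)) + 1e-3)
      if (is.finite(sn) && sn > cap) step <- step * (cap / sn)
      return(p - step)
    }
    ix <- if (is.null(names(g))) seq_along(g) else names(g)
    for (k in ix) p[[k]] <- rec(p[[k]], g[[k]])
    p
  }
  rec(params, grads)
}

# ---- helpers ----------------------------------------------------------------

# Stack a list of 3D volumes into a (X, Y, Z, 1, N) batch array.
stack_volumes <- function(volumes) {
  if (!is.list(volumes)) volumes <- list(volumes)
  d <- dim(volumes[[1]])
  if (length(d) != 3) stop("volumes must be 3-d arrays")
  for (v in volumes) {
    if (!identical(dim(v), d)) stop("all volumes in a batch must share one shape")
  }
  array(unlist(volumes, use.names = FALSE), dim = c(d, 1L, length(volumes)))
}
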