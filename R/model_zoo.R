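#' Encoder configuration
#'
#' Describes the SFCN-style 3D convolutional encoder: five blocks of
#' \{3x3x3 conv, batch norm, 2x2x2 max pool, ReLU\}, one block of
#' \{1x1x1 conv, batch norm, ReLU\}, and a final block of
#' \{2x2x2 average pool, dropout, flatten\}.  Convolutions preserve spatial
#' extents ("same" padding); max pooling uses floor division on odd extents
#' and passes extents of 1 through unchanged; the average pool is skipped
#' (identity) when any spatial extent is below 2, which supports desk-scale
#' inputs such as 24x24x24.
#'
#' @param input_shape integer(3), spatial extent of input volumes.
#' @param channel_widths integer(6), output channels of the six conv blocks.
#'   Defaults to the original SFCN widths.
#' @param dropout_rate dropout probability in the final block, in `[0, 1)`.
#' @param avgpool_kernel average-pool kernel/stride (fixed at 2).
#' @return An object of class `encoder_config`.
#' @examples
#' cfg <- encoder_config(c(160, 192, 160))
#' feature_length(cfg)  # 768
#' @export
encoder_config <- function(input_shape = c(160L, 192L, 160L),
                           channel_widths = c(32L, 64L, 128L, 256L, 256L, 64L),
                           dropout_rate = 0.2,
                           avgpool_kernel = 2L) {
  input_shape <- as.integer(input_shape)
  channel_widths <- as.integer(channel_widths)
  if (length(input_shape) != 3 || any(input_shape < 1))
    stop("input_shape must be 3 positive integers")
  if (length(channel_widths) != 6 || any(channel_widths < 1))
    stop("channel_widths must be 6 positive counts")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (avgpool_kernel != 2L)
    stop("only avgpool_kernel = 2 is supported")
  structure(list(input_shape = input_shape,
                 channel_widths = channel_widths,
                 dropout_rate = dropout_rate,
                 avgpool_kernel = as.integer(avgpool_kernel)),
            class = "encoder_config")
}

#' Encoder output length
#'
#' Number of features produced by the encoder for a given configuration,
#' obtained by walking the pooling chain: five floor-mode 2x2x2 max pools
#' (extent 1 passes through), then an optional 2x2x2 average pool applied
#' only when all spatial extents are at least 2, times the last channel
#' width.  For the full-size 160x192x160 input with SFCN widths this is
#' 5x6x5 cells pooled to 2x3x2, times 64 channels = 768.
#'
#' @param config an [encoder_config()].
#' @return Integer feature count.
#' @export
feature_length <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  d <- config$input_shape
  for (b in 1:5) {
    d <- ifelse(d == 1L, 1L, d %/% 2L)
    if (any(d < 1L)) stop("spatial extent collapsed to 0 after max pooling")
  }
  if (all(d >= 2L)) d <- d %/% 2L
  as.integer(prod(d) * config$channel_widths[6])
}

#' Create a model bundle
#'
#' A bundle holds the encoder parameters (including batch-norm running
#' statistics, which travel with the model between centers), the disease-head
#' parameters (dense layer + sigmoid) and the scanner-head parameters (dense
#' layer + softmax over `M` scanner types).
#'
#' @param config an [encoder_config()].
#' @param M number of scanner types in the global label space (`M >= 2`).
#' @param seed integer seed for parameter initialization.
#' @return An object of class `model_bundle`.
#' @export
model_bundle <- function(config, M, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  M <- as.integer(M)
  if (M < 2) stop("M must be at least 2")
  F <- feature_length(config)
  with_seed(derive_seed(seed, "init"), {
    encoder <- nn_encoder_init(config)
    disease_head <- list(w = matrix(rnorm(F, sd = sqrt(1 / F)), F, 1), b = 0)
    scanner_head <- list(w = matrix(rnorm(F * M, sd = sqrt(1 / F)), F, M), b = numeric(M))
    structure(list(config = config, M = M, feature_length = F,
                   encoder = encoder,
                   disease_head = disease_head,
                   scanner_head = scanner_head),
              class = "model_bundle")
  })
}

#' Encoder features for a batch of volumes
#'
#' Runs the encoder in evaluation mode (running batch-norm statistics,
#' dropout off), which is deterministic for fixed parameters.
#'
#' @param bundle a [model_bundle()].
#' @param volumes a list of 3D arrays (or a single array) matching the
#'   configured input shape.
#' @param chunk maximum number of volumes pushed through at once.
#' @return An N x F feature matrix.
#' @export
forward_features <- function(bundle, volumes, chunk = 16L) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (!is.list(volumes)) volumes <- list(volumes)
  for (v in volumes) {
    if (!identical(dim(v), as.integer(bundle$config$input_shape)))
      stop("volume shape does not match the encoder input shape")
  }
  n <- length(volumes)
  out <- matrix(0, n, bundle$feature_length)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    x <- stack_volumes(volumes[i:j])
    fw <- nn_encoder_forward(bundle$encoder, bundle$config, x, mode = "eval")
    out[i:j, ] <- fw$features
    i <- j + 1L
  }
  out
}

#' Disease-head probabilities
#'
#' Sigmoid of an affine map of the features: one probability in (0, 1) per
#' row, discriminating diseased from healthy.
#'
#' @param bundle a [model_bundle()].
#' @param features N x F feature matrix from [forward_features()].
#' @return Numeric vector of length N.
#' @export
predict_disease <- function(bundle, features) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (ncol(features) != bundle$feature_length)
    stop("feature width does not match the bundle")
  as.vector(nn_sigmoid(features %*% bundle$disease_head$w + bundle$disease_head$b))
}

#' Scanner-head probabilities
#'
#' Softmax of an affine map of the features: an N x M row-stochastic matrix
#' over the global scanner label space.
#'
#' @inheritParams predict_disease
#' @param M optional expected number of scanner classes; an error is raised
#'   if it disagrees with the bundle.
#' @return N x M matrix with positive entries and unit row sums.
#' @export
predict_scanner <- function(bundle, features, M = NULL) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (ncol(features) != bundle$feature_length)
    stop("feature width does not match the bundle")
  if (!is.null(M) && as.integer(M) != bundle$M)
    stop("scanner label space size does not match the bundle")
  z <- sweep(features %*% bundle$scanner_head$w, 2, bundle$scanner_head$b, "+")
  nn_softmax(z)
}

#' Save / load a model bundle checkpoint
#'
#' Single-file parameter archive (RDS).
#'
#' @param bundle a [model_bundle()].
#' @param path file path.
#' @return `save_bundle` returns `path` invisibly; `load_bundle` returns the
#'   bundle.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "model_bundle")) stop("file does not contain a model bundle")
  b
}

#' Read / write an encoder configuration as YAML
#'
#' @param config an [encoder_config()].
#' @param path file path.
#' @return `read_encoder_config` returns an [encoder_config()].
#' @export
write_encoder_config <- function(config, path) {
  stopifnot(inherits(config, "encoder_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_encoder_config
#' @export
read_encoder_config <- function(path) {
  x <- yaml::read_yaml(path)
  encoder_config(input_shape = x$input_shape,
                 channel_widths = x$channel_widths,
                 dropout_rate = x$dropout_rate,
                 avgpool_kernel = x$avgpool_kernel)
}

#' Recalibrate batch-norm running statistics
#'
#' Recomputes every block's running mean and variance as the exact
#' per-channel moments of the current activations over a reference set of
#' volumes (one pass, layer by layer).  Used between harmonization cycles:
#' adversarial encoder updates shift activation distributions away from the
#' statistics collected during pre-training, and recalibration keeps the
#' frozen-statistics normalization faithful to the data, revives units that
#' would otherwise sit entirely below the ReLU threshold for some centers,
#' and renormalizes each channel's scale.
#'
#' @param bundle a [model_bundle()].
#' @param volumes reference volumes (typically the training set).
#' @param chunk volumes per forward pass.
#' @return The bundle with updated running statistics.
#' @export
recalibrate_bn <- function(bundle, volumes, chunk = 16L) {
  stopifnot(inherits(bundle, "model_bundle"))
  n <- length(volumes)
  nblock <- length(bundle$encoder)
  sums <- vector("list", nblock)
  counts <- numeric(nblock)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    x <- stack_volumes(volumes[i:j])
    h <- x
    for (b in seq_len(nblock)) {
      blk <- bundle$encoder[[b]]
      cv <- conv3d_fw(h, blk$w, blk$b)
      d <- dim(cv)
      V <- prod(d[1:3])
      cs <- channel_sums(cv, cv, as.integer(V), as.integer(d[4]))
      if (is.null(sums[[b]])) sums[[b]] <- list(s = cs$sum, s2 = cs$sum_prod)
      else sums[[b]] <- list(s = sums[[b]]$s + cs$sum,
                             s2 = sums[[b]]$s2 + cs$sum_prod)
      counts[b] <- counts[b] + V * d[5]
      # propagate with this chunk's own statistics: deeper layers then see
      # approximately the geometry that will be in force after this update
      mu <- cs$sum / (V * d[5])
      va <- pmax(cs$sum_prod / (V * d[5]) - mu * mu, 0)
      ivar <- 1 / sqrt(va + 1e-5)
      y <- channel_affine(channel_affine(cv, ivar, -mu * ivar, as.integer(V), as.integer(d[4])),
                          blk$gamma, blk$beta, as.integer(V), as.integer(d[4]))
      if (b <= 5) {
        mp <- maxpool3d_fw(y)
        h <- mp$y * (mp$y > 0)
      } else {
        h <- y * (y > 0)
      }
    }
    i <- j + 1L
  }
  for (b in seq_len(nblock)) {
    mu <- sums[[b]]$s / counts[b]
    va <- pmax(sums[[b]]$s2 / counts[b] - mu * mu, 0)
    bundle$encoder[[b]]$run_mean <- mu
    bundle$encoder[[b]]$run_var <- va
  }
  bundle
}
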