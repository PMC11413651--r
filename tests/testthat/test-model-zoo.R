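# Encoder shape contracts, head algebra, and the correctness of the manual
# backpropagation against finite differences.

# Independent shape-chain oracle: walk the pooling arithmetic directly.
shape_oracle <- function(shape, last_width) {
  d <- shape
  for (i in 1:5) d <- ifelse(d == 1, 1, d %/% 2)
  if (all(d >= 2)) d <- d %/% 2
  prod(d) * last_width
}

test_that("feature_length reproduces the published 768 and the shape oracle", {
  expect_identical(feature_length(encoder_config(c(160L, 192L, 160L))), 768L)
  cases <- list(
    list(shape = c(64L, 64L, 64L), widths = c(2L, 2L, 2L, 2L, 2L, 16L)),
    list(shape = c(24L, 24L, 24L), widths = c(2L, 2L, 2L, 2L, 2L, 8L)),
    list(shape = c(32L, 48L, 20L), widths = c(2L, 2L, 2L, 2L, 2L, 6L)),
    list(shape = c(96L, 96L, 96L), widths = c(4L, 4L, 4L, 4L, 4L, 10L))
  )
  for (cs in cases) {
    expect_identical(
      feature_length(encoder_config(cs$shape, channel_widths = cs$widths)),
      as.integer(shape_oracle(cs$shape, cs$widths[6])))
  }
  # the two spec'd desk-scale values
  expect_identical(feature_length(encoder_config(c(64L, 64L, 64L),
    channel_widths = c(2L, 2L, 2L, 2L, 2L, 16L))), 16L)
  expect_identical(feature_length(encoder_config(c(24L, 24L, 24L),
    channel_widths = c(2L, 2L, 2L, 2L, 2L, 8L))), 8L)
})

test_that("encoder configuration is validated", {
  expect_error(encoder_config(c(8, 8)), "3 positive")
  expect_error(encoder_config(c(8, 8, 8), channel_widths = 1:5), "6 positive")
  expect_error(encoder_config(c(8, 8, 8), dropout_rate = 1), "dropout")
})

test_that("evaluation-mode features are deterministic and well-shaped", {
  b <- tiny_bundle()
  vols <- tiny_volumes(4)
  f1 <- forward_features(b, vols)
  f2 <- forward_features(b, vols)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(4L, b$feature_length))
  expect_true(all(is.finite(f1)))
  # degenerate all-zero input stays finite
  z <- forward_features(b, list(array(0, dim = c(8, 8, 8))))
  expect_true(all(is.finite(z)))
  expect_error(forward_features(b, list(array(0, dim = c(4, 4, 4)))), "shape")
})

test_that("disease head is a sigmoid affine map", {
  b <- tiny_bundle()
  f <- forward_features(b, tiny_volumes(3))
  b0 <- b
  b0$disease_head$w[] <- 0
  b0$disease_head$b <- 0
  expect_equal(predict_disease(b0, f), rep(0.5, 3))
  # hand-set 2-feature toy against scalar arithmetic
  cfg2 <- tiny_config(widths = c(2L, 2L, 2L, 2L, 2L, 2L))
  b2 <- model_bundle(cfg2, 2L, seed = 1)
  b2$disease_head$w <- matrix(c(0.5, -1), 2, 1)
  b2$disease_head$b <- 0.25
  feats <- rbind(c(1, 2), c(0.3, -0.4))
  expected <- 1 / (1 + exp(-(feats %*% c(0.5, -1) + 0.25)))
  expect_equal(predict_disease(b2, feats), as.vector(expected), tolerance = 1e-12)
  # monotone in the logit
  expect_gt(predict_disease(b2, rbind(c(2, 0)))[1],
            predict_disease(b2, rbind(c(1, 0)))[1])
})

test_that("scanner head rows are probabilities on the simplex", {
  b <- tiny_bundle(M = 4L)
  f <- forward_features(b, tiny_volumes(5))
  P <- predict_scanner(b, f)
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)
  expect_true(all(P > 0))
  b0 <- b
  b0$scanner_head$w[] <- 0
  b0$scanner_head$b[] <- 0
  expect_equal(predict_scanner(b0, f), matrix(0.25, 5, 4))
  # hand-set 2-class toy
  cfg2 <- tiny_config(widths = c(2L, 2L, 2L, 2L, 2L, 2L))
  b2 <- model_bundle(cfg2, 2L, seed = 1)
  b2$scanner_head$w <- matrix(c(1, 0, 0, 1), 2, 2)
  b2$scanner_head$b <- c(0, 0)
  z <- c(1.5, -0.5)
  expect_equal(predict_scanner(b2, rbind(z))[1, ],
               exp(z) / sum(exp(z)), tolerance = 1e-12)
  expect_error(predict_scanner(b, f, M = 7), "label space")
})

test_that("backpropagated gradients match finite differences for all losses", {
  b <- tiny_bundle(M = 3L)
  batch <- tiny_batch(b, n = 3L)
  h <- asNamespace("harmonytm")
  x <- h$stack_volumes(batch$volumes)

  loss_of <- function(bundle, which) {
    fw <- h$nn_encoder_forward(bundle$encoder, bundle$config, x, mode = "train")
    feats <- fw$features
    if (which == "task") {
      p <- as.vector(h$nn_sigmoid(feats %*% bundle$disease_head$w +
                                    bundle$disease_head$b))
      loss_pd(batch$y_disease, h$.clip01(p))
    } else {
      P <- h$nn_softmax(sweep(feats %*% bundle$scanner_head$w, 2,
                              bundle$scanner_head$b, "+"))
      if (which == "scanner") loss_scanner(batch$y_scanner, P)
      else loss_confusion(P)
    }
  }
  grad_of <- function(bundle, which) {
    fw <- h$nn_encoder_forward(bundle$encoder, bundle$config, x,
                               mode = "train", want_cache = TRUE)
    feats <- fw$features
    N <- batch$N
    if (which == "task") {
      p <- as.vector(h$nn_sigmoid(feats %*% bundle$disease_head$w +
                                    bundle$disease_head$b))
      gfeat <- matrix((p - batch$y_disease) / N, N, 1) %*% t(bundle$disease_head$w)
    } else {
      P <- h$nn_softmax(sweep(feats %*% bundle$scanner_head$w, 2,
                              bundle$scanner_head$b, "+"))
      dz <- if (which == "scanner") (P - batch$y_scanner) / N
            else (P - 1 / bundle$M) / N
      gfeat <- dz %*% t(bundle$scanner_head$w)
    }
    h$nn_encoder_backward(bundle$encoder, fw$cache, gfeat)
  }

  eps <- 1e-5
  set.seed(99)
  for (which in c("task", "scanner", "conf")) {
    g <- grad_of(b, which)
    for (trial in 1:12) {
      blk <- sample(1:6, 1)
      field <- sample(c("w", "b", "gamma", "beta"), 1)
      idx <- sample(length(g[[blk]][[field]]), 1)
      up <- b; dn <- b
      up$encoder[[blk]][[field]][idx] <- up$encoder[[blk]][[field]][idx] + eps
      dn$encoder[[blk]][[field]][idx] <- dn$encoder[[blk]][[field]][idx] - eps
      num <- (loss_of(up, which) - loss_of(dn, which)) / (2 * eps)
      expect_lt(abs(num - g[[blk]][[field]][idx]), 1e-6)
    }
  }
})

test_that("checkpoints and YAML configs round-trip", {
  b <- tiny_bundle()
  path <- withr::local_tempfile(fileext = ".rds")
  save_bundle(b, path)
  expect_identical(load_bundle(path), b)

  cfg <- tiny_config()
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_encoder_config(cfg, yml)
  expect_equal(read_encoder_config(yml), cfg)
})

test_that("batch-norm recalibration matches the activation moments", {
  b <- tiny_bundle()
  vols <- tiny_volumes(12)
  b2 <- recalibrate_bn(b, vols, chunk = 12L)
  # after recalibration over the same data in one chunk, eval-mode post-BN
  # activations have approximately zero mean per channel in block 1
  h <- asNamespace("harmonytm")
  x <- h$stack_volumes(vols)
  cv <- h$conv3d_fw(x, b2$encoder[[1]]$w, b2$encoder[[1]]$b)
  d <- dim(cv)
  cs <- h$channel_sums(cv, cv, as.integer(prod(d[1:3])), as.integer(d[4]))
  mu <- cs$sum / (prod(d[1:3]) * d[5])
  expect_equal(as.vector(mu), as.vector(b2$encoder[[1]]$run_mean),
               tolerance = 1e-10)
})
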