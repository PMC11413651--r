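# Task metrics, scanner-leakage metrics and the PCA + probe audit, each
# against an independent oracle.

brute_force_auroc <- function(y, p) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

test_that("binary metrics match hand-computed values", {
  perfect <- binary_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unlist(perfect), c(accuracy = 1, auroc = 1, sensitivity = 1,
                                  specificity = 1, precision = 1, f1 = 1))
  m <- binary_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$auroc, 0.75)
  expect_equal(m$auroc, brute_force_auroc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)))
  # constant score: chance AUROC through tie handling
  expect_equal(binary_metrics(c(1, 0, 1, 0), rep(0.5, 4))$auroc, 0.5)
  expect_error(binary_metrics(c(1, 1), c(0.2, 0.9)), "both classes")
})

test_that("the rank-based AUROC equals the pairwise estimator", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    expect_equal(auroc(y, p), brute_force_auroc(y, p), tolerance = 1e-12)
  }
})

test_that("weighted multiclass metrics equal the support-weighted oracle", {
  # diagonal confusion
  P <- diag(3)[c(1, 2, 3, 1), ]
  m <- multiclass_weighted_metrics(c(1, 2, 3, 1), P)
  expect_equal(m$metrics$accuracy, 1)
  expect_equal(m$metrics$f1, 1)
  expect_equal(diag(m$confusion), c(2L, 1L, 1L))

  # supports (2,1,1), one error: true class 1 predicted as 2
  y <- c(1, 1, 2, 3)
  pred <- c(1, 2, 2, 3)
  P <- diag(3)[pred, ]
  m <- multiclass_weighted_metrics(y, P)
  # per-class one-vs-rest oracle, weights 2/4, 1/4, 1/4
  sens <- c(1/2, 1, 1); prec <- c(1, 1/2, 1)
  spec <- c(1, 2/3, 1)
  f1 <- 2 * prec * sens / (prec + sens)
  w <- c(2, 1, 1) / 4
  expect_equal(m$metrics$accuracy, 3/4)
  expect_equal(m$metrics$sensitivity, sum(w * sens))
  expect_equal(m$metrics$specificity, sum(w * spec))
  expect_equal(m$metrics$precision, sum(w * prec))
  expect_equal(m$metrics$f1, sum(w * f1))
  # confusion marginals conserve the test counts
  expect_equal(rowSums(m$confusion), c(2, 1, 1))
  expect_equal(sum(m$confusion), 4)

  # all predictions equal to the majority class
  y <- c(1, 1, 1, 2, 3)
  P <- diag(3)[rep(1, 5), ]
  m <- multiclass_weighted_metrics(y, P)
  expect_equal(m$metrics$sensitivity, 3/5)  # majority share
  expect_error(multiclass_weighted_metrics(c(1, 4), diag(3)[c(1, 1), ]),
               "label space")
})

test_that("weighted metrics match a randomized support-weighted oracle", {
  set.seed(202)
  for (i in 1:30) {
    M <- sample(2:5, 1)
    n <- sample(10:40, 1)
    y <- sample(M, n, replace = TRUE)
    if (length(unique(y)) < M) y[seq_len(M)] <- seq_len(M)
    P <- matrix(runif(n * M), n, M)
    m <- multiclass_weighted_metrics(y, P)
    pred <- max.col(P, ties.method = "first")
    ws <- vapply(seq_len(M), function(c) sum(y == c), numeric(1)) / n
    sens <- vapply(seq_len(M), function(c) {
      if (sum(y == c) == 0) 0 else mean(pred[y == c] == c)
    }, numeric(1))
    expect_equal(m$metrics$accuracy, mean(pred == y))
    expect_equal(m$metrics$sensitivity, sum(ws * sens))
  }
})

test_that("PCA probes separate constructed clouds and not shuffled labels", {
  set.seed(55)
  n <- 1000
  lab <- rep(1:2, each = n / 2)
  # two clouds separated along the first axis, spread tiny vs separation
  X <- cbind(ifelse(lab == 1, -5, 5) + rnorm(n, sd = 0.2),
             rnorm(n, sd = 1), rnorm(n, sd = 0.5), rep(1, n))  # constant col
  pr <- pca_probe(X, lab, sample(lab))
  expect_equal(pr$probe_acc$scanner$mode1, 1.0)
  # shuffled labels: chance +/- 5 points
  expect_lt(abs(pr$probe_acc$disease$both - 0.5), 0.05)  # n = 1000, 200 held out
  # PCA scores centered; leading mode carries the most variance
  expect_lt(max(abs(colMeans(pr$coords))), 1e-8)
  expect_gte(var(pr$coords[, 1]), var(pr$coords[, 2]))
})

test_that("the full-feature linear probe decodes a separable labeling", {
  set.seed(66)
  X <- matrix(rnorm(200 * 4), 200, 4)
  y <- as.integer(X[, 2] > 0) + 1L
  tr <- 1:150
  acc <- linear_probe(X[tr, ], y[tr], X[-tr, ], y[-tr])
  expect_gt(acc, 0.95)
})

test_that("evaluation reports serialize to JSON and CSV", {
  spec <- toy_cohort_spec(seed = 44, n_per_center = c(10L, 10L, 10L))
  shards <- generate_cohort(spec)
  sp <- split_cohort(shards, 0.3, seed = 1)
  b <- model_bundle(tiny_config(widths = c(4L, 4L, 8L, 8L, 8L, 8L)), 2L, seed = 1)
  rep <- evaluate_bundle(b, sp$train, sp$test, seed = 1)
  expect_s3_class(rep, "eval_report")
  expect_true(all(unlist(rep$disease_metrics) >= 0 &
                    unlist(rep$disease_metrics) <= 1))
  expect_equal(sum(rep$confusion), length(sp$test$volumes))
  dir <- tempfile("report")
  write_report(rep, dir, "before")
  expect_true(file.exists(file.path(dir, "before.json")))
  expect_true(file.exists(file.path(dir, "before_confusion.csv")))
  expect_true(file.exists(file.path(dir, "before_pca_coords.csv")))
  parsed <- jsonlite::read_json(file.path(dir, "before.json"))
  expect_named(parsed, c("disease_metrics", "scanner_metrics", "feature_probe",
                         "pca_probe", "pca_var_explained"))
})
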