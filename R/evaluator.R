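# Task metrics, scanner-leakage metrics and the PCA + linear-probe
# representation audit.

#' Area under the ROC curve
#'
#' Rank-based (Wilcoxon) estimator; tied scores count one half, matching the
#' pairwise-comparison definition exactly.
#'
#' @param y binary labels.
#' @param p scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(y, p) {
  if (length(unique(y)) < 2) stop("AUROC undefined for a single class")
  r <- rank(p, ties.method = "average")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary disease-classification metrics
#'
#' Accuracy, AUROC, sensitivity, specificity, precision and F1 at a fixed
#' decision threshold (AUROC is threshold-free).  Ratios with a zero
#' denominator (e.g. precision with no positive predictions) are reported
#' as 0.
#'
#' @param y binary labels; both classes must be present.
#' @param p predicted probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return Named list with `accuracy`, `auroc`, `sensitivity`,
#'   `specificity`, `precision`, `f1`.
#' @export
binary_metrics <- function(y, p, threshold = 0.5) {
  if (length(y) != length(p)) stop("y and p must have equal length")
  if (length(unique(y)) < 2) stop("both classes must be present")
  pred <- as.integer(p > threshold)
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  list(accuracy = (tp + tn) / length(y),
       auroc = auroc(y, p),
       sensitivity = sens, specificity = spec, precision = prec, f1 = f1)
}

#' Weighted multiclass scanner metrics and confusion matrix
#'
#' Argmax decision rule.  Sensitivity, specificity, precision and F1 are
#' computed per class one-vs-rest and averaged with weights proportional to
#' class support; accuracy is the overall fraction correct.  The confusion
#' matrix follows the rows-are-actual convention.
#'
#' @param y integer class ids in `1..M`.
#' @param P N x M score matrix (rows need not be normalized; argmax only).
#' @param M number of classes; defaults to `ncol(P)`.
#' @return List with `metrics` (accuracy, sensitivity, specificity,
#'   precision, f1), `per_class` data frame and `confusion` (M x M counts,
#'   rows = actual).
#' @export
multiclass_weighted_metrics <- function(y, P, M = ncol(P)) {
  y <- as.integer(y)
  if (any(y < 1 | y > M)) stop("class id outside the label space 1..M")
  if (nrow(P) != length(y)) stop("y and P must agree in length")
  pred <- max.col(P, ties.method = "first")
  N <- length(y)
  conf <- matrix(0L, M, M)
  for (i in seq_len(N)) conf[y[i], pred[i]] <- conf[y[i], pred[i]] + 1L
  support <- rowSums(conf)
  sens <- spec <- prec <- f1 <- numeric(M)
  for (c in seq_len(M)) {
    tp <- conf[c, c]
    fn <- support[c] - tp
    fp <- sum(conf[, c]) - tp
    tn <- N - tp - fn - fp
    sens[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec[c] <- if (tn + fp > 0) tn / (tn + fp) else 0
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[c] <- if (prec[c] + sens[c] > 0) 2 * prec[c] * sens[c] / (prec[c] + sens[c]) else 0
  }
  w <- support / N
  list(metrics = list(accuracy = sum(diag(conf)) / N,
                      sensitivity = sum(w * sens),
                      specificity = sum(w * spec),
                      precision = sum(w * prec),
                      f1 = sum(w * f1)),
       per_class = data.frame(class = seq_len(M), support = support,
                              sensitivity = sens, specificity = spec,
                              precision = prec, f1 = f1),
       confusion = conf)
}

# ---- ridge-penalized logistic probes ---------------------------------------

# Multinomial logistic regression with a fixed L2 penalty on the weights
# (not the intercept), fitted deterministically by L-BFGS from a zero start.
# This is the linear probe used throughout the representation audit.
ridge_logistic_fit <- function(X, y, levels, lambda = 1, maxit = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- length(levels)
  if (K < 2) stop("probe requires at least 2 classes")
  p <- ncol(X)
  yi <- match(y, levels)
  if (any(is.na(yi))) stop("labels outside the stated levels")
  Xi <- cbind(1, X)
  Yh <- matrix(0, n, K)
  Yh[cbind(seq_len(n), yi)] <- 1
  obj <- function(par) {
    W <- matrix(par, p + 1, K)
    Z <- Xi %*% W
    Z <- Z - apply(Z, 1, max)
    lse <- log(rowSums(exp(Z)))
    -sum(Z[cbind(seq_len(n), yi)] - lse) / n +
      lambda / (2 * n) * sum(W[-1, , drop = FALSE]^2)
  }
  grad <- function(par) {
    W <- matrix(par, p + 1, K)
    Z <- Xi %*% W
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    P <- E / rowSums(E)
    G <- crossprod(Xi, P - Yh) / n
    G[-1, ] <- G[-1, ] + lambda / n * W[-1, , drop = FALSE]
    as.vector(G)
  }
  fit <- optim(numeric((p + 1) * K), obj, grad, method = "L-BFGS-B",
               control = list(maxit = maxit))
  structure(list(W = matrix(fit$par, p + 1, K), levels = levels),
            class = "ridge_logistic")
}

predict_ridge_logistic <- function(fit, X) {
  Z <- cbind(1, as.matrix(X)) %*% fit$W
  fit$levels[max.col(Z, ties.method = "first")]
}

#' Held-out accuracy of a linear probe
#'
#' Fits a ridge-penalized logistic probe on training features and reports
#' accuracy on held-out features.  Used to measure how linearly decodable a
#' label (scanner type, disease status) is from a representation.  Features
#' are standardized with the training set's means and standard deviations,
#' making the probe (and its fixed ridge strength) invariant to the scale
#' of individual feature dimensions.
#'
#' @param X_train,y_train training features and labels.
#' @param X_test,y_test held-out features and labels.
#' @param lambda ridge strength (default 1).
#' @return Held-out accuracy.
#' @export
linear_probe <- function(X_train, y_train, X_test, y_test, lambda = 1) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  mu <- colMeans(X_train)
  sdev <- apply(X_train, 2, sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  X_train <- sweep(sweep(X_train, 2, mu, "-"), 2, sdev, "/")
  X_test <- sweep(sweep(X_test, 2, mu, "-"), 2, sdev, "/")
  levels <- sort(unique(c(y_train, y_test)))
  fit <- ridge_logistic_fit(X_train, y_train, levels, lambda)
  mean(predict_ridge_logistic(fit, as.matrix(X_test)) == y_test)
}

# Stratified index split: per class, floor(frac * n_c) test samples (at
# least one when the class has >= min_for_test members).
stratified_split <- function(labels, test_frac, seed, min_for_test = 2L) {
  with_seed(seed, {
    test <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      k <- floor(test_frac * length(idx))
      if (k == 0 && length(idx) >= min_for_test) k <- 1L
      if (k > 0) test <- c(test, sample(idx, k))
    }
    sort(test)
  })
}

#' PCA + linear-probe representation audit
#'
#' Centers the feature matrix, computes the first two principal modes, and
#' fits ridge-logistic probes on mode 1 alone, mode 2 alone, and both
#' jointly, for the scanner labels and the disease labels.  Probe accuracy
#' is measured on a held-out part of a seeded stratified 80/20 split, which
#' avoids the trivially optimistic in-sample separability of
#' high-dimensional probes.  Constant feature columns are dropped before the
#' PCA.
#'
#' @param features n x F matrix (n > 2, F >= 2).
#' @param labels_scanner integer scanner ids.
#' @param labels_disease binary disease labels.
#' @param seed split seed.
#' @param test_frac held-out fraction (default 0.2).
#' @param lambda ridge strength of the probes.
#' @return List with `coords` (n x 2 PCA scores), `var_explained`, and
#'   `probe_acc`: per-label-set accuracies for `mode1`, `mode2`, `both`.
#' @export
pca_probe <- function(features, labels_scanner, labels_disease,
                      seed = 1L, test_frac = 0.2, lambda = 1) {
  features <- as.matrix(features)
  if (nrow(features) <= 2) stop("need more than 2 samples")
  keep <- apply(features, 2, function(col) sd(col) > 1e-12)
  X <- features[, keep, drop = FALSE]
  if (ncol(X) < 2) {
    # representation collapsed to (at most) a single varying direction:
    # report flat coordinates and chance-free NA probes rather than failing
    warning("fewer than 2 non-constant features; representation is degenerate")
    na3 <- list(mode1 = NA_real_, mode2 = NA_real_, both = NA_real_)
    return(list(coords = matrix(0, nrow(features), 2),
                var_explained = c(NA_real_, NA_real_),
                probe_acc = list(scanner = na3, disease = na3)))
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  sc <- pc$x[, 1:2, drop = FALSE]
  probe_one <- function(labels, tag) {
    idx <- stratified_split(labels, test_frac, derive_seed(seed, tag))
    tr <- setdiff(seq_len(nrow(sc)), idx)
    if (length(idx) == 0 || length(unique(labels[tr])) < 2)
      return(list(mode1 = NA_real_, mode2 = NA_real_, both = NA_real_))
    list(
      mode1 = linear_probe(sc[tr, 1, drop = FALSE], labels[tr],
                           sc[idx, 1, drop = FALSE], labels[idx], lambda),
      mode2 = linear_probe(sc[tr, 2, drop = FALSE], labels[tr],
                           sc[idx, 2, drop = FALSE], labels[idx], lambda),
      both = linear_probe(sc[tr, , drop = FALSE], labels[tr],
                          sc[idx, , drop = FALSE], labels[idx], lambda)
    )
  }
  list(coords = sc,
       var_explained = (pc$sdev[1:2]^2) / sum(pc$sdev^2),
       probe_acc = list(scanner = probe_one(labels_scanner, "pca_scanner"),
                        disease = probe_one(labels_disease, "pca_disease")))
}

#' Full evaluation report for a trained bundle
#'
#' Computes held-out disease metrics (disease head), scanner-leakage metrics
#' and confusion matrix (scanner head), a held-out full-feature linear probe
#' for scanner and disease labels (fitted on training features), and the
#' PCA + probe audit over the features of all samples.
#'
#' @param bundle a [model_bundle()].
#' @param train,test sample lists with `volumes`, `disease_labels`,
#'   `scanner_labels` (see [pool_shards()]).
#' @param seed seed for probe splits.
#' @return An `eval_report` list.
#' @export
evaluate_bundle <- function(bundle, train, test, seed = 1L) {
  ftr <- forward_features(bundle, train$volumes)
  fte <- forward_features(bundle, test$volumes)
  p_dis <- predict_disease(bundle, fte)
  P_sc <- predict_scanner(bundle, fte)
  dm <- binary_metrics(test$disease_labels, p_dis)
  mm <- multiclass_weighted_metrics(test$scanner_labels, P_sc, bundle$M)
  feats_all <- rbind(ftr, fte)
  audit <- pca_probe(feats_all,
                     c(train$scanner_labels, test$scanner_labels),
                     c(train$disease_labels, test$disease_labels),
                     seed = derive_seed(seed, "audit"))
  probe_scanner <- linear_probe(ftr, train$scanner_labels, fte, test$scanner_labels)
  probe_disease <- linear_probe(ftr, train$disease_labels, fte, test$disease_labels)
  structure(list(disease_metrics = dm,
                 scanner_metrics = mm$metrics,
                 scanner_per_class = mm$per_class,
                 confusion = mm$confusion,
                 feature_probe = list(scanner = probe_scanner,
                                      disease = probe_disease),
                 pca = audit),
            class = "eval_report")
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON plus plot-ready CSVs for the confusion matrix
#' and PCA coordinates.
#'
#' @param report an `eval_report` from [evaluate_bundle()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @export
write_report <- function(report, dir, prefix = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  core <- list(disease_metrics = report$disease_metrics,
               scanner_metrics = report$scanner_metrics,
               feature_probe = report$feature_probe,
               pca_probe = report$pca$probe_acc,
               pca_var_explained = report$pca$var_explained)
  jsonlite::write_json(core, file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(report$confusion),
            file.path(dir, paste0(prefix, "_confusion.csv")), row.names = FALSE)
  write.csv(as.data.frame(report$pca$coords),
            file.path(dir, paste0(prefix, "_pca_coords.csv")), row.names = FALSE)
  invisible(dir)
}
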