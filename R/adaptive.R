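#' Adaptive scanner-unlearning schedule
#'
#' Production harmonization loop used by [run_experiment()].  Each cycle
#' applies the per-batch three-loss procedure (in its combined-update form,
#' see [harmonization_step()]) over the training cohort with the traveling
#' or centralized schedule, wrapped in three pieces of convergence
#' machinery, all driven exclusively by training-side diagnostics:
#'
#' \enumerate{
#'   \item \emph{Optimal adversary refits.}  At every cycle boundary the
#'     scanner head is refitted to convergence on the current encoder
#'     features (a convex ridge-logistic fit).  The confusion update then
#'     pushes against the best linear scanner readout rather than a lagging
#'     online approximation of it, which is the condition under which the
#'     adversarial game removes linearly decodable scanner information.
#'   \item \emph{Balance controller with rollback.}  The confusion weight
#'     is doubled while the scanner probe on a held-in validation split of
#'     the training data remains above chance, and the run is rolled back
#'     to its best checkpoint (with the weight halved) whenever disease
#'     accuracy on that split drops more than `disease_tolerance` below its
#'     pre-harmonization value.  Excursions into representation collapse
#'     are thereby undone instead of being absorbing.
#'   \item \emph{Checkpoint selection.}  The returned model is the cycle
#'     checkpoint with the lowest validation scanner-probe accuracy among
#'     those whose validation disease accuracy stayed within tolerance —
#'     the realization of "trained until convergence" for an adversarial
#'     objective whose trajectory is not monotone.
#' }
#'
#' @param shards training cohort as a list of center shards.
#' @param bundle pre-trained [model_bundle()] (see [pretrain()]).
#' @param config a [tm_config()]; `lr_conf_scale` seeds the controller's
#'   initial confusion weight.
#' @param approach `"tm"` (traveling schedule, single-center batches) or
#'   `"central"` (pooled shuffled batches).
#' @param cycles number of harmonization cycles (default 8).
#' @param conf_weight_max controller ceiling for the confusion weight.
#' @param disease_tolerance allowed drop in validation disease accuracy.
#' @param val_frac fraction of the training pool held in for the
#'   controller's diagnostics.
#' @param probe_lambda ridge strength of the refits and diagnostics probes.
#' @param verbose print per-cycle controller state.
#' @return `list(bundle, history, controller, selected_cycle)`; `controller`
#'   is a data frame with one row per cycle (confusion weight, validation
#'   disease accuracy and scanner-probe accuracy, rollback flag).
#' @export
harmonize_adaptive <- function(shards, bundle, config,
                               approach = c("tm", "central"),
                               cycles = 8L,
                               conf_weight_max = 64,
                               disease_tolerance = 0.05,
                               val_frac = 0.3,
                               probe_lambda = 1,
                               verbose = FALSE) {
  approach <- match.arg(approach)
  stopifnot(inherits(bundle, "model_bundle"), inherits(config, "tm_config"))
  pool <- pool_shards(shards)
  M <- bundle$M

  state_of <- function(b) {
    n <- length(pool$volumes)
    f <- forward_features(b, pool$volumes)
    ds <- ps <- numeric(2)
    for (k in 1:2) {
      idx <- with_seed(derive_seed(config$seed, "ctrl_split", k),
                       sample(n, max(2L, floor(val_frac * n))))
      tr <- setdiff(seq_len(n), idx)
      ds[k] <- mean(as.integer(predict_disease(b, f[idx, , drop = FALSE]) > 0.5) ==
                      pool$disease_labels[idx])
      ps[k] <- tryCatch(
        linear_probe(f[tr, , drop = FALSE], pool$scanner_labels[tr],
                     f[idx, , drop = FALSE], pool$scanner_labels[idx],
                     lambda = probe_lambda),
        error = function(e) 1)
    }
    c(dis = mean(ds), probe = mean(ps))
  }

  refit_head <- function(b) {
    f <- forward_features(b, pool$volumes)
    Xs <- scale_probe_features(f)
    mu <- attr(Xs, "center"); sdev <- attr(Xs, "scale")
    fit <- ridge_logistic_fit(Xs, pool$scanner_labels,
                              levels = seq_len(M), lambda = probe_lambda)
    # fold the standardization into the head weights
    W <- fit$W[-1, , drop = FALSE] / sdev
    b$scanner_head$w <- W
    b$scanner_head$b <- fit$W[1, ] - as.vector(mu %*% W)
    b
  }

  st0 <- state_of(bundle)
  best <- list(score = st0[["probe"]], bundle = bundle, cycle = 0L)
  w <- config$lr_conf_scale
  chance <- 1 / M
  opt <- harmon_optimizers()
  hist <- list()
  ctrl <- list()
  crashed_prev <- FALSE
  for (cyc in seq_len(cycles)) {
    bundle <- refit_head(bundle)
    opt$scanner <- adam_init()
    cfg <- config
    cfg$n_cycles <- 1L
    cfg$seed <- derive_seed(config$seed, "harmonize", cyc)
    cfg$lr_initial <- config$lr_initial * config$lr_decay^(cyc - 1)
    cfg$lr_conf_scale <- w
    r <- if (approach == "tm") {
      run_tm(shards, bundle, cfg, mode = "harmonize", opt = opt, combined = TRUE)
    } else {
      run_centralized(pool, bundle, cfg, mode = "harmonize", opt = opt,
                      combined = TRUE)
    }
    bundle <- r$bundle
    opt <- r$opt
    r$history$cycle <- cyc - 1L
    hist[[cyc]] <- r$history
    st <- state_of(bundle)
    crashed <- st[["dis"]] < st0[["dis"]] - disease_tolerance
    if (!crashed && st[["probe"]] < best$score) {
      best <- list(score = st[["probe"]], bundle = bundle, cycle = cyc)
    }
    # a single below-tolerance cycle is a transient the task update usually
    # repairs (and the productive unlearning happens during these
    # excursions); roll back only when the crash persists
    rolled <- FALSE
    if (crashed && crashed_prev) {
      bundle <- best$bundle
      opt$task <- adam_init()
      opt$conf <- adam_init()
      w <- max(w / 2, 0.25)
      rolled <- TRUE
      crashed <- FALSE  # handled; next cycle starts from a healthy state
    } else if (!crashed && st[["probe"]] > chance + 0.05) {
      w <- min(w * 2, conf_weight_max)
    }
    crashed_prev <- crashed
    ctrl[[cyc]] <- data.frame(cycle = cyc, conf_weight = cfg$lr_conf_scale,
                              val_disease = st[["dis"]],
                              val_scanner_probe = st[["probe"]],
                              rolled_back = rolled)
    if (verbose)
      message(sprintf("cycle %d: w=%.2g val dis=%.3f probe=%.3f%s",
                      cyc, cfg$lr_conf_scale, st[["dis"]], st[["probe"]],
                      if (crashed) " [rollback]" else ""))
  }
  list(bundle = best$bundle,
       history = do.call(rbind, hist),
       controller = do.call(rbind, ctrl),
       selected_cycle = best$cycle)
}

# Standardize probe features, keeping the transform as attributes so it can
# be folded back into affine head parameters.
scale_probe_features <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
  out <- Xs
  attr(out, "center") <- mu
  attr(out, "scale") <- sdev
  out
}
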