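#' Pool center shards into one sample list
#'
#' @param shards list of center shards.
#' @return A list with parallel `volumes`, `disease_labels`,
#'   `scanner_labels`, `center_ids` covering every sample in the cohort.
#' @export
pool_shards <- function(shards) {
  if (length(shards) == 0) stop("empty cohort")
  list(
    volumes = do.call(c, lapply(shards, function(s) s$volumes)),
    disease_labels = do.call(c, lapply(shards, function(s) s$disease_labels)),
    scanner_labels = do.call(c, lapply(shards, function(s) s$scanner_labels)),
    center_ids = do.call(c, lapply(shards, function(s)
      rep(s$center_id, length(s$volumes))))
  )
}

#' Centralized training baseline
#'
#' Identical architecture, losses and per-batch updates as the traveling
#' model, but trained on the pooled cohort: every epoch shuffles the pool
#' and draws batches of `max_batch` (plus a final remainder), so batches may
#' mix data from several centers.  The number of epochs equals
#' `config$n_cycles`, which makes the gradient-step count match the
#' traveling-model budget exactly (same pool, same batch rule).
#'
#' @param pool pooled samples from [pool_shards()].
#' @param bundle a [model_bundle()].
#' @param config a [tm_config()]; note the centralized baseline
#'   conventionally uses a larger initial learning rate than the traveling
#'   model (e.g. `1e-3` vs `1e-4` at full scale).
#' @param mode one of `"harmonize"`, `"task_only"`, `"scanner_head"`.
#' @param opt optional optimizer states to continue from.
#' @param combined passed to [harmonization_step()].
#' @return `list(bundle, history, opt)`; `history` has one row per epoch
#'   with mean losses and `n_mixed`, the number of batches that mixed two or
#'   more centers.
#' @export
run_centralized <- function(pool, bundle, config,
                            mode = c("harmonize", "task_only", "scanner_head"),
                            opt = NULL, combined = FALSE) {
  mode <- match.arg(mode)
  n <- length(pool$volumes)
  if (n == 0) stop("empty pool")
  stopifnot(inherits(bundle, "model_bundle"), inherits(config, "tm_config"))
  if (is.null(opt)) opt <- harmon_optimizers()
  hist <- list()
  with_seed(derive_seed(config$seed, paste0("central_", mode)), {
    for (epoch in seq_len(config$n_cycles) - 1L) {
      lr <- lr_at(epoch, config)
      ord <- if (n == 1) 1L else sample(n)
      plan <- batch_plan(n, config$max_batch)
      pos <- 0L
      recs <- matrix(NA_real_, length(plan), 4)
      n_mixed <- 0L
      for (bi in seq_along(plan)) {
        idx <- ord[(pos + 1L):(pos + plan[bi])]
        pos <- pos + plan[bi]
        if (length(unique(pool$center_ids[idx])) > 1) n_mixed <- n_mixed + 1L
        batch <- tm_batch(pool$volumes[idx], pool$disease_labels[idx],
                          pool$scanner_labels[idx], bundle$M, NA)
        if (mode == "harmonize") {
          r <- harmonization_step(batch, bundle, opt,
                                  lr * config$lr_task_scale,
                                  lr * config$lr_scanner_scale,
                                  lr * config$lr_conf_scale,
                                  combined = combined)
          bundle <- r$bundle; opt <- r$opt
          recs[bi, ] <- c(r$record$l_pd, r$record$l_sc, r$record$l_conf,
                          r$record$l_total)
        } else if (mode == "task_only") {
          r <- step_task(batch, bundle, opt, lr)
          bundle <- r$bundle; opt <- r$opt
          recs[bi, 1] <- r$loss
        } else {
          r <- step_scanner(batch, bundle, opt, lr)
          bundle <- r$bundle; opt <- r$opt
          recs[bi, 2] <- r$loss
        }
      }
      hist[[length(hist) + 1L]] <- data.frame(
        cycle = epoch, center = "pooled",
        l_pd = mean(recs[, 1]), l_sc = mean(recs[, 2]),
        l_conf = mean(recs[, 3]), l_total = mean(recs[, 4]),
        n_mixed = n_mixed, stringsAsFactors = FALSE)
    }
  })
  list(bundle = bundle, history = do.call(rbind, hist), opt = opt)
}

#' Centralized pre-training (phase A + phase B)
#'
#' Same two phases as [pretrain()] but on the pooled cohort.
#'
#' @inheritParams run_centralized
#' @param tm_config a [tm_config()] whose pretraining cycle budgets are used.
#' @return `list(bundle, history_task, history_scanner)`.
#' @export
pretrain_centralized <- function(pool, bundle, tm_config) {
  cfg_a <- tm_config
  cfg_a$n_cycles <- tm_config$pretrain_cycles_task
  a <- run_centralized(pool, bundle, cfg_a, mode = "task_only")
  cfg_b <- tm_config
  cfg_b$n_cycles <- tm_config$pretrain_cycles_scanner
  cfg_b$seed <- derive_seed(tm_config$seed, "pretrain_b")
  b <- run_centralized(pool, a$bundle, cfg_b, mode = "scanner_head")
  list(bundle = b$bundle, history_task = a$history, history_scanner = b$history)
}
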