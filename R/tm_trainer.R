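#' Traveling-model training configuration
#'
#' @param n_cycles number of traveling cycles; each cycle visits every center
#'   exactly once with one epoch of local training (default 30).
#' @param max_batch maximum batch size; a center with fewer samples trains
#'   with what it has (default 5).
#' @param lr_initial initial learning rate for Adam (default `1e-4`).
#' @param lr_decay multiplicative decay applied per cycle (exponential decay;
#'   default 0.95, must be positive).
#' @param seed integer seed governing schedules, within-center shuffling and
#'   dropout.
#' @param lr_task_scale,lr_scanner_scale,lr_conf_scale multipliers applied
#'   to the cycle learning rate for the three harmonization sub-updates.
#' @param pretrain_cycles_task,pretrain_cycles_scanner fixed cycle budgets
#'   standing in for "until convergence" in the two [pretrain()] phases.
#' @return An object of class `tm_config`.
#' @export
tm_config <- function(n_cycles = 30L, max_batch = 5L, lr_initial = 1e-4,
                      lr_decay = 0.95, seed = 1L,
                      pretrain_cycles_task = 6L,
                      pretrain_cycles_scanner = 2L,
                      lr_task_scale = 1, lr_scanner_scale = 1,
                      lr_conf_scale = 1) {
  if (n_cycles < 1) stop("n_cycles must be at least 1")
  if (max_batch < 1) stop("max_batch must be at least 1")
  if (lr_decay <= 0) stop("lr_decay must be positive")
  structure(list(n_cycles = as.integer(n_cycles),
                 max_batch = as.integer(max_batch),
                 lr_initial = lr_initial, lr_decay = lr_decay,
                 seed = as.integer(seed),
                 pretrain_cycles_task = as.integer(pretrain_cycles_task),
                 pretrain_cycles_scanner = as.integer(pretrain_cycles_scanner),
                 lr_task_scale = lr_task_scale,
                 lr_scanner_scale = lr_scanner_scale,
                 lr_conf_scale = lr_conf_scale),
            class = "tm_config")
}

#' Traveling schedule for one cycle
#'
#' A fresh permutation of the centers is drawn for every cycle, introducing
#' cycle-to-cycle variability analogous to batch shuffling in centralized
#' training.  The permutation is a deterministic function of
#' `(seed, cycle_index)`.
#'
#' @param center_ids vector of unique center ids.
#' @param cycle_index 0-based cycle number.
#' @param seed integer seed.
#' @return An object of class `travel_schedule` with the visiting order.
#' @export
make_schedule <- function(center_ids, cycle_index, seed) {
  if (length(center_ids) == 0) stop("center list must be nonempty")
  if (anyDuplicated(center_ids)) stop("duplicate center ids")
  order <- with_seed(derive_seed(seed, "schedule", cycle_index), {
    if (length(center_ids) == 1) center_ids else sample(center_ids)
  })
  structure(list(cycle_index = as.integer(cycle_index),
                 center_order = order, seed = as.integer(seed)),
            class = "travel_schedule")
}

#' Batch plan for one center epoch
#'
#' Full batches of `max_batch` samples plus a final remainder batch; a
#' center with fewer than `max_batch` samples trains with a single batch of
#' whatever it has.
#'
#' @param shard_size number of samples at the center (`>= 1`).
#' @param max_batch maximum batch size (default 5).
#' @return Integer vector of batch sizes summing to `shard_size`.
#' @examples
#' batch_plan(12)  # 5 5 2
#' batch_plan(3)   # 3
#' @export
batch_plan <- function(shard_size, max_batch = 5L) {
  if (shard_size < 1) stop("shard_size must be at least 1")
  q <- shard_size %/% max_batch
  r <- shard_size %% max_batch
  as.integer(c(rep(max_batch, q), if (r > 0) r))
}

#' Learning rate at a given cycle
#'
#' Exponential decay: `lr_initial * lr_decay^cycle_index`.
#'
#' @param cycle_index 0-based cycle number.
#' @param config a [tm_config()].
#' @return Scalar learning rate.
#' @export
lr_at <- function(cycle_index, config) {
  if (cycle_index < 0) stop("cycle_index must be nonnegative")
  if (config$lr_decay <= 0) stop("lr_decay must be positive")
  config$lr_initial * config$lr_decay^cycle_index
}

#' Run the traveling-model loop
#'
#' For each cycle a fresh schedule is drawn; the model then visits each
#' center in order and trains for one epoch over that center's batches
#' ([batch_plan()]).  Every batch contains samples from a single center.
#' The model object — encoder parameters, batch-norm running statistics,
#' both heads — and the optimizer states travel between centers and across
#' cycles without reset.
#'
#' Modes: `"task_only"` applies only the disease objective (step 1);
#' `"scanner_head"` trains the scanner head on frozen-encoder features
#' (step 2); `"harmonize"` applies the full three-step
#' [harmonization_step()] per batch.
#'
#' @param shards list of center shards.
#' @param bundle a [model_bundle()]; pre-trained when `mode = "harmonize"`.
#' @param config a [tm_config()].
#' @param mode one of `"harmonize"`, `"task_only"`, `"scanner_head"`.
#' @param opt optional optimizer states to continue from; fresh states by
#'   default.
#' @param combined passed to [harmonization_step()].
#' @param checkpoint_dir optional directory for per-cycle checkpoints.
#' @return `list(bundle, history, opt)`; `history` is a data frame with one
#'   row per (cycle, center) visit and columns `cycle`, `center`, `l_pd`,
#'   `l_sc`, `l_conf`, `l_total` (per-visit batch means; components not
#'   computed in a mode are `NA`).
#' @export
run_tm <- function(shards, bundle, config,
                   mode = c("harmonize", "task_only", "scanner_head"),
                   opt = NULL, combined = FALSE, checkpoint_dir = NULL) {
  mode <- match.arg(mode)
  if (length(shards) == 0) stop("empty shards")
  stopifnot(inherits(bundle, "model_bundle"), inherits(config, "tm_config"))
  if (is.null(opt)) opt <- harmon_optimizers()
  center_ids <- vapply(shards, function(s) s$center_id, character(1))
  if (anyDuplicated(center_ids)) stop("duplicate center ids")
  hist <- list()
  with_seed(derive_seed(config$seed, paste0("tm_", mode)), {
    for (cycle in seq_len(config$n_cycles) - 1L) {
      lr <- lr_at(cycle, config)
      sched <- make_schedule(center_ids, cycle, config$seed)
      for (cid in sched$center_order) {
        shard <- shards[[match(cid, center_ids)]]
        n <- length(shard$volumes)
        ord <- if (n == 1) 1L else sample(n)
        plan <- batch_plan(n, config$max_batch)
        pos <- 0L
        recs <- matrix(NA_real_, length(plan), 4)
        for (bi in seq_along(plan)) {
          idx <- ord[(pos + 1L):(pos + plan[bi])]
          pos <- pos + plan[bi]
          batch <- tm_batch(shard$volumes[idx], shard$disease_labels[idx],
                            shard$scanner_labels[idx], bundle$M, cid)
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
          cycle = cycle, center = cid,
          l_pd = mean(recs[, 1]), l_sc = mean(recs[, 2]),
          l_conf = mean(recs[, 3]), l_total = mean(recs[, 4]),
          stringsAsFactors = FALSE)
      }
      if (!is.null(checkpoint_dir)) {
        save_bundle(bundle, file.path(checkpoint_dir,
                                      sprintf("cycle_%03d.rds", cycle)))
      }
    }
  })
  list(bundle = bundle, history = do.call(rbind, hist), opt = opt)
}

#' Write a loss history to CSV
#'
#' @param history data frame from [run_tm()] or [run_centralized()].
#' @param path file path.
#' @export
write_history <- function(history, path) {
  write.csv(history, path, row.names = FALSE)
  invisible(path)
}
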