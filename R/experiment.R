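#' Stratified train/test split of a cohort
#'
#' Per center and per disease class, a fraction of samples is held out for
#' testing; centers (or within-center classes) with a single sample
#' contribute to training only.  The split is seeded and deterministic.
#'
#' @param shards list of center shards.
#' @param test_frac held-out fraction (default 0.2).
#' @param seed split seed.
#' @return `list(train_shards, train, test)` where `train` and `test` are
#'   pooled sample lists (see [pool_shards()]).
#' @export
split_cohort <- function(shards, test_frac = 0.2, seed = 1L) {
  train_shards <- list()
  test_v <- list(); test_d <- numeric(0); test_s <- integer(0); test_c <- character(0)
  for (s in shards) {
    n <- length(s$volumes)
    idx_test <- if (n < 2) integer(0) else
      stratified_split(s$disease_labels, test_frac,
                       derive_seed(seed, paste0("split_", s$center_id)))
    idx_train <- setdiff(seq_len(n), idx_test)
    if (length(idx_train) > 0) {
      train_shards[[length(train_shards) + 1L]] <- structure(
        list(center_id = s$center_id,
             volumes = s$volumes[idx_train],
             disease_labels = s$disease_labels[idx_train],
             scanner_labels = s$scanner_labels[idx_train]),
        class = "center_shard")
    }
    if (length(idx_test) > 0) {
      test_v <- c(test_v, s$volumes[idx_test])
      test_d <- c(test_d, s$disease_labels[idx_test])
      test_s <- c(test_s, s$scanner_labels[idx_test])
      test_c <- c(test_c, rep(s$center_id, length(idx_test)))
    }
  }
  list(train_shards = train_shards,
       train = pool_shards(train_shards),
       test = list(volumes = test_v, disease_labels = test_d,
                   scanner_labels = test_s, center_ids = test_c))
}

#' Default synthetic study conditions
#'
#' A 16-center cohort of about 320 samples imaged on a shared pool of 4
#' scanner types: highly variable shard sizes (2 to 80, several centers
#' below 5), centers that contain only one class (prevalence 0 or 1),
#' several centers operating two scanners, desk-scale 24x24x24 volumes,
#' scanner confound at full strength, and a disease effect calibrated so a
#' mask-mean threshold oracle sits near 80% accuracy.
#'
#' @param seed cohort seed.
#' @param confound_strength scanner-effect scaling (default 1).
#' @param disease_delta disease intensity shift (default 0.45).
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L, confound_strength = 1,
                                disease_delta = 0.45) {
  pool <- list(
    scanner_params(gain = 1.00, offset = 0.00, smooth_sigma = 0.0, noise_sd = 0.02),
    scanner_params(gain = 1.15, offset = 0.10, smooth_sigma = 0.5, noise_sd = 0.03),
    scanner_params(gain = 0.85, offset = -0.10, smooth_sigma = 1.0, noise_sd = 0.04),
    scanner_params(gain = 1.30, offset = 0.20, smooth_sigma = 0.25, noise_sd = 0.05)
  )
  sizes <- c(2, 3, 3, 4, 5, 8, 10, 12, 15, 18, 20, 24, 28, 32, 56, 80)
  # scanner exposure is kept roughly balanced across the pool so that
  # chance level for scanner decoding is close to 1/M
  smap <- list(1L, 2L, 3L, 4L, 1L, c(1L, 2L), 2L, 3L, c(3L, 4L), 4L,
               1L, 2L, 4L, 3L, c(3L, 4L), c(1L, 2L))
  prev <- c(0.5, 0, 1, 0.5, 0.4, 0.6, 0, 1, 0.5, 0.5,
            0.45, 0.55, 0.5, 0.5, 0.35, 0.5)
  cohort_spec(n_centers = 16L, scanner_pool = pool, center_sizes = sizes,
              center_scanner_map = smap, prevalence_per_center = prev,
              volume_shape = c(24L, 24L, 24L),
              disease_delta = disease_delta,
              confound_strength = confound_strength,
              noise_sd = 0.05, seed = seed)
}

#' Experiment configuration
#'
#' Settings for the full before/after x centralized/traveling-model
#' experiment.  Exactly one of `cohort` (a [cohort_spec()]) or `manifest`
#' (path to a manifest CSV with NIfTI volume paths) must be given.
#'
#' @param seed master seed; all randomness (cohort, split, initialization,
#'   schedules, probes) is derived from it.
#' @param cohort a [cohort_spec()], or `NULL` when `manifest` is used.
#' @param manifest path to a manifest CSV, or `NULL`.
#' @param M scanner label space size (required with `manifest`; inferred
#'   from the cohort spec otherwise).
#' @param channel_widths encoder widths for the desk-scale runs.
#' @param tm a [tm_config()] (its `seed` is overridden by `seed`).
#' @param central_lr_initial initial learning rate of the centralized
#'   baseline.
#' @param harmonize_lr_initial initial learning rate of the harmonization
#'   phase (both approaches).
#' @param harmonize_cycles number of harmonization cycles after
#'   pre-training (default 8).
#' @param approaches subset of `c("tm", "central")`.
#' @param test_frac held-out fraction.
#' @param out_dir optional output directory for reports, histories and
#'   checkpoints.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              cohort = default_cohort_spec(seed),
                              manifest = NULL,
                              M = NULL,
                              channel_widths = c(4L, 8L, 16L, 16L, 16L, 8L),
                              tm = tm_config(lr_initial = 1e-3, lr_decay = 0.95,
                                             pretrain_cycles_task = 6L,
                                             pretrain_cycles_scanner = 6L,
                                             lr_scanner_scale = 0.3,
                                             lr_conf_scale = 2),
                              central_lr_initial = 1e-3,
                              harmonize_lr_initial = 2e-3,
                              harmonize_cycles = 8L,
                              approaches = c("tm", "central"),
                              test_frac = 0.2,
                              out_dir = NULL) {
  if (is.null(cohort) == is.null(manifest))
    stop("exactly one of cohort or manifest must be given")
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "cohort_spec"))
    M <- length(cohort$scanner_pool)
  } else if (is.null(M)) {
    stop("M is required when loading from a manifest")
  }
  approaches <- match.arg(approaches, c("tm", "central"), several.ok = TRUE)
  structure(list(seed = as.integer(seed), cohort = cohort, manifest = manifest,
                 M = as.integer(M), channel_widths = as.integer(channel_widths),
                 tm = tm, central_lr_initial = central_lr_initial,
                 harmonize_lr_initial = harmonize_lr_initial,
                 harmonize_cycles = as.integer(harmonize_cycles),
                 approaches = approaches, test_frac = test_frac,
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Run the before/after x centralized/traveling-model experiment
#'
#' Generates (or loads) the cohort, draws one common stratified test split,
#' then for each requested approach: initializes a model, pre-trains it
#' (phase A disease task, phase B scanner head), evaluates the
#' pre-harmonization state, runs the adversarial harmonization cycles, and
#' evaluates again.  All four reports share the test split, so before/after
#' and centralized/TM comparisons are like-for-like.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-stage progress.
#' @return A list with one entry per approach, each holding `before` and
#'   `after` [evaluate_bundle()] reports plus training histories, and the
#'   `split` sizes.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  shards <- if (!is.null(config$cohort)) generate_cohort(config$cohort)
            else read_cohort_nifti(config$manifest)
  M <- config$M
  shape <- dim(shards[[1]]$volumes[[1]])
  sp <- split_cohort(shards, config$test_frac, derive_seed(config$seed, "split"))
  arch <- encoder_config(shape, channel_widths = config$channel_widths)
  out <- list(split = list(n_train = length(sp$train$volumes),
                           n_test = length(sp$test$volumes)))

  for (approach in config$approaches) {
    say("[%s] pre-training", approach)
    tmcfg <- config$tm
    tmcfg$seed <- derive_seed(config$seed, paste0("train_", approach))
    bundle <- model_bundle(arch, M, seed = derive_seed(config$seed, paste0("init_", approach)))
    if (approach == "tm") {
      pre <- pretrain(sp$train_shards, bundle, tmcfg)
    } else {
      tmcfg$lr_initial <- config$central_lr_initial
      pre <- pretrain_centralized(sp$train, bundle, tmcfg)
    }
    say("[%s] evaluating pre-harmonization model", approach)
    before <- evaluate_bundle(pre$bundle, sp$train, sp$test,
                              seed = derive_seed(config$seed, "eval"))
    hcfg <- tmcfg
    hcfg$lr_initial <- config$harmonize_lr_initial
    hcfg$seed <- derive_seed(tmcfg$seed, "harmonize")
    say("[%s] harmonizing (%d cycles)", approach, config$harmonize_cycles)
    harm <- harmonize_adaptive(sp$train_shards, pre$bundle, hcfg,
                               approach = approach,
                               cycles = config$harmonize_cycles,
                               verbose = verbose)
    say("[%s] evaluating harmonized model", approach)
    after <- evaluate_bundle(harm$bundle, sp$train, sp$test,
                             seed = derive_seed(config$seed, "eval"))
    out[[approach]] <- list(before = before, after = after,
                            history = list(pretrain_task = pre$history_task,
                                           pretrain_scanner = pre$history_scanner,
                                           harmonize = harm$history))
    if (!is.null(config$out_dir)) {
      dir <- file.path(config$out_dir, approach)
      write_report(before, dir, "before")
      write_report(after, dir, "after")
      write_history(harm$history, file.path(dir, "harmonize_history.csv"))
    }
  }
  out
}
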