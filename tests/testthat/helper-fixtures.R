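# Shared fixtures: everything is generated in code at test time.

tiny_config <- function(shape = c(8L, 8L, 8L),
                        widths = c(2L, 3L, 3L, 2L, 2L, 4L),
                        dropout = 0) {
  encoder_config(shape, channel_widths = widths, dropout_rate = dropout)
}

tiny_bundle <- function(M = 3L, seed = 7L, ...) {
  model_bundle(tiny_config(...), M, seed = seed)
}

tiny_volumes <- function(n, shape = c(8L, 8L, 8L), seed = 42L) {
  harmonytm:::with_seed(seed, {
    lapply(seq_len(n), function(i) array(rnorm(prod(shape)), dim = shape))
  })
}

tiny_batch <- function(bundle, n = 3L, seed = 42L) {
  vols <- tiny_volumes(n, bundle$config$input_shape, seed)
  harmonytm:::with_seed(seed + 1L, {
    tm_batch(vols,
             rep_len(c(1, 0), n),
             sample(bundle$M, n, replace = TRUE),
             bundle$M, "center_a")
  })
}

# Small multi-center cohort spec for trainer tests: separable disease signal,
# mild confound, 8^3 volumes.
toy_cohort_spec <- function(seed = 1L, n_per_center = c(6L, 5L, 9L),
                            confound = 0.5, delta = 0.8, shape = c(8L, 8L, 8L)) {
  pool <- list(scanner_params(gain = 1.1, offset = 0.05, noise_sd = 0.02),
               scanner_params(gain = 0.9, offset = -0.05, smooth_sigma = 0.5,
                              noise_sd = 0.02))
  cohort_spec(n_centers = length(n_per_center), scanner_pool = pool,
              center_sizes = n_per_center,
              center_scanner_map = rep_len(list(1L, 2L, c(1L, 2L)),
                                           length(n_per_center)),
              prevalence_per_center = rep_len(0.5, length(n_per_center)),
              volume_shape = shape,
              disease_delta = delta, confound_strength = confound,
              noise_sd = 0.05, seed = seed)
}

# The directional study (pre-training + 8 adversarial cycles on the default
# 16-center cohort) is expensive, so it is computed once per test run and
# shared between the blocks that examine it.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_runs <- function(seeds = 1:3) {
  key <- paste(seeds, collapse = "_")
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  runs <- lapply(seeds, function(seed) {
    cfg <- experiment_config(seed = seed, approaches = "tm")
    run_experiment(cfg)
  })
  .acceptance_cache[[key]] <- runs
  runs
}
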