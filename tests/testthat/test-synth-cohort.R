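# Synthetic multi-center cohort generator: exact effect algebra, seeded
# determinism, manifest/YAML/NIfTI round trips, and the statistical
# properties the downstream experiments rely on.

test_that("shard sizes and label spaces follow the spec", {
  spec <- toy_cohort_spec(seed = 4, n_per_center = c(2L, 5L, 10L))
  shards <- generate_cohort(spec)
  expect_length(shards, 3)
  expect_equal(vapply(shards, function(s) length(s$volumes), integer(1)),
               c(2L, 5L, 10L))
  for (i in seq_along(shards)) {
    s <- shards[[i]]
    expect_length(s$disease_labels, length(s$volumes))
    expect_length(s$scanner_labels, length(s$volumes))
    expect_true(all(s$scanner_labels %in% spec$center_scanner_map[[i]]))
    expect_true(all(s$disease_labels %in% c(0, 1)))
  }
})

test_that("identical spec and seed give a bit-identical cohort", {
  spec <- toy_cohort_spec(seed = 9)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  spec2 <- toy_cohort_spec(seed = 10)
  expect_false(identical(generate_cohort(spec), generate_cohort(spec2)))
})

test_that("cohort spec invariants are enforced", {
  expect_error(cohort_spec(2, list(scanner_params()), c(3, 3),
                           list(1L, 1L), c(0.5, 0.5)),
               "at least 2")
  pool <- list(scanner_params(), scanner_params(gain = 1.2))
  expect_error(cohort_spec(2, pool, c(3, 3, 3), list(1L, 2L), c(0.5, 0.5)),
               "length n_centers")
  expect_error(cohort_spec(2, pool, c(3, 3), list(1L, 3L), c(0.5, 0.5)),
               "outside the pool")
  expect_error(cohort_spec(2, pool, c(3, 3), list(1L, integer(0)), c(0.5, 0.5)),
               "at least one scanner")
  expect_error(scanner_params(gain = 0), "positive")
  expect_error(scanner_params(smooth_sigma = -1), "nonnegative")
})

test_that("scanner effect follows its closed-form algebra", {
  v <- array(runif(6^3), dim = c(6, 6, 6))
  p <- scanner_params(gain = 2, offset = 0.3, smooth_sigma = 1, noise_sd = 0.1)
  expect_identical(inject_scanner_effect(v, p, strength = 0), v)
  p_gain <- scanner_params(gain = 2)
  expect_equal(mean(inject_scanner_effect(v, p_gain, 1)), 2 * mean(v),
               tolerance = 1e-12)
  p_off <- scanner_params(offset = 0.5)
  expect_equal(mean(inject_scanner_effect(v, p_off, 1)), mean(v) + 0.5,
               tolerance = 1e-12)
  # half strength interpolates the gain
  expect_equal(inject_scanner_effect(v, p_gain, 0.5), v * 1.5, tolerance = 1e-12)
  expect_error(inject_scanner_effect(array(NA_real_, dim(v)), p_gain, 1), "finite")
})

test_that("disease effect shifts exactly the masked voxels", {
  v <- array(0, dim = c(5, 5, 5))
  mask <- array(FALSE, dim = c(5, 5, 5))
  mask[1:2, 1, 1] <- TRUE
  mask[3, 3, 3] <- TRUE
  out <- inject_disease_effect(v, mask, 1)
  expect_equal(sum(out), 3)
  expect_true(all(out[mask] == 1))
  expect_true(all(out[!mask] == 0))
  expect_identical(inject_disease_effect(v, mask, 0), v)
  expect_equal(mean(out[mask]) - mean(v[mask]), 1)
  expect_error(inject_disease_effect(v, mask[1:4, , ], 1), "shape")
})

test_that("manifests round-trip and validate", {
  shards <- generate_cohort(toy_cohort_spec(seed = 2))
  path <- tempfile(fileext = ".csv")
  write_manifest(shards, path)
  df <- read_manifest(path)
  expect_identical(df, manifest_from_shards(shards))
  # writing back what was read is an identity on the metadata
  path2 <- tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE)
  expect_identical(read_manifest(path2), df)

  # empty shard list -> header-only CSV
  path3 <- tempfile(fileext = ".csv")
  write_manifest(list(), path3)
  empty <- read_manifest(path3)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("sample_id", "center_id", "scanner_id",
                        "disease_label", "volume_path"))

  # unknown scanner id against the label space
  bad <- df
  bad$scanner_id[1] <- 99L
  path4 <- tempfile(fileext = ".csv")
  write.csv(bad, path4, row.names = FALSE)
  expect_error(read_manifest(path4, scanner_space = 2), "outside the label space")
  # missing column
  path5 <- tempfile(fileext = ".csv")
  write.csv(df[, -2], path5, row.names = FALSE)
  expect_error(read_manifest(path5), "missing columns")
})

test_that("cohort specs round-trip through YAML", {
  spec <- toy_cohort_spec(seed = 6)
  path <- tempfile(fileext = ".yaml")
  write_cohort_spec(spec, path)
  spec2 <- read_cohort_spec(path)
  expect_identical(generate_cohort(spec), generate_cohort(spec2))
})

test_that("volumes round-trip through NIfTI at single precision", {
  shards <- generate_cohort(toy_cohort_spec(seed = 3, n_per_center = c(2L, 2L, 2L)))
  dir <- tempfile("nifti")
  df <- write_cohort_nifti(shards, dir)
  back <- read_cohort_nifti(file.path(dir, "manifest.csv"))
  expect_length(back, 3)
  expect_equal(back[[1]]$disease_labels, shards[[1]]$disease_labels)
  expect_equal(back[[2]]$scanner_labels, shards[[2]]$scanner_labels)
  # float32 storage: values agree to single precision
  expect_equal(back[[1]]$volumes[[1]], shards[[1]]$volumes[[1]],
               tolerance = 1e-6)
})

test_that("scanner decodability from raw voxels rises with confound strength", {
  probe_at <- function(strength, seed) {
    spec <- toy_cohort_spec(seed = seed, n_per_center = rep(50L, 4),
                            confound = strength, delta = 0,
                            shape = c(8L, 8L, 8L))
    spec$center_scanner_map <- list(1L, 2L, c(1L, 2L), c(1L, 2L))
    shards <- generate_cohort(spec)
    pool <- pool_shards(shards)
    X <- t(vapply(pool$volumes, as.vector, numeric(8^3)))
    idx <- harmonytm:::with_seed(seed, sample(nrow(X), 100))
    tr <- setdiff(seq_len(nrow(X)), idx)
    linear_probe(X[tr, ], pool$scanner_labels[tr],
                 X[idx, ], pool$scanner_labels[idx])
  }
  for (seed in c(21, 22, 23)) {
    a0 <- probe_at(0, seed)
    a5 <- probe_at(0.5, seed)
    a1 <- probe_at(1.0, seed)
    expect_gte(a5, a0 - 0.02)
    expect_gte(a1, a5 - 0.02)
  }
})

test_that("zero confound and zero disease effect give chance-level probes", {
  spec <- toy_cohort_spec(seed = 31, n_per_center = rep(50L, 4),
                          confound = 0, delta = 0, shape = c(8L, 8L, 8L))
  spec$center_scanner_map <- list(1L, 2L, c(1L, 2L), c(1L, 2L))
  shards <- generate_cohort(spec)
  pool <- pool_shards(shards)
  X <- t(vapply(pool$volumes, as.vector, numeric(8^3)))
  idx <- harmonytm:::with_seed(31, sample(nrow(X), 100))
  tr <- setdiff(seq_len(nrow(X)), idx)
  acc <- linear_probe(X[tr, ], pool$scanner_labels[tr],
                      X[idx, ], pool$scanner_labels[idx])
  expect_lt(abs(acc - 0.5), 0.05 + 0.05)  # chance 1/2 for two scanner types
})

test_that("a mask-mean threshold detects the disease when delta >> noise", {
  spec <- toy_cohort_spec(seed = 41, n_per_center = rep(40L, 3),
                          confound = 0, delta = 0.2, shape = c(8L, 8L, 8L))
  # delta = 4 x noise_sd
  spec$noise_sd <- 0.05
  shards <- generate_cohort(spec)
  pool <- pool_shards(shards)
  acc <- mask_mean_oracle(pool$volumes, pool$disease_labels, spec$disease_mask)
  expect_gt(acc, 0.9)
})

test_that("default study conditions sit near the calibrated oracle point", {
  spec <- default_cohort_spec(seed = 11)
  shards <- generate_cohort(spec)
  pool <- pool_shards(shards)
  expect_equal(length(pool$volumes), 320)
  acc <- mask_mean_oracle(pool$volumes, pool$disease_labels, spec$disease_mask)
  expect_gt(acc, 0.7)
  expect_lt(acc, 0.9)
})
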