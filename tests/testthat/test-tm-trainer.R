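# Traveling-model loop: schedules, the batch-size rule, learning-rate decay
# and the single-center-batch contract.

test_that("schedules are deterministic permutations that vary across cycles", {
  expect_identical(make_schedule("only", 0, 1)$center_order, "only")
  ids <- sprintf("c%02d", 1:10)
  s1 <- make_schedule(ids, 3, 42)
  s2 <- make_schedule(ids, 3, 42)
  expect_identical(s1$center_order, s2$center_order)
  expect_setequal(s1$center_order, ids)
  differs <- vapply(1:5, function(seed) {
    !identical(make_schedule(ids, 0, seed)$center_order,
               make_schedule(ids, 1, seed)$center_order)
  }, logical(1))
  expect_true(all(differs))
  expect_error(make_schedule(c("a", "a"), 0, 1), "duplicate")
})

test_that("the batch plan fills fives and a remainder", {
  expect_identical(batch_plan(3), 3L)
  expect_identical(batch_plan(5), 5L)
  expect_identical(batch_plan(12), c(5L, 5L, 2L))
  set.seed(8)
  for (n in sample(1:60, 15)) {
    plan <- batch_plan(n)
    expect_equal(sum(plan), n)
    expect_true(all(plan <= 5))
    expect_true(all(plan[-length(plan)] == 5))
  }
  expect_error(batch_plan(0), "at least 1")
})

test_that("the learning rate decays exponentially", {
  cfg <- tm_config(lr_initial = 1e-4, lr_decay = 0.9)
  expect_identical(lr_at(0, cfg), 1e-4)
  expect_equal(lr_at(2, cfg), 8.1e-5, tolerance = 1e-12)
  lrs <- vapply(0:10, lr_at, numeric(1), config = cfg)
  expect_true(all(diff(lrs) < 0))
  expect_error(tm_config(lr_decay = 0), "positive")
})

test_that("each cycle visits every center exactly once and batches stay single-center", {
  spec <- toy_cohort_spec(seed = 12, n_per_center = c(3L, 7L, 11L))
  shards <- generate_cohort(spec)
  # tag volumes with their center so batch composition can be audited
  for (i in seq_along(shards)) {
    shards[[i]]$volumes <- lapply(shards[[i]]$volumes, function(v) {
      attr(v, "origin") <- shards[[i]]$center_id
      v
    })
  }
  seen <- list()
  local_mocked_bindings(
    tm_batch = function(volumes, y_disease, scanner_ids, M, center_id = NA) {
      origins <- vapply(volumes, attr, character(1), "origin")
      seen[[length(seen) + 1L]] <<- origins
      out <- list(volumes = lapply(volumes, function(v) { attributes(v) <- list(dim = dim(v)); v }),
                  y_disease = as.numeric(y_disease),
                  y_scanner = harmonytm:::one_hot(scanner_ids, M),
                  scanner_ids = as.integer(scanner_ids),
                  center_id = center_id, N = length(volumes))
      structure(out, class = "tm_batch")
    },
    .package = "harmonytm"
  )
  b0 <- model_bundle(tiny_config(), 2L, seed = 1)
  cfg <- tm_config(n_cycles = 2L, lr_initial = 1e-3, seed = 3)
  r <- run_tm(shards, b0, cfg, mode = "task_only")
  # every logged batch came from a single center
  expect_true(all(vapply(seen, function(o) length(unique(o)) == 1, logical(1))))
  # bookkeeping: 2 cycles x 3 centers
  expect_equal(nrow(r$history), 6)
  for (cyc in 0:1) {
    expect_setequal(r$history$center[r$history$cycle == cyc],
                    vapply(shards, function(s) s$center_id, character(1)))
  }
  # batch count per center epoch follows the batch plan
  expect_length(seen, 2 * sum(lengths(lapply(c(3, 7, 11), batch_plan))))
})

test_that("a full traveling run is reproducible from its seed", {
  shards <- generate_cohort(toy_cohort_spec(seed = 17))
  b0 <- model_bundle(tiny_config(), 2L, seed = 5)
  cfg <- tm_config(n_cycles = 2L, lr_initial = 1e-3, seed = 11)
  r1 <- run_tm(shards, b0, cfg, mode = "task_only")
  r2 <- run_tm(shards, b0, cfg, mode = "task_only")
  expect_identical(r1$history, r2$history)
  expect_identical(r1$bundle, r2$bundle)
  expect_error(run_tm(list(), b0, cfg), "empty")
})

test_that("task-only traveling training learns a separable toy cohort", {
  for (seed in c(23, 24, 25)) {
    spec <- toy_cohort_spec(seed = seed, confound = 0.1, delta = 1.5,
                            n_per_center = c(12L, 12L, 12L))
    shards <- generate_cohort(spec)
    b0 <- model_bundle(tiny_config(widths = c(4L, 4L, 8L, 8L, 8L, 4L)),
                       2L, seed = seed)
    cfg <- tm_config(n_cycles = 10L, lr_initial = 5e-3, seed = seed)
    r <- run_tm(shards, b0, cfg, mode = "task_only")
    pool <- pool_shards(shards)
    f <- forward_features(r$bundle, pool$volumes)
    acc <- mean(as.integer(predict_disease(r$bundle, f) > 0.5) ==
                  pool$disease_labels)
    expect_gt(acc, 0.9)
  }
})
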