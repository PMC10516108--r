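test_that("stage seeds are deterministic, distinct and in integer range", {
  s1 <- derive_seed(1, "generate", 0)
  expect_identical(s1, derive_seed(1, "generate", 0))
  expect_false(s1 == derive_seed(1, "generate", 1))
  expect_false(s1 == derive_seed(1, "cluster", 0))
  expect_false(s1 == derive_seed(2, "generate", 0))
  seeds <- vapply(0:50, function(i) derive_seed(123, "x", i), integer(1))
  expect_true(all(seeds >= 1 & seeds < 2^31 - 1))
  expect_false(anyDuplicated(seeds) > 0)
})

micro_setup <- make_micro_setup(master_seed = 5L)
micro_pp <- make_surrogate_for(micro_setup, seed = 5L)

test_that("a zero-iteration run records exactly the pretraining metrics row", {
  res <- suppressWarnings(run_loop(pose_provider = micro_pp,
                                   config = micro_run_config(),
                                   mode = "complete", n_iterations = 0,
                                   setup = micro_setup))
  expect_equal(nrow(res$metrics), 1L)
  expect_equal(res$metrics$iteration, 0)
  expect_true(res$metrics$max_score >= res$metrics$mean_score)
  expect_true(res$metrics$fraction_above_threshold >= 0 &&
                res$metrics$fraction_above_threshold <= 100)
})

test_that("one iteration fine-tunes, appends a row and is seed-deterministic", {
  a <- suppressWarnings(run_loop(pose_provider = micro_pp,
                                 config = micro_run_config(),
                                 mode = "complete", n_iterations = 1,
                                 setup = micro_setup))
  expect_equal(a$metrics$iteration, c(0, 1))
  expect_false(identical(a$model$params, micro_setup$model$params))
  b <- suppressWarnings(run_loop(pose_provider = micro_pp,
                                 config = micro_run_config(),
                                 mode = "complete", n_iterations = 1,
                                 setup = micro_setup))
  expect_identical(a$metrics, b$metrics)
  # the seed ledger records every stage of every iteration
  expect_true(all(c("generate", "cluster", "select", "alset", "finetune") %in%
                    a$seed_ledger$stage))
})

test_that("the naive control trains on above-threshold replicas only", {
  res <- suppressWarnings(run_loop(pose_provider = micro_pp,
                                   config = micro_run_config(),
                                   mode = "naive", n_iterations = 1,
                                   setup = micro_setup))
  expect_equal(nrow(res$metrics), 2L)
  # naive mode never clusters
  expect_false("cluster" %in%
                 res$seed_ledger$stage[!is.na(res$seed_ledger$iteration)])
})

test_that("interrupted runs resume to the same final metrics", {
  wd <- withr::local_tempdir()
  full <- suppressWarnings(run_loop(pose_provider = micro_pp,
                                    config = micro_run_config(),
                                    mode = "complete", n_iterations = 2,
                                    setup = micro_setup, workdir = wd))
  expect_true(file.exists(file.path(wd, "metrics.csv")))
  expect_true(file.exists(file.path(wd, "manifest.json")))
  # simulate an interruption after iteration 1 by dropping later checkpoints
  wd2 <- withr::local_tempdir()
  file.copy(file.path(wd, c("state_iter000.rds", "state_iter001.rds")), wd2)
  resumed <- suppressWarnings(run_loop(pose_provider = micro_pp,
                                       config = micro_run_config(),
                                       mode = "complete", n_iterations = 2,
                                       workdir = wd2, resume = TRUE))
  expect_equal(resumed$metrics, full$metrics)
  # manifest is valid JSON with the run configuration
  man <- jsonlite::read_json(file.path(wd, "manifest.json"))
  expect_equal(man$mode, "complete")
  expect_equal(man$config$k, 5)
})

test_that("broom-style accessors and plots work on run results", {
  res <- suppressWarnings(run_loop(pose_provider = micro_pp,
                                   config = micro_run_config(),
                                   mode = "complete", n_iterations = 0,
                                   setup = micro_setup))
  expect_identical(tidy(res), res$metrics)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(glance(res$model), "tbl_df")
  d <- compute_descriptors(micro_corpus, descriptor_provider_fast())
  pj <- fit_projection(d, 4)
  expect_s3_class(autoplot(pj), "ggplot")
  co <- project(pj, d)
  cl <- cluster_molecules(co, k = 4, n_restarts = 3, seed = 1)
  expect_s3_class(tidy(cl), "tbl_df")
  expect_s3_class(autoplot(cl, co), "ggplot")
  expect_s3_class(tidy(micro_prep$vocabulary), "tbl_df")
})
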