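test_that("unbiased dataset build is reproducible and reports diagnostics", {
  ligs <- small_ligands()
  cfg <- generation_config("polar")
  dir1 <- tempfile("ds1"); dir2 <- tempfile("ds2")
  r1 <- run_dataset_build(ligs, cfg, seed = 5, out_dir = dir1)
  r2 <- run_dataset_build(ligs, cfg, seed = 5, out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "labels.csv")),
                   readLines(file.path(dir2, "labels.csv")))
  expect_identical(r1$complexes$label, r2$complexes$label)

  # both labels present with non-extreme balance at default config
  pool <- memo("wf_pool", function() {
    ligs50 <- embed_ligands(generate_fixture_ligands(50, seed = 77), seed = 78)
    run_dataset_build(ligs50, generation_config("polar"), seed = 9)
  })
  expect_true(all(c("active", "inactive") %in% pool$complexes$label))
  expect_gt(pool$active_fraction, 0.1)
  expect_lt(pool$active_fraction, 0.9)

  # one diagnostic distribution per label
  expect_true(all(c("active", "inactive") %in% pool$diagnostic$label))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
})

test_that("bias-matched build matches labels or logs discards deterministically", {
  ligs <- small_ligands()[1:6, ]
  cfg <- generation_config("polar")
  # attainable targets: use labels the unconditioned generator can reach
  ligs$label <- rep(c("active", "inactive"), 3)
  r <- run_bias_matched_build(ligs, cfg, seed = 3, max_attempts = 100L)
  expect_equal(sum(r$discard_log$discarded), 0)
  expect_identical(r$complexes$label, ligs$label[!r$discard_log$discarded])

  r2 <- run_bias_matched_build(ligs, cfg, seed = 3, max_attempts = 100L)
  expect_identical(r$discard_log, r2$discard_log)

  expect_error(run_bias_matched_build(ligs, cfg, seed = 3, max_attempts = 0L),
               "max_attempts")

  # unattainable target labels produce discards, not errors
  hard <- ligs[1:2, ]
  hard$label <- "active"
  cfg_hard <- generation_config("contribution", score_threshold = 1e9)
  rh <- run_bias_matched_build(hard, cfg_hard, seed = 3, max_attempts = 3L)
  expect_equal(sum(rh$discard_log$discarded), 2)
  expect_equal(nrow(rh$complexes), 0)
})

test_that("active-only test sets are filtered, active, and summarised", {
  ligs <- memo("testset_ligs", function() {
    embed_ligands(generate_fixture_ligands(40, seed = 55), seed = 56)
  })
  refs <- small_ligands()[1:3, ]
  cfg <- generation_config("contribution")
  r <- run_active_testset_build(ligs, refs, cfg, n = 15L, seed = 2,
                                max_tanimoto = 0.8, min_heavy = 15L)
  expect_true(all(r$complexes$label == "active"))
  expect_true(all(r$complexes$n_heavy >= 15))
  expect_true(all(c("frac_zero", "frac_above_1", "frac_above_2") %in%
                    names(r$contribution_summary)))
  expect_gte(r$contribution_summary$frac_zero, 0)

  expect_error(run_active_testset_build(ligs, refs, cfg, n = 1000L, seed = 2),
               "short by")
})

test_that("the benchmark trains one model per featurizer and is seeded", {
  pool <- memo("bm_pool", function() {
    ligs <- embed_ligands(generate_fixture_ligands(120, seed = 31), seed = 32)
    run_dataset_build(ligs, generation_config("polar"), seed = 4)$complexes
  })
  bm <- run_benchmark(pool, test_size = 40L, cutoffs = c(3, 4),
                      num_trees = 80L, seed = 10)
  expect_equal(nrow(bm), 3)   # morgan + two cutoffs
  expect_identical(bm$model, c("RF_Morgan", "RF_PLEC_3", "RF_PLEC_4"))
  bm2 <- run_benchmark(pool, test_size = 40L, cutoffs = c(3, 4),
                       num_trees = 80L, seed = 10)
  expect_identical(bm$accuracy, bm2$accuracy)
  expect_s3_class(ggplot2::autoplot(bm), "ggplot")
})

test_that("perturbation studies trace the key atom across distances", {
  pool <- memo("bm_pool", function() {
    ligs <- embed_ligands(generate_fixture_ligands(120, seed = 31), seed = 32)
    run_dataset_build(ligs, generation_config("polar"), seed = 4)$complexes
  })
  cfg4 <- featurizer_config(plec_cutoff = 4)
  ds <- build_dataset(pool, "plec", cfg4)
  m4 <- train_random_forest(ds$X, ds$y, "plec", cfg4, num_trees = 150L, seed = 2)

  lig <- small_ligands()$mol[[7]]
  base <- make_single_contact_complex(lig, generation_config("polar"),
                                      distance = 2.8, n_far = 3L, seed = 12)
  expect_equal(nrow(base$records), 1)
  expect_equal(base$label, "active")

  dists <- seq(1.5, 10, length.out = 12)
  pt <- run_perturbation_study(base, list(m4), distances = dists)
  expect_equal(nrow(pt), 12)
  expect_equal(pt$distance, dists)
  expect_true(all(pt$key_atom == base$records$atom_idx[1]))
  # inside the cutoff the key atom ranks clearly above its outside ranks
  expect_lt(mean(pt$rank[pt$distance < 4]), mean(pt$rank[pt$distance > 4]))
  expect_s3_class(ggplot2::autoplot(pt), "ggplot")

  # a multi-interaction complex is rejected as a perturbation base
  multi <- generate_conditioned(lig, generation_config("polar"), "active",
                                100L, seed = 1)
  if (!is.null(multi) && nrow(multi$records) != 1) {
    expect_error(run_perturbation_study(multi, list(m4), distances = dists),
                 "exactly one")
  }
})

test_that("the command-line entry point exposes the workflows", {
  cli <- system.file("cli", "synthbind.R", package = "synthbind")
  expect_true(nzchar(cli) && file.exists(cli))
  out_dir <- tempfile("cliout")
  rscript <- file.path(R.home("bin"), "Rscript")
  res <- system2(rscript, c(cli, "generate", "--n-ligands", "8",
                            "--rule", "polar", "--seed", "3",
                            "--out", out_dir),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out_dir, "labels.csv")),
              info = paste(res, collapse = "\n"))
  labs <- read.csv(file.path(out_dir, "labels.csv"))
  expect_equal(nrow(labs), 8)
})
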