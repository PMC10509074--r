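make_complex_pool <- function(n = 60, rule = "polar", seed = 17) {
  memo(paste0("pool_", rule, "_", n, "_", seed), function() {
    ligs <- small_ligands()
    cxs <- list()
    for (i in seq_len(n)) {
      lig <- ligs$mol[[(i %% nrow(ligs)) + 1]]
      cxs[[i]] <- generate_complex(lig, generation_config(rule), seed = seed + i)
    }
    complex_set(cxs)
  })
}

test_that("dataset building maps complexes to fingerprint rows in order", {
  pool <- make_complex_pool(60)
  ds <- build_dataset(pool, "morgan")
  expect_equal(nrow(ds$X), 60)
  expect_equal(length(ds$y), 60)
  expect_identical(ds$ids, pool$id)
  expect_identical(ds$y, as.integer(pool$label == "active"))

  # morgan rows are identical for the same ligand regardless of protein
  same_lig <- which(pool$ligand_id == pool$ligand_id[1])[1:2]
  expect_equal(ds$X[same_lig[1], ], ds$X[same_lig[2], ])

  expect_error(build_dataset(pool[0, ], "morgan"), "empty")
})

test_that("random forest training is seeded and learns a separable rule", {
  # one informative bit: bit 1 determines the label
  set.seed(4)
  X <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(80, 32))
  X[1:40, 1] <- 1
  X[, 2] <- rbinom(80, 1, 0.5)
  colnames(X) <- paste0("b", 0:31)
  y <- c(rep(1L, 40), rep(0L, 40))
  m <- train_random_forest(X, y, "morgan", seed = 5)
  expect_equal(mean((predict_score(m, X) > 0.5) == (y == 1)), 1.0)

  m2 <- train_random_forest(X, y, "morgan", seed = 5)
  expect_identical(predict_score(m, X), predict_score(m2, X))
  expect_true(all(predict_score(m, X) >= 0 & predict_score(m, X) <= 1))
  expect_equal(m$name, "RF_Morgan")

  expect_error(train_random_forest(X, rep(1L, 80), "morgan"), "both classes")
})

test_that("classifier evaluation reports accuracy, baselines, and AU-PRC", {
  # perfect scorer: balanced separable training, imbalanced 90/10 test set
  Xtr <- Matrix::sparseMatrix(i = 1:40, j = rep(1, 40), x = 1, dims = c(80, 16))
  colnames(Xtr) <- paste0("b", 0:15)
  ytr <- as.integer(seq_len(80) <= 40)
  m <- train_random_forest(Xtr, ytr, "morgan", seed = 2)
  X <- Matrix::sparseMatrix(i = 1:10, j = rep(1, 10), x = 1, dims = c(100, 16))
  colnames(X) <- paste0("b", 0:15)
  y <- as.integer(seq_len(100) <= 10)
  ev <- evaluate_classifier(m, X, y)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$au_prc, 1.0)
  expect_equal(ev$random_accuracy, 0.9)
  expect_equal(ev$balanced_accuracy, 1.0)

  # an uninformative model on a 90/10 split predicts the majority class
  X0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(200, 16))
  colnames(X0) <- paste0("b", 0:15)
  set.seed(9)
  y0 <- as.integer(runif(200) < 0.1)  # approx 10% actives, no signal
  m0 <- train_random_forest(X0, y0, "morgan", seed = 3)
  ev0 <- evaluate_classifier(m0, X0, y0)
  expect_equal(ev0$accuracy, ev0$random_accuracy)
  expect_equal(ev0$random_accuracy, mean(y0 == 0))

  expect_error(evaluate_classifier(m, X[1:10, ], rep(1L, 10)), "both classes")
})

test_that("masking attributions have one score per heavy atom and zero out for constant scorers", {
  pool <- make_complex_pool(60)
  ds <- build_dataset(pool, "plec", featurizer_config(plec_cutoff = 4))
  m <- train_random_forest(ds$X, ds$y, "plec", featurizer_config(plec_cutoff = 4),
                           num_trees = 100, seed = 6)
  cx <- pool$complex[[1]]
  att <- masking_attributions(m, cx)
  expect_equal(nrow(att), cx$ligand$n_heavy)
  expect_true(is.numeric(att$s))

  # a forest with no usable features scores every input identically -> s_i = 0
  X0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(40, 2048))
  X0[, 1] <- 1  # one constant feature so training is well-posed
  colnames(X0) <- paste0("b", 0:2047)
  y0 <- rep(c(0L, 1L), 20)
  m0 <- train_random_forest(X0, y0, "morgan", num_trees = 50, seed = 1)
  att0 <- masking_attributions(m0, cx)
  expect_true(all(att0$s == 0))
})

test_that("PLEC attributions single out the interacting atom", {
  # train a focused PLEC_4 model on a seeded pool, then check that the key
  # atom of single-contact complexes gets the top masking score most times
  pool <- make_complex_pool(120, seed = 900)
  cfg <- featurizer_config(plec_cutoff = 4)
  ds <- build_dataset(pool, "plec", cfg)
  m <- train_random_forest(ds$X, ds$y, "plec", cfg, num_trees = 200, seed = 6)
  hits <- 0L; total <- 0L
  for (k in 1:10) {
    lig <- small_ligands()$mol[[(k %% 12) + 1]]
    cx <- tryCatch(make_single_contact_complex(lig, generation_config("polar"),
                                               distance = 2.8, seed = 60 + k),
                   error = function(e) NULL)
    if (is.null(cx)) next
    total <- total + 1L
    att <- masking_attributions(m, cx)
    if (which.max(att$s) == cx$records$atom_idx[1]) hits <- hits + 1L
  }
  expect_gte(total, 5L)
  expect_gte(hits / total, 0.7)
})

test_that("tidy and glance methods summarise models and reports", {
  pool <- make_complex_pool(60)
  ds <- build_dataset(pool, "morgan")
  m <- train_random_forest(ds$X, ds$y, "morgan", num_trees = 50, seed = 2)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$model, "RF_Morgan")
  expect_equal(td$num_trees, 50)

  acts <- pool[pool$label == "active", ]
  contribs <- lapply(acts$complex, `[[`, "contributions")
  rep <- metrics_report(contribs, acts)
  expect_s3_class(tidy(rep), "tbl_df")
  gl <- glance(rep)
  expect_equal(gl$n_complexes, nrow(acts))
  expect_equal(gl$mean_attribution_auc, 1.0)
})
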