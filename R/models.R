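#' Random-forest baseline models and masking attributions
#'
#' The baselines follow the standard naming convention: `RF_Morgan` for a
#' ligand-only forest on Morgan fingerprints and `RF_PLEC_n` for a forest on
#' PLEC-style fingerprints with distance cutoff `n` (Angstrom). Per-atom
#' attributions use atom masking: `s_i = score(m) - score(m \ i)`, the drop
#' in the model's active-class probability when atom `i` is replaced by a
#' dummy atom.
#'
#' @name models
NULL

#' Build a fingerprint dataset from complexes
#'
#' @param complexes Complex-set tibble (all sharing one rule).
#' @param featurizer `"morgan"` or `"plec"`.
#' @param config A [featurizer_config()].
#' @return List: sparse feature matrix `X` (row i = complex i), integer
#'   label vector `y` (1 = active), `ids`, `featurizer`, `config`.
#' @export
build_dataset <- function(complexes, featurizer = c("morgan", "plec"),
                          config = featurizer_config()) {
  featurizer <- match.arg(featurizer)
  assert_that(nrow(complexes) >= 1, "empty complex set")
  assert_that(length(unique(complexes$rule)) == 1,
              "all complexes must share one binding rule")
  fps <- vector("list", nrow(complexes))
  ok <- logical(nrow(complexes))
  for (i in seq_len(nrow(complexes))) {
    fp <- tryCatch({
      if (featurizer == "morgan") morgan_fingerprint(complexes$complex[[i]]$ligand, config)
      else plec_fingerprint(complexes$complex[[i]], config)
    }, error = function(e) NULL)
    if (is.null(fp)) {
      warn(sprintf("featurization failed for complex '%s'; skipped", complexes$id[i]))
    } else {
      fps[[i]] <- fp; ok[i] <- TRUE
    }
  }
  assert_that(any(ok), "featurization failed for every complex")
  list(X = fingerprint_matrix(fps[ok]),
       y = as.integer(complexes$label[ok] == "active"),
       ids = complexes$id[ok],
       featurizer = featurizer, config = config)
}

#' Train a random-forest classifier on a fingerprint matrix
#'
#' A probability forest (default 500 trees, sqrt(p) candidate features per
#' split, unlimited depth), seeded and single-threaded so identical inputs
#' give identical predictions.
#'
#' @param X Feature matrix (sparse `dgCMatrix` or dense).
#' @param y Integer/factor labels with both classes present (1 = active).
#' @param featurizer,config Featurizer tag and [featurizer_config()] snapshot
#'   stored with the model (used by [masking_attributions()]).
#' @param num_trees,mtry Forest hyperparameters (`mtry = NULL`: sqrt(p)).
#' @param seed Integer seed.
#' @return An `sb_rf_model` with the conventional model name.
#' @export
train_random_forest <- function(X, y, featurizer = "morgan",
                                config = featurizer_config(),
                                num_trees = 500L, mtry = NULL, seed = 1L) {
  y <- as.integer(as.character(factor(y, levels = c(0, 1), labels = c(0, 1))))
  assert_that(length(unique(y)) == 2, "training labels must contain both classes")
  fit <- ranger::ranger(
    x = X, y = factor(y, levels = c(0L, 1L)),
    num.trees = num_trees,
    mtry = mtry %||% max(1L, floor(sqrt(ncol(X)))),
    probability = TRUE, seed = as.integer(seed %% 2147483647),
    num.threads = 1L, verbose = FALSE
  )
  name <- if (featurizer == "morgan") "RF_Morgan" else
    sprintf("RF_PLEC_%s", format(config$plec_cutoff))
  structure(list(fit = fit, featurizer = featurizer, config = config,
                 name = name, seed = as.integer(seed %% 2147483647)),
            class = "sb_rf_model")
}

#' @exportS3Method base::print
print.sb_rf_model <- function(x, ...) {
  cat(sprintf("<sb_rf_model> %s: %d trees, %d features, OOB error %.4f\n",
              x$name, x$fit$num.trees, x$fit$num.independent.variables,
              x$fit$prediction.error))
  invisible(x)
}

#' Active-class probability scores
#'
#' @param model An `sb_rf_model`.
#' @param X Feature matrix with the model's bit layout.
#' @return Numeric scores in \[0, 1\].
#' @export
predict_score <- function(model, X) {
  p <- predict(model$fit, data = X, num.threads = 1L)$predictions
  as.numeric(p[, "1"])
}

# Average precision (step-wise integral of the precision-recall curve),
# active class positive.
average_precision <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1]) / sum(lab)
}

#' Evaluate a classifier on a test set
#'
#' Accuracy at score threshold 0.5; the random-accuracy baseline
#' `max(fraction active, fraction inactive)`; area under the
#' precision-recall curve (average precision, actives positive); and
#' balanced variants computed on a label-balanced resample of the test set
#' (majority class down-sampled, seeded).
#'
#' @param model An `sb_rf_model`.
#' @param X_test,y_test Test features and 0/1 labels (both classes required).
#' @param seed Seed for the balanced resample.
#' @return One-row tibble: `model`, `accuracy`, `random_accuracy`, `au_prc`,
#'   `balanced_accuracy`, `balanced_au_prc`, `n_test`.
#' @export
evaluate_classifier <- function(model, X_test, y_test, seed = 1L) {
  y_test <- as.integer(y_test)
  assert_that(length(unique(y_test)) == 2,
              "test labels must contain both classes for AU-PRC")
  s <- predict_score(model, X_test)
  acc <- mean((s > 0.5) == (y_test == 1))
  rand_acc <- max(mean(y_test == 1), mean(y_test == 0))
  auprc <- average_precision(s, y_test)
  idx_a <- which(y_test == 1); idx_i <- which(y_test == 0)
  n_bal <- min(length(idx_a), length(idx_i))
  bal <- with_seed(derive_seed(seed, 1L, "balance"), {
    sel <- c(sample(idx_a, n_bal), sample(idx_i, n_bal))
    list(acc = mean((s[sel] > 0.5) == (y_test[sel] == 1)),
         auprc = average_precision(s[sel], y_test[sel]))
  })
  tibble::tibble(model = model$name, accuracy = acc,
                 random_accuracy = rand_acc, au_prc = auprc,
                 balanced_accuracy = bal$acc, balanced_au_prc = bal$auprc,
                 n_test = length(y_test))
}

#' Per-atom masking attributions
#'
#' For every heavy atom, `s_i = score(m) - score(m \ i)`: the unmasked
#' active-class probability minus the probability with atom `i` replaced by
#' a dummy ([mask_atom()]). Higher `s_i` means greater importance. All
#' masked variants are featurized and scored in one batch.
#'
#' @param model An `sb_rf_model` (its stored featurizer and config are used).
#' @param complex An `sb_complex`.
#' @return An `sb_attributions` tibble (`atom`, `s`) with attribute
#'   `score_unmasked`.
#' @export
masking_attributions <- function(model, complex) {
  n <- complex$ligand$n_heavy
  feat_one <- function(cx) {
    if (model$featurizer == "morgan") morgan_fingerprint(cx$ligand, model$config)
    else plec_fingerprint(cx, model$config)
  }
  fps <- vector("list", n + 1L)
  fps[[1]] <- feat_one(complex)
  failed <- logical(n)
  for (i in seq_len(n)) {
    fps[[i + 1L]] <- tryCatch(feat_one(mask_atom(complex, i)),
                              error = function(e) NULL)
    failed[i] <- is.null(fps[[i + 1L]])
  }
  keep <- c(TRUE, !failed)
  scores <- predict_score(model, fingerprint_matrix(fps[keep]))
  s <- rep(NA_real_, n)
  s[!failed] <- scores[1] - scores[-1]
  if (any(failed)) {
    warn(sprintf("masking featurization failed for %d atom(s)", sum(failed)))
  }
  out <- tibble::tibble(atom = seq_len(n), s = s)
  structure(out, score_unmasked = scores[1],
            class = c("sb_attributions", class(out)))
}
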