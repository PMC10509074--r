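#' End-to-end dataset and benchmark workflows
#'
#' Reproducible pipelines over the generator, featurizers, models and
#' metrics: unbiased dataset construction with a ligand-bias diagnostic,
#' bias-matched construction from externally labelled ligands, active-only
#' test-set construction, the multi-cutoff random-forest benchmark, and the
#' single-interaction perturbation case study. Every workflow is a pure
#' function of (inputs, config, seed) and writes a manifest when given an
#' output directory.
#'
#' @name workflows
NULL

workflow_manifest <- function(out_dir, config, seed, extra = list()) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(list(
    package = "synthbind",
    version = as.character(utils::packageVersion("synthbind")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = unclass(config)
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

labels_table <- function(complexes) {
  complexes[, c("id", "ligand_id", "rule", "label", "total_score", "n_heavy")]
}

#' Build an unbiased synthetic dataset
#'
#' Generates one unconditioned complex per ligand and emits a ligand-bias
#' diagnostic: the distribution of interactable-atom counts per ligand,
#' split by label. If actives and decoys show near-identical distributions,
#' a ligand-only model has no trivial signal to exploit.
#'
#' @param ligands Ligand-set tibble with 3D conformations.
#' @param config A [generation_config()].
#' @param seed Integer seed.
#' @param out_dir Optional output directory (manifest, labels CSV,
#'   diagnostic CSV; per-complex structure files if `write_structures`).
#' @param write_structures Write per-complex SDF/PDB/CSV file sets.
#' @return List: `complexes` (complex-set tibble), `diagnostic` tibble
#'   (`label`, `n_interactable`, `n_ligands`), `active_fraction`,
#'   `rejected` (ids with `n_lig = 0`).
#' @export
run_dataset_build <- function(ligands, config, seed, out_dir = NULL,
                              write_structures = FALSE) {
  complexes <- generate_complexes(ligands, config, seed)
  n_int <- vapply(complexes$complex, function(cx) n_lig(cx$assignment), integer(1))
  diagnostic <- dplyr::count(
    tibble::tibble(label = complexes$label, n_interactable = n_int),
    .data$label, .data$n_interactable, name = "n_ligands")
  active_fraction <- mean(complexes$label == "active")
  if (!is.null(out_dir)) {
    workflow_manifest(out_dir, config, seed,
                      list(n_ligands = nrow(ligands),
                           n_complexes = nrow(complexes),
                           n_rejected = length(attr(complexes, "rejected")),
                           active_fraction = active_fraction))
    write.csv(labels_table(complexes), file.path(out_dir, "labels.csv"),
              row.names = FALSE)
    write.csv(diagnostic, file.path(out_dir, "bias_diagnostic.csv"),
              row.names = FALSE)
    if (write_structures) {
      for (cx in complexes$complex) write_complex(cx, file.path(out_dir, "complexes"))
    }
  }
  list(complexes = complexes, diagnostic = diagnostic,
       active_fraction = active_fraction,
       rejected = attr(complexes, "rejected"))
}

#' Build a bias-matched dataset from externally labelled ligands
#'
#' For each ligand, resamples the synthetic protein until the rule label
#' matches the ligand's external label (at most `max_attempts` proteins);
#' ligands that never match are discarded and logged. The resulting dataset
#' carries the external labels' ligand-specific bias while every kept
#' complex is consistent with the binding rule.
#'
#' @param labelled_ligands Ligand-set tibble with an extra `label` column
#'   ("active"/"inactive").
#' @param config A [generation_config()].
#' @param seed Integer seed.
#' @param max_attempts Resampling budget per ligand (>= 1).
#' @param out_dir Optional output directory.
#' @return List: `complexes`, `discard_log` tibble (`ligand_id`, `target`,
#'   `attempts`, `discarded`).
#' @export
run_bias_matched_build <- function(labelled_ligands, config, seed,
                                   max_attempts = 100L, out_dir = NULL) {
  assert_that(max_attempts >= 1, "max_attempts must be >= 1")
  assert_that("label" %in% names(labelled_ligands),
              "labelled_ligands needs a 'label' column")
  cxs <- list()
  log <- vector("list", nrow(labelled_ligands))
  for (i in seq_len(nrow(labelled_ligands))) {
    target <- labelled_ligands$label[i]
    cx <- generate_conditioned(labelled_ligands$mol[[i]], config, target,
                               max_attempts, derive_seed(seed, i, "match"))
    discarded <- is.null(cx)
    log[[i]] <- tibble::tibble(ligand_id = labelled_ligands$id[i],
                               target = target,
                               attempts = attr(cx, "attempts") %||% max_attempts,
                               discarded = discarded)
    if (!discarded) cxs[[length(cxs) + 1L]] <- cx
  }
  discard_log <- dplyr::bind_rows(log)
  complexes <- complex_set(cxs)
  if (!is.null(out_dir)) {
    workflow_manifest(out_dir, config, seed,
                      list(n_ligands = nrow(labelled_ligands),
                           n_complexes = nrow(complexes),
                           n_discarded = sum(discard_log$discarded),
                           max_attempts = max_attempts))
    write.csv(labels_table(complexes), file.path(out_dir, "labels.csv"),
              row.names = FALSE)
    write.csv(discard_log, file.path(out_dir, "discard_log.csv"),
              row.names = FALSE)
  }
  list(complexes = complexes, discard_log = discard_log)
}

#' Build an active-only external test set
#'
#' Filters candidate ligands against the training references (Tanimoto and
#' heavy-atom-count criteria), randomly selects `n`, and pairs each with a
#' synthetic protein resampled until the complex is active. Emits a
#' ground-truth contribution summary: the fraction of atoms with zero
#' contribution and the fractions above scores 1 and 2.
#'
#' @param ligands Candidate ligand-set tibble (3D).
#' @param references Reference (training) ligand-set tibble; empty set
#'   applies the size criterion only.
#' @param config A [generation_config()].
#' @param n Test-set size.
#' @param seed Integer seed.
#' @param max_tanimoto,min_heavy Filter parameters.
#' @param max_attempts Resampling budget per ligand.
#' @param out_dir Optional output directory.
#' @return List: `complexes` (all active), `contribution_summary`,
#'   `discarded` (ids never active within the budget).
#' @export
run_active_testset_build <- function(ligands, references, config, n = 500L,
                                     seed = 1L, max_tanimoto = 0.8,
                                     min_heavy = 15L, max_attempts = 100L,
                                     out_dir = NULL) {
  pool <- similarity_and_size_filter(ligands, references, max_tanimoto, min_heavy)
  if (nrow(pool) < n) {
    abort(sprintf("only %d ligands survive the filters; %d requested (short by %d)",
                  nrow(pool), n, n - nrow(pool)))
  }
  sel <- with_seed(derive_seed(seed, 0L, "testset"),
                   sort(sample.int(nrow(pool), n)))
  pool <- pool[sel, , drop = FALSE]
  cxs <- list()
  discarded <- character(0)
  for (i in seq_len(nrow(pool))) {
    cx <- generate_conditioned(pool$mol[[i]], config, "active",
                               max_attempts, derive_seed(seed, i, "act"))
    if (is.null(cx)) discarded <- c(discarded, pool$id[i])
    else cxs[[length(cxs) + 1L]] <- cx
  }
  complexes <- complex_set(cxs)
  allc <- unlist(lapply(complexes$complex, `[[`, "contributions"))
  contribution_summary <- tibble::tibble(
    n_atoms = length(allc),
    frac_zero = mean(allc == 0),
    frac_above_1 = mean(allc > 1),
    frac_above_2 = mean(allc > 2)
  )
  if (!is.null(out_dir)) {
    workflow_manifest(out_dir, config, seed,
                      list(n_requested = n, n_complexes = nrow(complexes),
                           n_discarded = length(discarded)))
    write.csv(labels_table(complexes), file.path(out_dir, "labels.csv"),
              row.names = FALSE)
    write.csv(contribution_summary,
              file.path(out_dir, "contribution_summary.csv"), row.names = FALSE)
  }
  list(complexes = complexes, contribution_summary = contribution_summary,
       discarded = discarded)
}

#' Multi-cutoff random-forest benchmark
#'
#' Splits the complexes into a seeded random holdout and training set,
#' trains `RF_Morgan` plus one `RF_PLEC_c` per distance cutoff, and
#' evaluates accuracy and AU-PRC on the holdout. When an active-only
#' evaluation set is supplied, each model's masking attributions are scored
#' against the ground truth (mean Attribution AUC; RER for the Contribution
#' rule).
#'
#' @param complexes Complex-set tibble.
#' @param eval_complexes Optional active-only complex-set tibble for
#'   attribution metrics.
#' @param test_size Holdout size.
#' @param cutoffs PLEC distance cutoffs (Angstrom), sorted.
#' @param config Base [featurizer_config()] (its `plec_cutoff` is replaced
#'   per model).
#' @param num_trees Forest size.
#' @param seed Integer seed.
#' @return An `sb_benchmark` tibble: one row per model with classification
#'   and (optionally) attribution metrics.
#' @export
run_benchmark <- function(complexes, eval_complexes = NULL, test_size = 500L,
                          cutoffs = seq(2.5, 6, by = 0.5),
                          config = featurizer_config(), num_trees = 500L,
                          seed = 1L) {
  assert_that(test_size < nrow(complexes), "test_size must be below the dataset size")
  assert_that(all(cutoffs > 0) && !is.unsorted(cutoffs), "cutoffs must be positive and sorted")
  idx_test <- with_seed(derive_seed(seed, 0L, "split"),
                        sort(sample.int(nrow(complexes), test_size)))
  train <- complexes[-idx_test, , drop = FALSE]
  test <- complexes[idx_test, , drop = FALSE]

  fit_eval <- function(featurizer, cfg) {
    ds_train <- build_dataset(train, featurizer, cfg)
    ds_test <- build_dataset(test, featurizer, cfg)
    model <- train_random_forest(ds_train$X, ds_train$y, featurizer, cfg,
                                 num_trees = num_trees,
                                 seed = derive_seed(seed, 1L, featurizer))
    row <- evaluate_classifier(model, ds_test$X, ds_test$y,
                               seed = derive_seed(seed, 2L, featurizer))
    if (!is.null(eval_complexes)) {
      attrs <- lapply(eval_complexes$complex, function(cx) {
        masking_attributions(model, cx)$s
      })
      rep <- metrics_report(attrs, eval_complexes)
      row$attribution_auc <- rep$mean_attribution_auc
      row$spearman <- rep$mean_spearman
      row$rer <- rep$rer
    }
    row$cutoff <- if (featurizer == "plec") cfg$plec_cutoff else NA_real_
    list(row = row, model = model)
  }

  results <- list()
  models <- list()
  m <- fit_eval("morgan", config)
  results[[1]] <- m$row; models[["RF_Morgan"]] <- m$model
  for (cutoff in cutoffs) {
    cfg <- config
    cfg$plec_cutoff <- cutoff
    p <- fit_eval("plec", cfg)
    results[[length(results) + 1L]] <- p$row
    models[[p$model$name]] <- p$model
  }
  out <- dplyr::bind_rows(results)
  structure(out, models = models, class = c("sb_benchmark", class(out)))
}

#' Single-interaction base complex for the perturbation study
#'
#' Builds a Polar-rule complex whose activity rests on exactly one
#' interaction: a complementary residue placed at `distance` from a chosen
#' polar ligand atom, plus optional far (non-interacting) residues sampled
#' outside the cutoff.
#'
#' @param ligand An `sb_ligand` with a 3D conformation and at least one
#'   Donor or Acceptor atom.
#' @param config A polar [generation_config()].
#' @param distance Residue-atom distance in Angstrom (inside the cutoff).
#' @param n_far Number of additional non-interacting residues.
#' @param seed Integer seed.
#' @return An `sb_complex` with exactly one interaction record.
#' @export
make_single_contact_complex <- function(ligand, config = generation_config("polar"),
                                        distance = 2.8, n_far = 0L, seed = 1L) {
  assert_that(identical(config$rule, "polar"),
              "the perturbation base uses the polar rule")
  assignment <- assign_pharmacophores(ligand, "polar")
  polar_atoms <- which(assignment$donor | assignment$acceptor)
  assert_that(length(polar_atoms) >= 1, "ligand has no Donor/Acceptor atom")
  xyz <- ligand_coords(ligand)
  box <- make_box(ligand, config$pad)
  place_contact <- function() {
    for (try_atom in polar_atoms[sample(seq_along(polar_atoms))]) {
      rtype <- if (assignment$donor[try_atom]) "HBA" else "HBD"
      # the key atom must be the *only* in-range complementary partner
      partner_ok <- if (rtype == "HBA") assignment$donor else assignment$acceptor
      others <- which(partner_ok & seq_len(nrow(xyz)) != try_atom)
      for (k in seq_len(200L)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        pos <- xyz[try_atom, ] + distance * u
        d_all <- sqrt(colSums((t(xyz) - pos)^2))
        inside <- all(pos >= box$lo) && all(pos <= box$hi)
        if (inside && all(d_all >= config$clash_dist) &&
            (!length(others) || all(d_all[others] >= config$polar_cutoff))) {
          return(list(atom = try_atom, type = rtype, pos = pos))
        }
      }
    }
    NULL
  }
  res <- with_seed(derive_seed(seed, 0L, "single"), place_contact())
  assert_that(!is.null(res),
              "could not place a single-contact residue for this ligand")
  residues <- tibble::tibble(x = res$pos[1], y = res$pos[2], z = res$pos[3],
                             type = res$type)
  if (n_far > 0) {
    far <- with_seed(derive_seed(seed, 2L, "far"), {
      out <- matrix(NA_real_, 0, 3)
      types <- character(0)
      guard <- 0L
      while (nrow(out) < n_far && guard < 2000L) {
        guard <- guard + 1L
        p <- runif(3, box$lo, box$hi)
        d_all <- sqrt(colSums((t(xyz) - p)^2))
        d_res <- if (nrow(out)) sqrt(colSums((t(out) - p)^2)) else Inf
        prev <- sqrt(sum((p - res$pos)^2))
        if (all(d_all >= config$polar_cutoff) && all(d_res >= config$min_sep) &&
            prev >= config$min_sep) {
          out <- rbind(out, p)
          types <- c(types, sample(c("HBA", "HBD"), 1))
        }
      }
      list(out = out, types = types)
    })
    if (nrow(far$out)) {
      residues <- dplyr::bind_rows(residues,
                                   tibble::tibble(x = far$out[, 1], y = far$out[, 2],
                                                  z = far$out[, 3], type = far$types))
    }
  }
  protein <- structure(list(residues = residues, box = box,
                            n_res_cap = nrow(residues)), class = "sb_protein")
  cx <- build_complex(ligand, assignment, protein, config, seed)
  assert_that(nrow(cx$records) == 1, "base complex does not have exactly one interaction")
  cx
}

#' Residue-distance perturbation case study
#'
#' Starting from a Polar-active complex with exactly one interaction, moves
#' the interacting residue along the atom-to-residue axis to each requested
#' distance, recomputes every model's masking attributions, and records the
#' rank of the key ligand atom. PLEC-based models are expected to rank the
#' key atom highly while the residue lies inside their distance cutoff and
#' to drop it beyond.
#'
#' @param base_complex An `sb_complex` with exactly one interaction record
#'   (see [make_single_contact_complex()]).
#' @param models List of `sb_rf_model` objects.
#' @param distances Residue-atom distances to probe (Angstrom).
#' @return An `sb_perturbation` tibble: `model`, `cutoff`, `distance`,
#'   `key_atom`, `rank`, `n_heavy`, `label`.
#' @export
run_perturbation_study <- function(base_complex, models,
                                   distances = seq(1.5, 10, length.out = 50)) {
  assert_that(nrow(base_complex$records) == 1,
              "base complex must have exactly one interaction record")
  key_atom <- base_complex$records$atom_idx[1]
  key_res <- base_complex$records$residue_idx[1]
  xyz_atom <- ligand_coords(base_complex$ligand)[key_atom, ]
  res0 <- as.numeric(base_complex$protein$residues[key_res, c("x", "y", "z")])
  u <- res0 - xyz_atom
  u <- u / sqrt(sum(u^2))
  if (is.null(names(models))) {
    names(models) <- vapply(models, `[[`, character(1), "name")
  }
  rows <- list()
  for (d in distances) {
    cx <- base_complex
    pos <- xyz_atom + d * u
    cx$protein$residues[key_res, c("x", "y", "z")] <- as.list(pos)
    cx <- build_complex(cx$ligand, cx$assignment, cx$protein, cx$config, cx$seed)
    for (nm in names(models)) {
      att <- masking_attributions(models[[nm]], cx)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = nm,
        cutoff = models[[nm]]$config$plec_cutoff %||% NA_real_,
        distance = d,
        key_atom = key_atom,
        rank = importance_ranks(att$s)[key_atom],
        n_heavy = cx$ligand$n_heavy,
        label = cx$label
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("sb_perturbation", class(out)))
}
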