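#' Attribution metrics
#'
#' Scores per-atom model attributions against the exactly known ground truth
#' of the synthetic binding rules:
#'
#' * **Attribution AUC** (Polar rule): sort atoms by attribution; 1 minus the
#'   number of adjacent transpositions needed to move every binding atom
#'   above every non-binding atom, divided by the worst case
#'   (`n_binders * n_non_binders`). Equivalently the fraction of concordant
#'   (binder, non-binder) pairs; tied scores count one half.
#' * **Spearman rho** between attributions and true contributions
#'   (Contribution rule), mid-ranks for ties, per complex.
#' * **MATR** (mean above-threshold ranking): the mean attribution rank
#'   (rank 1 = most important) of all atoms whose true contribution exceeds
#'   a threshold `t`, pooled across the dataset. Lower is better.
#' * **RER** (relative efficiency of ranking): `MATR(model) /
#'   MATR(ground-truth ranking)` at a threshold (default `t = 0.96`);
#'   1.00 is optimal.
#'
#' @name attribution_metrics
NULL

#' Attribution AUC for binary binder masks
#'
#' @param scores Per-atom attribution values.
#' @param binder_mask Per-atom logical (TRUE = atom participates in binding).
#' @return Value in \[0, 1\], or `NA` for degenerate masks (no binder or no
#'   non-binder).
#' @export
attribution_auc <- function(scores, binder_mask) {
  binder_mask <- as.logical(binder_mask)
  assert_that(length(scores) == length(binder_mask),
              "scores and binder_mask lengths differ")
  sb <- scores[binder_mask]
  sn <- scores[!binder_mask]
  if (!length(sb) || !length(sn)) return(NA_real_)
  cmp <- outer(sb, sn, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(sb) * length(sn))
}

#' Spearman rank correlation between attributions and ground truth
#'
#' @param scores Per-atom attribution values.
#' @param true_contributions Per-atom ground-truth contributions.
#' @return Spearman rho, or `NA` for degenerate inputs (fewer than 3 atoms
#'   or a constant vector).
#' @export
spearman_attribution <- function(scores, true_contributions) {
  if (length(scores) < 3 ||
      length(unique(scores)) < 2 || length(unique(true_contributions)) < 2) {
    return(NA_real_)
  }
  cor(scores, true_contributions, method = "spearman")
}

# rank 1 = highest attribution, mid-ranks for ties
importance_ranks <- function(scores) {
  rank(-scores, ties.method = "average")
}

#' Mean above-threshold ranking
#'
#' Within each complex, atoms are ranked by attribution (rank 1 = most
#' important, mid-ranks for ties); the ranks of all atoms with true
#' contribution > `t` are pooled across the dataset and averaged.
#'
#' @param attributions List of per-atom attribution vectors (one per complex).
#' @param contributions List of matching ground-truth contribution vectors.
#' @param t Contribution threshold.
#' @return Mean rank (>= 1).
#' @export
matr <- function(attributions, contributions, t) {
  assert_that(length(attributions) == length(contributions),
              "attribution and contribution lists differ in length")
  pooled <- unlist(purrr::map2(attributions, contributions, function(a, g) {
    importance_ranks(a)[g > t]
  }), use.names = FALSE)
  if (!length(pooled)) {
    abort(sprintf("MATR undefined: no atom has true contribution > %g", t))
  }
  mean(pooled)
}

#' Relative efficiency of ranking
#'
#' `MATR(model attributions) / MATR(ground-truth ranking)` at threshold `t`.
#' The ground-truth ranking orders atoms by their true contribution, so a
#' model whose attributions reproduce the ground truth scores exactly 1.00.
#'
#' @param model_attributions List of per-atom attribution vectors.
#' @param ground_truth_contributions List of matching contribution vectors.
#' @param t Contribution threshold (default 0.96, the ten-percent-of-atoms
#'   threshold used for reporting).
#' @return RER ratio.
#' @export
rer <- function(model_attributions, ground_truth_contributions, t = 0.96) {
  matr(model_attributions, ground_truth_contributions, t) /
    matr(ground_truth_contributions, ground_truth_contributions, t)
}

#' Random-attribution baseline
#'
#' Draws i.i.d. uniform attribution scores for every atom of every complex
#' and averages the metric over replicates: mean Attribution AUC for the
#' Polar rule, RER for the Contribution rule.
#'
#' @param complexes Complex-set tibble carrying ground truth.
#' @param metric `"auc"` or `"rer"`.
#' @param n_replicates Number of random-score replicates.
#' @param t RER threshold (Contribution only).
#' @param seed Integer seed.
#' @return Mean metric value over replicates; attribute `per_replicate`
#'   holds the replicate values.
#' @export
random_attribution_baseline <- function(complexes, metric = c("auc", "rer"),
                                        n_replicates = 5L, t = 0.96, seed = 1L) {
  metric <- match.arg(metric)
  assert_that(n_replicates >= 1, "n_replicates must be >= 1")
  contribs <- lapply(complexes$complex, `[[`, "contributions")
  vals <- vapply(seq_len(n_replicates), function(r) {
    with_seed(derive_seed(seed, r, "randbase"), {
      rand <- lapply(contribs, function(g) runif(length(g)))
      if (metric == "auc") {
        aucs <- purrr::map2_dbl(rand, contribs, function(a, g) {
          attribution_auc(a, g > 0)
        })
        mean(aucs, na.rm = TRUE)
      } else {
        rer(rand, contribs, t)
      }
    })
  }, numeric(1))
  structure(mean(vals), per_replicate = vals)
}

#' Dataset-level attribution metrics report
#'
#' Computes per-complex Attribution AUC and Spearman rho for a list of
#' attribution vectors against a complex set's ground truth, plus the MATR
#' curve over a threshold grid and the RER at the reporting threshold.
#' Degenerate complexes (no binder or no non-binder atoms; constant vectors)
#' are skipped and counted.
#'
#' @param attributions List of per-atom attribution vectors (one per row of
#'   `complexes`).
#' @param complexes Complex-set tibble.
#' @param matr_grid Thresholds for the MATR curve.
#' @param rer_threshold Threshold for the RER summary.
#' @return An `sb_metrics_report`: list with `per_complex` tibble,
#'   `matr_curve` tibble, and scalar summaries.
#' @export
metrics_report <- function(attributions, complexes,
                           matr_grid = seq(0, 3, by = 0.2),
                           rer_threshold = 0.96) {
  assert_that(length(attributions) == nrow(complexes),
              "one attribution vector per complex required")
  contribs <- lapply(complexes$complex, `[[`, "contributions")
  per <- tibble::tibble(
    id = complexes$id,
    label = complexes$label,
    attribution_auc = purrr::map2_dbl(attributions, contribs,
                                      function(a, g) attribution_auc(a, g > 0)),
    spearman = purrr::map2_dbl(attributions, contribs, spearman_attribution)
  )
  curve <- tibble::tibble(
    t = matr_grid,
    matr_model = vapply(matr_grid, function(tt) {
      tryCatch(matr(attributions, contribs, tt), error = function(e) NA_real_)
    }, numeric(1)),
    matr_perfect = vapply(matr_grid, function(tt) {
      tryCatch(matr(contribs, contribs, tt), error = function(e) NA_real_)
    }, numeric(1))
  )
  rer_val <- tryCatch(rer(attributions, contribs, rer_threshold),
                      error = function(e) NA_real_)
  structure(list(
    per_complex = per,
    matr_curve = curve,
    mean_attribution_auc = mean(per$attribution_auc, na.rm = TRUE),
    mean_spearman = mean(per$spearman, na.rm = TRUE),
    rer = rer_val,
    rer_threshold = rer_threshold,
    n_complexes = nrow(per),
    n_skipped_auc = sum(is.na(per$attribution_auc)),
    n_skipped_spearman = sum(is.na(per$spearman))
  ), class = "sb_metrics_report")
}

#' @exportS3Method base::print
print.sb_metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<sb_metrics_report> %d complexes\n",
                     "  mean Attribution AUC: %.3f (%d skipped)\n",
                     "  mean Spearman rho:    %.3f (%d skipped)\n",
                     "  RER(t = %.2f):        %.3f\n"),
              x$n_complexes, x$mean_attribution_auc, x$n_skipped_auc,
              x$mean_spearman, x$n_skipped_spearman,
              x$rer_threshold, x$rer))
  invisible(x)
}

#' Write a metrics report to CSV/JSON files
#'
#' @param report An `sb_metrics_report`.
#' @param out_dir Output directory.
#' @param prefix File-name prefix.
#' @export
write_metrics_report <- function(report, out_dir, prefix = "metrics") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$per_complex,
            file.path(out_dir, paste0(prefix, "_per_complex.csv")),
            row.names = FALSE)
  write.csv(report$matr_curve,
            file.path(out_dir, paste0(prefix, "_matr_curve.csv")),
            row.names = FALSE)
  jsonlite::write_json(
    report[c("mean_attribution_auc", "mean_spearman", "rer", "rer_threshold",
             "n_complexes", "n_skipped_auc", "n_skipped_spearman")],
    file.path(out_dir, paste0(prefix, "_summary.json")), auto_unbox = TRUE)
  invisible(out_dir)
}
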