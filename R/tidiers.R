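#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted random-forest baseline
#'
#' One row per feature with non-zero split importance (impurity importance
#' is not stored by default, so this reports the forest's variable usage
#' summary: the number of features and trees).
#'
#' @param x An `sb_rf_model`.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.sb_rf_model <- function(x, ...) {
  tibble::tibble(
    model = x$name,
    featurizer = x$featurizer,
    num_trees = x$fit$num.trees,
    mtry = x$fit$mtry,
    num_features = x$fit$num.independent.variables,
    oob_brier = x$fit$prediction.error
  )
}

#' @rdname tidy.sb_rf_model
#' @export
glance.sb_rf_model <- function(x, ...) {
  tidy.sb_rf_model(x)
}

#' Tidy an attribution metrics report
#'
#' `tidy()` returns the per-complex metric table; `glance()` the one-row
#' dataset summary.
#'
#' @param x An `sb_metrics_report`.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.sb_metrics_report <- function(x, ...) {
  x$per_complex
}

#' @rdname tidy.sb_metrics_report
#' @export
glance.sb_metrics_report <- function(x, ...) {
  tibble::tibble(
    mean_attribution_auc = x$mean_attribution_auc,
    mean_spearman = x$mean_spearman,
    rer = x$rer,
    rer_threshold = x$rer_threshold,
    n_complexes = x$n_complexes,
    n_skipped_auc = x$n_skipped_auc,
    n_skipped_spearman = x$n_skipped_spearman
  )
}

#' @importFrom rlang .data
NULL
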