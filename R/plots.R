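#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_vline labs theme_minimal facet_wrap scale_x_continuous
NULL

#' Plot benchmark accuracy against PLEC cutoff
#'
#' PLEC models appear as a curve over the distance cutoff; the ligand-only
#' Morgan model as a horizontal reference.
#'
#' @param object An `sb_benchmark` from [run_benchmark()].
#' @param metric Column to plot (default `"accuracy"`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sb_benchmark <- function(object, metric = "accuracy", ...) {
  plec <- object[!is.na(object$cutoff), , drop = FALSE]
  morgan <- object[is.na(object$cutoff), , drop = FALSE]
  p <- ggplot(plec, aes(x = .data$cutoff, y = .data[[metric]])) +
    geom_line(colour = "#2c7fb8") +
    geom_point(colour = "#2c7fb8") +
    labs(x = "PLEC distance cutoff (Å)", y = metric,
         title = "Random-forest performance across PLEC cutoffs") +
    theme_minimal()
  if (nrow(morgan) && metric %in% names(morgan)) {
    p <- p + ggplot2::geom_hline(yintercept = morgan[[metric]][1],
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a MATR curve
#'
#' Mean above-threshold ranking of the model attributions and of the
#' ground-truth (perfect) ranking over the threshold grid.
#'
#' @param object An `sb_metrics_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sb_metrics_report <- function(object, ...) {
  curve <- tidyr::pivot_longer(object$matr_curve,
                               cols = c("matr_model", "matr_perfect"),
                               names_to = "ranking", values_to = "matr")
  curve$ranking <- ifelse(curve$ranking == "matr_model", "model", "perfect")
  ggplot(curve, aes(x = .data$t, y = .data$matr, colour = .data$ranking)) +
    geom_line() +
    labs(x = "contribution threshold t", y = "mean above-threshold rank",
         colour = NULL, title = "MATR curve") +
    theme_minimal()
}

#' Plot the perturbation case study
#'
#' Rank of the key ligand atom as the interacting residue is moved away,
#' one curve per model, with each model's distance cutoff marked.
#'
#' @param object An `sb_perturbation` from [run_perturbation_study()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sb_perturbation <- function(object, ...) {
  cuts <- unique(object[!is.na(object$cutoff), c("model", "cutoff")])
  p <- ggplot(object, aes(x = .data$distance, y = .data$rank,
                          colour = .data$model)) +
    geom_line() +
    labs(x = "residue–atom distance (Å)", y = "rank of key atom",
         colour = NULL,
         title = "Key-atom rank vs. residue distance") +
    theme_minimal()
  if (nrow(cuts)) {
    p <- p + geom_vline(data = cuts,
                        aes(xintercept = .data$cutoff, colour = .data$model),
                        linetype = "dotted", show.legend = FALSE)
  }
  p
}

#' Plot the ligand-bias diagnostic
#'
#' Distribution of interactable-atom counts per ligand, by label. Matching
#' distributions indicate a dataset free of this ligand-specific bias.
#'
#' @param diagnostic The `diagnostic` tibble from [run_dataset_build()].
#' @return A ggplot object.
#' @export
plot_bias_diagnostic <- function(diagnostic) {
  ggplot(diagnostic, aes(x = .data$n_interactable, y = .data$n_ligands)) +
    geom_col(fill = "#2c7fb8") +
    facet_wrap(~label, ncol = 1) +
    labs(x = "interactable atoms per ligand", y = "ligands",
         title = "Ligand-bias diagnostic") +
    theme_minimal()
}
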