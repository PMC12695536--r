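#' Plot per-type validation correlations
#'
#' Bar plot of the per-cell-type Pearson r between true and estimated
#' proportions, with the validation threshold as a dashed line.
#'
#' @param object A `validation_report` from [evaluate_deconv()].
#' @param r_threshold Threshold line (default 0.70).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, r_threshold = 0.70, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$cell_type,
                                                  -.data$pearson_r),
                               y = .data$pearson_r,
                               fill = .data$validated)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = r_threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Pearson r (true vs estimated)",
                  fill = "validated") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot estimated composition per sample
#'
#' Stacked bar plot of estimated cell-type proportions, the standard view of
#' a deconvolved cohort.
#'
#' @param object A [deconv_result()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deconv_result
#' @export
autoplot.deconv_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample, y = .data$proportion,
                               fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "estimated proportion", fill = NULL,
                  title = sprintf("engine: %s", object$engine)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot tumor / residue / TME partition per sample
#'
#' @param object A `contamination_report` from [contamination_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contamination_report
#' @export
autoplot.contamination_report <- function(object, ...) {
  long <- object |>
    select("sample", "tumor_fraction", "same_lineage_fraction",
           "residual_normal_fraction", "tme_fraction") |>
    tidyr::pivot_longer(-"sample", names_to = "component",
                        values_to = "fraction") |>
    mutate(component = factor(
      .data$component,
      levels = c("tumor_fraction", "same_lineage_fraction",
                 "residual_normal_fraction", "tme_fraction")
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$fraction,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Scatter plots of estimated vs true proportions per cell type
#'
#' @param mixtures A [mixture_set()].
#' @param result A [deconv_result()] on the same samples.
#' @return A ggplot object, facetted by cell type.
#' @export
plot_truth_scatter <- function(mixtures, result) {
  df <- proportions_vs_truth(mixtures, result)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true_proportion,
                                   y = .data$proportion)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~cell_type, scales = "free") +
    ggplot2::labs(x = "true proportion", y = "estimated proportion") +
    ggplot2::theme_minimal()
}
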