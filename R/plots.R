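#' Plot the survivor counts of the identification cascade
#'
#' @param report The `stages` tibble of [apply_filter_cascade()].
#' @return A ggplot object.
#' @export
plot_filter_cascade <- function(report) {
  df <- dplyr::mutate(report,
                      stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage,
                                   y = .data$retained_n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$retained_n), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "transcripts retained",
                  title = "lncRNA identification cascade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot JS tissue-specificity score distributions
#'
#' @param specificity Output of [js_specificity()], optionally with a
#'   `category` column joined on.
#' @param cutoff Cutoff line to draw.
#' @return A ggplot object.
#' @export
plot_specificity <- function(specificity, cutoff = 0.25) {
  aes <- if ("category" %in% names(specificity)) {
    ggplot2::aes(x = .data$js_score, colour = .data$category)
  } else {
    ggplot2::aes(x = .data$js_score)
  }
  ggplot2::ggplot(dplyr::filter(specificity, !is.na(.data$js_score)), aes) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "JS tissue-specificity score", y = "density") +
    ggplot2::theme_minimal()
}

#' Heatmap of module-trait correlations
#'
#' @param module_trait The `module_trait` tibble of
#'   [kme_and_trait_correlation()].
#' @return A ggplot object.
#' @export
plot_module_trait <- function(module_trait) {
  ggplot2::ggplot(module_trait,
                  ggplot2::aes(x = .data$trait, y = .data$module,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.1g)", .data$r, .data$p)), size = 2.5) +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
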