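#' Plot pairwise sharing rates by relationship
#'
#' Dot plot of pair sharing rates grouped by true relationship label,
#' faceted by caller — a visual version of the familial relationship
#' classification test (well-behaved callers show three separated bands).
#'
#' @param pairs A pair table from [build_pair_table()].
#' @return A ggplot object.
#' @export
plot_sharing <- function(pairs) {
  ggplot2::ggplot(
    pairs,
    ggplot2::aes(x = .data$true_label, y = .data$sharing_rate,
                 colour = .data$true_label)
  ) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::facet_wrap(~source) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "pairwise sharing rate", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a Venn agreement table
#'
#' Bar chart of mean per-sample component counts per source subset, before
#' and after Mendelian filtering.
#'
#' @param venn A table from [venn_table()].
#' @return A ggplot object.
#' @export
plot_venn <- function(venn) {
  long <- tidyr::pivot_longer(
    venn, dplyr::all_of(c("mean_n_raw", "mean_n_inherited")),
    names_to = "stage", values_to = "mean_n"
  )
  long$stage <- ifelse(long$stage == "mean_n_raw", "raw", "inherited")
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$sources, y = .data$mean_n, fill = .data$stage)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "source subset (Venn cell)",
                  y = "mean components per sample", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
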