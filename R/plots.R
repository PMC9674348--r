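#' Plot per-sample total iBAQ intensity
#'
#' @param totals tibble from [sum_ibaq()].
#' @return a ggplot.
#' @export
plot_sum_ibaq <- function(totals) {
  ggplot2::ggplot(totals,
                  ggplot2::aes(x = .data$sample, y = .data$sum_ibaq,
                               fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(Sigma ~ "iBAQ"), fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot sample PCA scores
#'
#' @param pca result of [sample_pca_and_correlation()].
#' @return a ggplot.
#' @export
plot_sample_pca <- function(pca) {
  ve <- round(100 * pca$var_explained, 1)
  ggplot2::ggplot(pca$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a two-cell-type LFQ comparison
#'
#' @param tbl tibble from [pairwise_scatter()].
#' @param type_a,type_b axis labels.
#' @return a ggplot.
#' @export
plot_pairwise_scatter <- function(tbl, type_a = "A", type_b = "B") {
  ggplot2::ggplot(stats::na.omit(tbl),
                  ggplot2::aes(x = .data$mean_a, y = .data$mean_b)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = bquote(Log[2] * "(LFQ) " * .(type_a)),
                  y = bquote(Log[2] * "(LFQ) " * .(type_b))) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of a permutation-ANOVA result
#' @param object an `anova_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot anova_result
#' @export
autoplot.anova_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$F, y = -log10(pmax(.data$q, 1e-4)),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ANOVA F", y = expression(-log[10] ~ q),
                  colour = sprintf("q < %g", attr(object, "q_threshold"))) +
    ggplot2::theme_minimal()
}

#' Bar chart of top enrichment scores
#' @param object an `enrichment_result`.
#' @param top_n number of genes shown.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, top_n = 25, ...) {
  d <- dplyr::arrange(tibble::as_tibble(object),
                      dplyr::desc(.data$score_percent)) |>
    utils::head(top_n)
  d$gene <- factor(d$gene, levels = rev(d$gene))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score_percent, y = .data$gene)) +
    ggplot2::geom_col(fill = "tan3") +
    ggplot2::labs(x = "% adipose tissue enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Funnel counts of a candidate report
#' @param object a `candidate_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot candidate_report
#' @export
autoplot.candidate_report <- function(object, ...) {
  g <- glance(object)
  d <- tibble::tibble(
    stage = factor(c("CM-detected", "CM & score-pass", "candidates"),
                   levels = c("CM-detected", "CM & score-pass", "candidates")),
    n = c(g$n_cm, g$n_cm_and_enriched, g$n_candidates)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot iBAQ abundance ranking coloured by cluster
#'
#' @param abundance tibble from [rank_by_abundance()].
#' @return a ggplot.
#' @export
plot_abundance_rank <- function(abundance) {
  ggplot2::ggplot(abundance,
                  ggplot2::aes(x = .data$rank, y = log10(pmax(.data$mean_ibaq, 1)),
                               colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "abundance rank", y = expression(log[10] ~ "iBAQ"),
                  colour = "cluster") +
    ggplot2::theme_minimal()
}
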