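# ggplot2 views of the main result types: screen volcano, pathway dropout
# matrix, SNV spectrum with Pattern I/II, exposure stacks, cohort scatter.

#' Volcano plot of gene-level screen results
#'
#' SigmaFC against -log10 permutation p, one panel per genotype.
#'
#' @param gene_table Output of [screen_gene_table()] (or any tibble with
#'   `sigma_fc`, `perm_p`, `genotype`, `gene`).
#' @param label_top Label this many genes by smallest p (default 5).
#' @return A ggplot object.
#' @export
plot_volcano <- function(gene_table, label_top = 5) {
  top <- gene_table |> arrange(.data$perm_p) |>
    group_by(.data$genotype) |> dplyr::slice_head(n = label_top) |> ungroup()
  ggplot2::ggplot(gene_table,
                  ggplot2::aes(.data$sigma_fc, -log10(.data$perm_p))) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 3) +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::labs(x = "SigmaFC (sum of guide log2 fold changes)",
                  y = expression(-log[10]~"permutation p")) +
    ggplot2::theme_bw()
}

#' Pathway dropout matrix
#'
#' Tile matrix of -log10 paired-t p (fill) with the pooled log2 fold change
#' printed in each cell, pathways by arm.
#'
#' @param pathway_stats Output of [pathway_dropout_stats()].
#' @return A ggplot object.
#' @export
plot_pathway_matrix <- function(pathway_stats) {
  d <- mutate(pathway_stats,
              arm = paste(.data$genotype, .data$treatment, sep = "\n"),
              neglogp = -log10(pmax(.data$paired_t_p, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(.data$arm, .data$pathway,
                                  fill = .data$neglogp)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$pooled_log2fc)),
                       size = 2.8) +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10]~p)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Six-class SNV spectrum with Pattern I / Pattern II annotation
#'
#' @param catalog A catalog from [build_catalog()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(catalog) {
  cls <- parse_context96(catalog$context)$class
  d <- catalog |>
    tidyr::pivot_longer(-"context", names_to = "sample", values_to = "n") |>
    mutate(class = rep(cls, times = length(unique(.data$sample))),
           pattern = ifelse(.data$class == "C>T", "Pattern I", "Pattern II")) |>
    group_by(.data$sample, .data$class, .data$pattern) |>
    summarise(n = sum(.data$n), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$class, .data$n, fill = .data$pattern)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = NULL, y = "SNV count") +
    ggplot2::theme_bw()
}

#' @method autoplot exposure_fit
#' @export
autoplot.exposure_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$sample, .data$exposure,
                               fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mutations attributed") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Cohort scatter: Signature-11 counts by RAD18 tertile and MGMT status
#'
#' Reproduces the stratified layout of the patient analysis: counts on a
#' log scale, dashed line at the hypermutation threshold.
#'
#' @param cohort Cohort tibble with `tertile`, `mgmt`, `sig11_count`.
#' @param threshold Hypermutation threshold (default 500).
#' @return A ggplot object.
#' @export
plot_cohort <- function(cohort, threshold = 500) {
  ggplot2::ggplot(cohort, ggplot2::aes(.data$tertile, .data$sig11_count + 1,
                                       colour = .data$tertile)) +
    ggplot2::geom_jitter(width = 0.2, height = 0) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~mgmt, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "adjusted RAD18 expression tertile",
                  y = "Signature-11 mutation count + 1") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}
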