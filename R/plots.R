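# ggplot2 views of the main result types.

#' QQ plot of TWAS p-values
#'
#' @param twas a `twas_result` tibble (needs `p`).
#' @return A ggplot object.
#' @export
plot_qq <- function(twas) {
  obs <- sort(twas$p)
  n <- length(obs)
  df <- tibble(expected = -log10((seq_len(n) - 0.5) / n),
               observed = -log10(obs))
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of TWAS associations
#'
#' @param twas a `twas_result` tibble.
#' @param annotation tibble `gene, chrom, tss`.
#' @param fdr highlight threshold on `q` (default 0.05).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(twas, annotation, fdr = 0.05) {
  df <- left_join(as_tibble(twas), annotation, by = "gene") |>
    mutate(significant = .data$q < fdr)
  ggplot2::ggplot(df, ggplot2::aes(.data$tss, -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#D55E00"),
                                 guide = "none") +
    ggplot2::labs(x = "TSS position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Elbow plot for the SD-cutoff of a gene-set expansion
#'
#' @param expansion an `expansion_result` from [expand_gene_set()].
#' @return A ggplot object.
#' @export
plot_elbow <- function(expansion) {
  ggplot2::ggplot(expansion$elbow, ggplot2::aes(.data$s, .data$set_size)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = expansion$sd_cutoff, linetype = 2) +
    ggplot2::labs(x = "SD multiplier", y = "included genes") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.twas_result <- function(object, ...) plot_qq(object)

#' @exportS3Method ggplot2::autoplot
autoplot.expansion_result <- function(object, ...) plot_elbow(object)
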