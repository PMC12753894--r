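#' Volcano plot of a differential-expression table
#'
#' @param object A `rho_de` table.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.rho_de <- function(object, ...) {
  th <- attr(object, "thresholds") %||% c(lfc = 1, fdr = 0.01)
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$fdr, 1e-300)),
                               colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-th[["lfc"]], th[["lfc"]]),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(th[["fdr"]]),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(up = "#b2182b",
                                            down = "#2166ac",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (tumor / normal)",
                  y = "-log10 FDR", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Background distribution of a resampling enrichment test
#'
#' Histogram of the per-list background statistic with the observed
#' pathway value marked.
#'
#' @param result A one-row [enrichment_test()] or
#'   [de_count_enrichment()] result (the per-list values ride along as
#'   an attribute).
#' @return A ggplot.
#' @export
plot_enrichment <- function(result) {
  per_list <- attr(result, "per_list")
  if (is.null(per_list)) {
    stop("result carries no per-list background values", call. = FALSE)
  }
  ggplot2::ggplot(tibble(statistic = per_list),
                  ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "white") +
    ggplot2::geom_vline(xintercept = result$observed, colour = "#b2182b",
                        linewidth = 1) +
    ggplot2::labs(x = paste0("background ", result$statistic_kind,
                             " per random list"),
                  y = "lists",
                  subtitle = sprintf("observed = %.0f, z = %.2f, p = %.3g",
                                     result$observed, result$z, result$p)) +
    ggplot2::theme_minimal()
}

#' Pan-cancer deregulation profile plot
#'
#' Stacked bar of up/down cohort counts per gene, ordered by breadth.
#'
#' @param profiles Output of [pan_cancer_classify()].
#' @param top Number of genes to show (default 40 by breadth).
#' @return A ggplot.
#' @export
plot_pan_cancer <- function(profiles, top = 40L) {
  d <- profiles |>
    arrange(dplyr::desc(.data$breadth_fraction)) |>
    head(n = top) |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    mutate(n = if_else(.data$direction == "n_down", -.data$n, .data$n))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$gene, -.data$breadth_fraction),
    y = .data$n, fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(n_up = "#b2182b",
                                          n_down = "#2166ac"),
                               labels = c(n_up = "up", n_down = "down")) +
    ggplot2::labs(x = NULL, y = "cohorts differentially expressed",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Lineage vulnerability plot
#'
#' Median score difference against -log10 FDR for every gene-lineage
#' test, with the flag thresholds marked.
#'
#' @param vulnerability Output of [lineage_vulnerability()].
#' @param diff_cutoff,fdr_cutoff Thresholds to draw (defaults 0.5,
#'   0.01).
#' @return A ggplot.
#' @export
plot_vulnerability <- function(vulnerability, diff_cutoff = 0.5,
                               fdr_cutoff = 0.01) {
  ggplot2::ggplot(vulnerability,
                  ggplot2::aes(x = .data$median_diff,
                               y = -log10(pmax(.data$fdr, 1e-300)),
                               colour = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::geom_vline(xintercept = c(-diff_cutoff, diff_cutoff),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(fdr_cutoff),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "median dependency difference (lineage - rest)",
                  y = "-log10 FDR", colour = "flagged") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
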