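#' Classify positive-selection calls from dN/dS q-values
#'
#' Post-processes a positive-selection table (gene-level q-values for the
#' global, missense and truncating signals, as produced by dN/dS-style
#' tools) into discrete calls. A gene is under significant positive
#' selection when `qglobal_cv < 0.01`; the sub-signal q-values then
#' separate missense-selected from truncation-selected genes, with
#' `both` when the two sub-signals are significant. A globally
#' significant gene with neither sub-signal significant is surfaced with
#' a warning but classed `none`.
#'
#' @param table Tibble with `gene`, `cohort`, `qglobal_cv`, `qmis_cv`,
#'   `qtrunc_cv`, one row per (gene, cohort).
#' @param q_cutoff Significance cutoff (default 0.01, strict `<`).
#' @return Input with a `class` column in `missense_selected`,
#'   `truncation_selected`, `both`, `none`.
#' @export
classify_selection <- function(table, q_cutoff = 0.01) {
  qs <- c(table$qglobal_cv, table$qmis_cv, table$qtrunc_cv)
  if (any(!is.finite(qs)) || any(qs < 0 | qs > 1)) {
    stop("q-values must lie in [0, 1]", call. = FALSE)
  }
  out <- table |>
    mutate(class = case_when(
      .data$qglobal_cv >= q_cutoff ~ "none",
      .data$qmis_cv < q_cutoff & .data$qtrunc_cv < q_cutoff ~ "both",
      .data$qmis_cv < q_cutoff ~ "missense_selected",
      .data$qtrunc_cv < q_cutoff ~ "truncation_selected",
      TRUE ~ "none"
    ))
  orphan <- out$qglobal_cv < q_cutoff & out$class == "none"
  if (any(orphan)) {
    warning("gene(s) globally significant without a significant ",
            "missense or truncating sub-signal: ",
            paste(unique(out$gene[orphan]), collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Share of genes under positive selection
#'
#' Fraction (as a percentage, one decimal) of catalog genes with at
#' least one non-`none` selection call in any cohort.
#'
#' @param calls Output of [classify_selection()].
#' @param n_catalog_genes Size of the curated gene list (denominator).
#' @return One-row tibble with `n_selected`, `n_catalog_genes`,
#'   `pct_selected`.
#' @export
selection_share <- function(calls, n_catalog_genes) {
  sel <- unique(calls$gene[calls$class != "none"])
  tibble(n_selected = length(sel),
         n_catalog_genes = as.integer(n_catalog_genes),
         pct_selected = round(100 * length(sel) / n_catalog_genes, 1))
}

#' In-cluster mutation fractions and hotspot prevalence
#'
#' Given per-mutation protein positions and detected mutation clusters
#' (from a clustering tool such as positional hotspot callers), computes
#' per (gene, cohort): the fraction of missense and of truncating
#' mutations falling inside clusters, and the hotspot prevalence (the
#' fraction of cohort samples carrying at least one in-cluster
#' mutation). Flags use the strict tiers: a fraction flag at > 30% for
#' either class, a prevalence flag at > 3%.
#'
#' @param mutations Mutation tibble with `gene`, `cohort_id`,
#'   `sample_id`, `variant_class`, `position` (1-based protein
#'   coordinates; required for every record).
#' @param clusters Tibble with `gene`, `cohort_id`, `start`, `end`
#'   (inclusive cluster intervals).
#' @param cohort_size Number of samples in the cohort (must be > 0).
#' @param fraction_cutoff,prevalence_cutoff Strict flag thresholds
#'   (defaults 0.30 and 0.03).
#' @return Tibble per (gene, cohort) with the fractions, prevalence and
#'   flags.
#' @export
hotspot_fractions <- function(mutations, clusters, cohort_size,
                              fraction_cutoff = 0.30,
                              prevalence_cutoff = 0.03) {
  if (cohort_size <= 0) stop("cohort_size must be > 0", call. = FALSE)
  if (anyNA(mutations$position)) {
    stop("every mutation record needs a position", call. = FALSE)
  }
  in_cluster <- rep(FALSE, nrow(mutations))
  if (nrow(clusters) > 0) {
    for (i in seq_len(nrow(clusters))) {
      hit <- mutations$gene == clusters$gene[i] &
        mutations$cohort_id == clusters$cohort_id[i] &
        mutations$position >= clusters$start[i] &
        mutations$position <= clusters$end[i]
      in_cluster <- in_cluster | hit
    }
  }
  ann <- mutate(mutations, in_cluster = in_cluster)
  ann |>
    group_by(gene = .data$gene, cohort_id = .data$cohort_id) |>
    summarise(
      n_missense = sum(.data$variant_class == "missense"),
      n_missense_in = sum(.data$variant_class == "missense" &
                            .data$in_cluster),
      n_truncating = sum(.data$variant_class == "truncating"),
      n_truncating_in = sum(.data$variant_class == "truncating" &
                              .data$in_cluster),
      hotspot_prevalence =
        n_distinct(.data$sample_id[.data$in_cluster]) / cohort_size,
      .groups = "drop"
    ) |>
    mutate(
      missense_fraction_in_clusters =
        if_else(.data$n_missense == 0, 0,
                .data$n_missense_in / .data$n_missense),
      truncating_fraction_in_clusters =
        if_else(.data$n_truncating == 0, 0,
                .data$n_truncating_in / .data$n_truncating),
      fraction_flag = .data$missense_fraction_in_clusters > fraction_cutoff |
        .data$truncating_fraction_in_clusters > fraction_cutoff,
      prevalence_flag = .data$hotspot_prevalence > prevalence_cutoff
    )
}
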