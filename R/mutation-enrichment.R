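NONSYNONYMOUS_CLASSES <- c("missense", "truncating", "other")

#' Flag and remove hypermutated samples
#'
#' A sample is hypermutated when its total mutation count exceeds
#' `multiplier` times the mean count of its cohort, the mean being
#' computed once over all samples (the rule is not re-applied after
#' removal). Hypermutated samples are dropped from the retained table so
#' that a handful of extreme genomes cannot dominate cohort-level burden
#' statistics.
#'
#' @param mutations Tibble with `sample_id`, `cohort_id`, `gene`,
#'   `variant_class` (one record per mutation).
#' @param multiplier Burden multiple defining hypermutation (default 4.5).
#' @return List with `retained` (filtered mutation table) and `report`
#'   (one row per sample: `per_sample_count`, `cohort_mean`,
#'   `hypermutator_flag`).
#' @export
filter_hypermutators <- function(mutations, multiplier = 4.5) {
  if (nrow(mutations) == 0) stop("no samples", call. = FALSE)
  report <- mutations |>
    count(.data$cohort_id, .data$sample_id, name = "per_sample_count") |>
    group_by(.data$cohort_id) |>
    mutate(cohort_mean = mean(.data$per_sample_count)) |>
    ungroup() |>
    mutate(hypermutator_flag =
             .data$per_sample_count > multiplier * .data$cohort_mean)
  flagged <- report$sample_id[report$hypermutator_flag]
  retained <- filter(mutations, !.data$sample_id %in% flagged)
  list(retained = retained, report = report)
}

#' Per-gene mutational load and prevalence
#'
#' Load counts protein-altering (non-synonymous: missense, truncating,
#' other) records per gene; prevalence is the fraction of samples with at
#' least one such record in the gene. Synonymous mutations are excluded
#' by default since the enrichment question concerns protein-altering
#' burden. Hypermutator filtering is the caller's responsibility (see
#' [filter_hypermutators()]).
#'
#' @param mutations Mutation tibble (post-filter).
#' @param genes Character vector of gene symbols to tabulate; genes
#'   absent from the table get load 0 and prevalence 0.
#' @param n_samples Number of retained samples in the cohort; defaults to
#'   the number of distinct samples in the table.
#' @param include_synonymous Count synonymous records too (default FALSE).
#' @return Tibble with `gene`, `load`, `n_mutated_samples`, `prevalence`.
#' @export
gene_load <- function(mutations, genes, n_samples = NULL,
                      include_synonymous = FALSE) {
  if (is.null(n_samples)) n_samples <- n_distinct(mutations$sample_id)
  keep <- if (include_synonymous) unique(mutations$variant_class)
          else NONSYNONYMOUS_CLASSES
  hits <- mutations |>
    filter(.data$variant_class %in% keep, .data$gene %in% genes)
  per_gene <- hits |>
    group_by(gene = .data$gene) |>
    summarise(load = n(),
              n_mutated_samples = n_distinct(.data$sample_id),
              .groups = "drop")
  tibble(gene = genes) |>
    left_join(per_gene, by = "gene") |>
    mutate(load = if_else(is.na(.data$load), 0L, as.integer(.data$load)),
           n_mutated_samples = if_else(is.na(.data$n_mutated_samples), 0L,
                                       as.integer(.data$n_mutated_samples)),
           prevalence = if (n_samples > 0)
             .data$n_mutated_samples / n_samples else 0)
}

#' Draw length-matched random gene lists
#'
#' Builds the resampling null for pathway-level burden statistics: genes
#' are binned by deciles of log10 coding length computed on the pathway
#' list, and each of `n_lists` random lists reproduces the pathway list's
#' per-bin counts exactly, sampling background genes (pathway genes
#' excluded) without replacement within a list and independently across
#' lists. This controls for the fact that longer genes accumulate more
#' mutations.
#'
#' @param catalog A `rho_catalog` (supplies the pathway lengths).
#' @param background Tibble with `symbol` and `coding_length_bp`.
#' @param n_lists Number of random lists (default 1000).
#' @param seed Integer seed.
#' @param n_bins Number of length bins (default 10 = deciles).
#' @return Object of class `rho_ensemble`: list with `lists` (character
#'   matrix, one row per list), `bin_edges`, `bin_counts`, `seed`.
#' @export
sample_length_matched_lists <- function(catalog, background,
                                        n_lists = 1000L, seed = 1L,
                                        n_bins = 10L) {
  background <- filter(as_tibble(background),
                       !.data$symbol %in% catalog$symbol)
  path_log <- log10(catalog$coding_length_bp)
  probs <- seq(0, 1, length.out = n_bins + 1)
  edges <- quantile(path_log, probs = probs, type = 7, names = FALSE)
  edges[1] <- -Inf
  edges[length(edges)] <- Inf
  path_bin <- cut(path_log, breaks = edges, include.lowest = TRUE,
                  labels = FALSE)
  need <- tabulate(path_bin, nbins = n_bins)
  bg_bin <- cut(log10(background$coding_length_bp), breaks = edges,
                include.lowest = TRUE, labels = FALSE)
  avail <- tabulate(bg_bin, nbins = n_bins)
  short <- which(avail < need)
  if (length(short) > 0) {
    stop("insufficient background genes in length bin(s): ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  bin_members <- split(background$symbol, factor(bg_bin, levels = 1:n_bins))
  k <- nrow(catalog)
  lists <- withr::with_seed(as.integer(seed), {
    m <- matrix(NA_character_, nrow = n_lists, ncol = k)
    for (l in seq_len(n_lists)) {
      picked <- unlist(lapply(seq_len(n_bins), function(b) {
        if (need[b] == 0) character(0)
        else sample(bin_members[[b]], need[b], replace = FALSE)
      }), use.names = FALSE)
      m[l, ] <- picked
    }
    m
  })
  structure(list(lists = lists, bin_edges = edges, bin_counts = need,
                 seed = as.integer(seed), list_size = k),
            class = "rho_ensemble")
}

#' @export
print.rho_ensemble <- function(x, ...) {
  cat("<rho_ensemble> ", nrow(x$lists), " length-matched lists of ",
      x$list_size, " genes\n", sep = "")
  invisible(x)
}

# Aggregate a per-gene load table into the ensemble statistic:
# total non-synonymous load, or total mutated-sample count
# (prevalence scaled to expected counts).
aggregate_statistic <- function(load_tbl, statistic) {
  if (statistic == "load") sum(load_tbl$load)
  else sum(load_tbl$n_mutated_samples)
}

#' Pathway burden enrichment against a resampled background
#'
#' Compares the pathway list's aggregate burden statistic (total
#' non-synonymous load, or total mutated-sample count for the prevalence
#' statistic) with its distribution over the length-matched random lists.
#' The observed value is expressed as a Z-score against the background
#' mean and sd (effect size), and the p-value is the upper-tail Poisson
#' probability P(X >= observed) at lambda = background mean. A
#' Shapiro-Wilk statistic on the background distribution is reported as a
#' normality diagnostic but never gates the test. FDR adjustment across
#' cohorts is applied afterwards with [adjust_enrichment()].
#'
#' @param load Per-gene load table for the pathway list (from
#'   [gene_load()] on catalog genes).
#' @param ensemble A `rho_ensemble` from [sample_length_matched_lists()].
#' @param background_load Per-gene load table covering every background
#'   gene used by the ensemble.
#' @param statistic `"load"` or `"prevalence"`.
#' @param cohort Cohort label carried into the result.
#' @return One-row tibble: `cohort`, `statistic_kind`, `observed`,
#'   `background_mean`, `background_sd`, `z`, `p`, `shapiro_w`, `tier`;
#'   the per-list background values are attached as attribute
#'   `"per_list"`.
#' @export
enrichment_test <- function(load, ensemble, background_load,
                            statistic = c("load", "prevalence"),
                            cohort = "C01") {
  statistic <- match.arg(statistic)
  col <- if (statistic == "load") "load" else "n_mutated_samples"
  stat_vec <- setNames(background_load[[col]], background_load$gene)
  miss <- setdiff(unique(as.vector(ensemble$lists)), names(stat_vec))
  if (length(miss) > 0) {
    stop("background_load is missing ensemble gene(s), e.g. ", miss[1],
         call. = FALSE)
  }
  per_list <- rowSums(matrix(stat_vec[as.vector(ensemble$lists)],
                             nrow = nrow(ensemble$lists)))
  observed <- if (statistic == "load") sum(load$load)
              else sum(load$n_mutated_samples)
  bg_mean <- mean(per_list)
  bg_sd <- sd(per_list)
  z <- if (bg_sd == 0) {
    if (observed == bg_mean) 0 else sign(observed - bg_mean) * Inf
  } else (observed - bg_mean) / bg_sd
  p <- ppois(observed - 1, lambda = bg_mean, lower.tail = FALSE)
  sh <- tryCatch(shapiro.test(per_list[seq_len(min(length(per_list),
                                                   5000L))])$statistic,
                 error = function(e) NA_real_)
  out <- tibble(
    cohort = cohort, statistic_kind = statistic, observed = observed,
    background_mean = bg_mean, background_sd = bg_sd, z = z, p = p,
    shapiro_w = unname(sh), tier = p_tier(p)
  )
  attr(out, "per_list") <- per_list
  out
}

p_tier <- function(p) {
  case_when(p < 0.001 ~ "p<0.001",
            p < 0.01 ~ "p<0.01",
            p < 0.05 ~ "p<0.05",
            TRUE ~ "ns")
}

#' Benjamini-Hochberg adjustment across enrichment results
#'
#' @param results Tibble of [enrichment_test()] rows (e.g. one per cohort
#'   and statistic).
#' @param fdr_cutoff Significance cutoff on the adjusted p (default 0.05).
#' @return Input with `fdr` and `significant` columns added.
#' @export
adjust_enrichment <- function(results, fdr_cutoff = 0.05) {
  results |>
    mutate(fdr = p.adjust(.data$p, method = "BH"),
           significant = .data$fdr < fdr_cutoff)
}

#' Read a MAF-like mutation TSV
#'
#' Accepts either the package's canonical columns (`sample_id`,
#' `cohort_id`, `gene`, `variant_class`, optional `position`) or
#' MAF-style headers (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`), mapping the usual MAF classification
#' vocabulary onto the four-class scheme: missense and in-frame events to
#' `missense`, nonsense/frameshift/splice/nonstop to `truncating`, silent
#' to `synonymous`, everything else to `other`.
#'
#' @param path TSV path.
#' @param cohort Cohort id to assign when the file carries none.
#' @return Mutation tibble in canonical columns.
#' @export
read_mutations <- function(path, cohort = "C01") {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if ("Tumor_Sample_Barcode" %in% names(raw)) {
    map <- c(
      Missense_Mutation = "missense", In_Frame_Del = "missense",
      In_Frame_Ins = "missense",
      Nonsense_Mutation = "truncating", Frame_Shift_Del = "truncating",
      Frame_Shift_Ins = "truncating", Splice_Site = "truncating",
      Nonstop_Mutation = "truncating",
      Silent = "synonymous"
    )
    cls <- unname(map[as.character(raw$Variant_Classification)])
    cls[is.na(cls)] <- "other"
    raw <- tibble(
      sample_id = as.character(raw$Tumor_Sample_Barcode),
      cohort_id = if ("cohort_id" %in% names(raw))
        as.character(raw$cohort_id) else cohort,
      gene = as.character(raw$Hugo_Symbol),
      variant_class = cls,
      position = if ("position" %in% names(raw))
        as.integer(raw$position) else NA_integer_
    )
  } else {
    if (!"cohort_id" %in% names(raw)) raw$cohort_id <- cohort
    if (!"position" %in% names(raw)) raw$position <- NA_integer_
    raw <- raw[, c("sample_id", "cohort_id", "gene", "variant_class",
                   "position")]
  }
  bad <- setdiff(unique(raw$variant_class),
                 c("synonymous", "missense", "truncating", "other"))
  if (length(bad) > 0) {
    stop("unknown variant_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  as_tibble(raw)
}
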