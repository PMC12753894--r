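#' Pairwise Spearman co-expression
#'
#' Spearman rank correlation (average ranks for ties) for every
#' unordered pair between two gene lists, with a p-value from the exact
#' permutation null for small cohorts (n <= 9 samples; all n!
#' permutations, tie-robust) and the t approximation otherwise, followed
#' by BH adjustment within the call (one cohort). A zero-variance gene
#' yields an undefined correlation, emitted as a flagged row rather than
#' an error.
#'
#' @param expr A `rho_expr` (normalized values recommended) with >= 5
#'   samples, or a gene-by-sample numeric matrix.
#' @param list_a,list_b Character vectors of gene symbols; pairs are the
#'   unordered combinations of one gene from each list (self-pairs
#'   dropped).
#' @param fdr_cutoff Significance cutoff on the adjusted p (default
#'   0.05).
#' @param cohort Cohort label.
#' @return Tibble with `gene_a`, `gene_b`, `cohort`, `rho`, `p`, `fdr`,
#'   `significant`, `undefined`.
#' @export
pairwise_spearman <- function(expr, list_a, list_b, fdr_cutoff = 0.05,
                              cohort = "C01") {
  x <- if (inherits(expr, "rho_expr")) expr$counts else as.matrix(expr)
  n <- ncol(x)
  if (n < 5) stop("need at least 5 samples", call. = FALSE)
  pairs <- tidyr::expand_grid(gene_a = list_a, gene_b = list_b) |>
    filter(.data$gene_a != .data$gene_b) |>
    mutate(key = paste(pmin(.data$gene_a, .data$gene_b),
                       pmax(.data$gene_a, .data$gene_b))) |>
    distinct(.data$key, .keep_all = TRUE) |>
    select(-"key")
  rows <- purrr::pmap(pairs, function(gene_a, gene_b) {
    a <- x[gene_a, ]; b <- x[gene_b, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(tibble(gene_a = gene_a, gene_b = gene_b, cohort = cohort,
                    rho = NA_real_, p = NA_real_, undefined = TRUE))
    }
    res <- spearman_test(a, b)
    tibble(gene_a = gene_a, gene_b = gene_b, cohort = cohort,
           rho = res$rho, p = res$p, undefined = FALSE)
  })
  bind_rows(rows) |>
    mutate(fdr = p.adjust(.data$p, method = "BH"),
           significant = !is.na(.data$fdr) & .data$fdr < fdr_cutoff)
}

# Spearman rho with average ranks; exact two-sided permutation p for
# n <= 9, t approximation above.
spearman_test <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  rho <- cor(ra, rb)
  n <- length(a)
  if (n <= 9) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, function(idx) cor(ra, rb[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p <- min(p, 1)
  }
  list(rho = rho, p = p)
}

# All permutations of 1..n as an n! x n integer matrix.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Cross-cohort co-regulation summary
#'
#' Summarises per-cohort co-expression results into the percentage of
#' tested cohorts in which a pair is significantly co-regulated, the
#' dominant correlation sign among significant cohorts (mixed on a
#' tie), and the strict percentage tiers (> 50%, > 25%).
#'
#' @param results Row-bound [pairwise_spearman()] tables over cohorts.
#' @return Tibble per pair: `gene_a`, `gene_b`, `n_tested`,
#'   `n_significant`, `pct_significant`, `dominant_sign`, `tier`.
#' @export
cross_cohort_summary <- function(results) {
  if (nrow(results) == 0) stop("no tested cohorts", call. = FALSE)
  results |>
    group_by(gene_a = .data$gene_a, gene_b = .data$gene_b) |>
    summarise(
      n_tested = n(),
      n_significant = sum(.data$significant, na.rm = TRUE),
      n_pos = sum(.data$significant & .data$rho > 0, na.rm = TRUE),
      n_neg = sum(.data$significant & .data$rho < 0, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(
      pct_significant = 100 * .data$n_significant / .data$n_tested,
      dominant_sign = case_when(.data$n_pos > .data$n_neg ~ "positive",
                                .data$n_neg > .data$n_pos ~ "negative",
                                TRUE ~ "mixed"),
      tier = case_when(.data$pct_significant > 50 ~ "gt50pct",
                       .data$pct_significant > 25 ~ "gt25pct",
                       TRUE ~ "below")
    ) |>
    select(-"n_pos", -"n_neg")
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

# Weighted Kolmogorov-Smirnov enrichment score (weight exponent 1 by
# default): hit increments proportional to |score|^exponent, miss
# increments uniform; ES is the running-sum value of largest magnitude.
gsea_es <- function(scores, hit_idx, exponent = 1) {
  N <- length(scores)
  K <- length(hit_idx)
  hit_idx <- sort(hit_idx)
  w <- abs(scores[hit_idx])^exponent
  if (sum(w) == 0) w <- rep(1, K)
  cumw <- cumsum(w) / sum(w)
  miss <- 1 / (N - K)
  misses_before <- hit_idx - seq_len(K)
  at_hit <- cumw - misses_before * miss
  before_hit <- c(0, cumw[-K]) - misses_before * miss
  cand <- c(at_hit, before_hit)
  cand[which.max(abs(cand))]
}

#' Pre-ranked gene set enrichment with permutation NES
#'
#' Computes, for each gene set, the weighted Kolmogorov-Smirnov
#' enrichment score (weight exponent 1) on a ranked gene list, a
#' gene-label permutation null (`n_perm` random placements of the set),
#' the normalized enrichment score NES = ES / mean(|ES*|) over same-sign
#' permutations, a one-tailed permutation p with the +1 correction, and
#' BH FDR across sets. Sets are intersected with the ranked universe;
#' sets smaller than `min_size` or larger than `max_size` after
#' intersection are dropped with a warning.
#'
#' @param ranked Tibble with `gene` and `score` (any order; sorted by
#'   decreasing score internally), or a named numeric vector.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations (default 10000).
#' @param max_size Maximum set size after intersection (default 800).
#' @param min_size Minimum set size after intersection (default 5).
#' @param seed Integer seed for the permutations.
#' @param exponent Weight exponent (default 1).
#' @return Tibble with `set_name`, `size`, `es`, `nes`, `p`, `fdr`.
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 10000L, max_size = 800L,
                           min_size = 5L, seed = 1L, exponent = 1) {
  if (is.numeric(ranked)) {
    ranked <- tibble(gene = names(ranked), score = unname(ranked))
  }
  if (any(!is.finite(ranked$score))) {
    stop("ranking scores must be finite", call. = FALSE)
  }
  ranked <- arrange(ranked, dplyr::desc(.data$score))
  scores <- ranked$score
  universe <- ranked$gene
  N <- length(universe)
  keep <- purrr::map(sets, ~ which(universe %in% .x))
  sizes <- lengths(keep)
  dropped <- names(sets)[sizes < min_size | sizes > max_size]
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped),
            " set(s) outside the size bounds after intersection: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
  }
  keep <- keep[sizes >= min_size & sizes <= max_size]
  if (length(keep) == 0) {
    return(tibble(set_name = character(0), size = integer(0),
                  es = numeric(0), nes = numeric(0), p = numeric(0),
                  fdr = numeric(0)))
  }
  rows <- withr::with_seed(as.integer(seed), {
    purrr::imap(keep, function(hit_idx, set_name) {
      K <- length(hit_idx)
      es <- gsea_es(scores, hit_idx, exponent)
      es_null <- vapply(seq_len(n_perm), function(i) {
        gsea_es(scores, sample.int(N, K), exponent)
      }, numeric(1))
      same_sign <- if (es >= 0) es_null[es_null >= 0] else
        es_null[es_null < 0]
      nes <- if (length(same_sign) == 0 || mean(abs(same_sign)) == 0)
        NA_real_ else es / mean(abs(same_sign))
      p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
      tibble(set_name = set_name, size = K, es = es, nes = nes, p = p)
    })
  })
  bind_rows(rows) |>
    mutate(fdr = p.adjust(.data$p, method = "BH"))
}

#' Top processes across cohorts by median NES
#'
#' Ranks gene sets by the median NES over the cohorts in which they were
#' tested (descending), breaking ties by set name for determinism, and
#' returns the top `k`.
#'
#' @param results Row-bound [preranked_gsea()] tables with a `cohort`
#'   column (a single-cohort table without one is accepted).
#' @param k Number of sets to return (default 100; all if fewer).
#' @return Tibble with `set_name`, `n_cohorts`, `median_nes`.
#' @export
top_processes <- function(results, k = 100L) {
  if (!"cohort" %in% names(results)) results$cohort <- "C01"
  results |>
    group_by(set_name = .data$set_name) |>
    summarise(n_cohorts = n(),
              median_nes = stats::median(.data$nes, na.rm = TRUE),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$median_nes), .data$set_name) |>
    head(n = k)
}
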