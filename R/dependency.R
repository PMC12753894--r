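#' Pan-cancer essentiality calls from dependency scores
#'
#' A gene is pan-cancer essential when its dependency score is below
#' `threshold` (default -0.5; more negative means stronger fitness cost
#' of knockout) in strictly more than `fraction` (default 10%) of the
#' screened cell lines. Both inequalities are strict.
#'
#' @param dep Long dependency tibble with `gene`, `cell_line`, `score`
#'   (e.g. from [dependency_long()] or [read_dependency_csv()]), or a
#'   gene-by-line score matrix.
#' @param threshold Dependency cutoff (default -0.5).
#' @param fraction Fraction-of-lines cutoff (default 0.10).
#' @return Tibble with `gene`, `n_lines`, `pct_lines_dependent`,
#'   `pan_essential`.
#' @export
pan_cancer_essential <- function(dep, threshold = -0.5, fraction = 0.10) {
  dep <- dependency_as_long(dep)
  if (nrow(dep) == 0) stop("empty dependency matrix", call. = FALSE)
  dep |>
    group_by(gene = .data$gene) |>
    summarise(n_lines = n(),
              pct_lines_dependent = 100 * mean(.data$score < threshold),
              .groups = "drop") |>
    mutate(pan_essential = .data$pct_lines_dependent > 100 * fraction)
}

#' Lineage-specific vulnerability statistics
#'
#' For every gene and lineage (with at least `min_group` cell lines),
#' compares the dependency scores of the lineage against all remaining
#' lines: the median difference (in minus out), a two-sample p-value
#' (Welch's unequal-variance test by default; Student's pooled test by
#' option), and a BH FDR over all gene-by-lineage tests. A gene is
#' flagged when |median difference| > `diff_cutoff` and FDR <
#' `fdr_cutoff`; direction is `sensitizing` when the lineage median is
#' lower (knockout costs more fitness in that lineage) and `protective`
#' otherwise.
#'
#' @param dep Long dependency tibble with `gene`, `cell_line`,
#'   `lineage`, `score`, or a score matrix plus `lines` sheet via
#'   [dependency_long()].
#' @param min_group Minimum lineage size (default 3; smaller lineages
#'   are skipped with a warning).
#' @param test `"welch"` (default) or `"student"`.
#' @param diff_cutoff,fdr_cutoff Flag thresholds (defaults 0.5, 0.01).
#' @return Tibble with `gene`, `lineage`, `n_in`, `median_in`,
#'   `median_out`, `median_diff`, `p`, `fdr`, `flagged`, `direction`.
#' @export
lineage_vulnerability <- function(dep, min_group = 3L,
                                  test = c("welch", "student"),
                                  diff_cutoff = 0.5, fdr_cutoff = 0.01) {
  test <- match.arg(test)
  dep <- dependency_as_long(dep)
  if (anyNA(dep$lineage)) stop("missing lineage labels", call. = FALSE)
  sizes <- dep |> distinct(.data$cell_line, .data$lineage) |>
    count(.data$lineage)
  small <- sizes$lineage[sizes$n < min_group]
  if (length(small) > 0) {
    warning("skipping lineage(s) below the minimum size: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  lineages <- setdiff(sizes$lineage, small)
  combos <- tidyr::expand_grid(gene = unique(dep$gene), lineage = lineages)
  by_gene <- split(dep, dep$gene)
  rows <- purrr::pmap(combos, function(gene, lineage) {
    d <- by_gene[[gene]]
    inside <- d$score[d$lineage == lineage]
    outside <- d$score[d$lineage != lineage]
    med_in <- median(inside); med_out <- median(outside)
    p <- welch_or_student_p(inside, outside, pooled = test == "student")
    tibble(gene = gene, lineage = lineage, n_in = length(inside),
           median_in = med_in, median_out = med_out,
           median_diff = med_in - med_out, p = p)
  })
  bind_rows(rows) |>
    mutate(fdr = p.adjust(.data$p, method = "BH"),
           flagged = abs(.data$median_diff) > diff_cutoff &
             .data$fdr < fdr_cutoff,
           direction = if_else(.data$median_diff < 0, "sensitizing",
                               "protective"))
}

welch_or_student_p <- function(a, b, pooled = FALSE) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (median(a) == median(b)) 1 else 0)
  }
  tryCatch(t.test(a, b, var.equal = pooled)$p.value,
           error = function(e) 1)
}

dependency_as_long <- function(dep) {
  if (is.matrix(dep)) {
    return(tibble(gene = rep(rownames(dep), times = ncol(dep)),
                  cell_line = rep(colnames(dep), each = nrow(dep)),
                  score = as.vector(dep)))
  }
  if (is.list(dep) && !is.data.frame(dep) && !is.null(dep$scores)) {
    return(dependency_long(dep))
  }
  as_tibble(dep)
}

#' Read a DepMap-style dependency CSV with a lineage sheet
#'
#' The score file has cell lines in rows (first column the cell-line
#' id) and genes in columns; the lineage sheet maps `cell_line` to
#' `lineage`.
#'
#' @param scores_path CSV of dependency scores.
#' @param lineage_path CSV with columns `cell_line`, `lineage`.
#' @return Long tibble with `gene`, `cell_line`, `lineage`, `score`.
#' @export
read_dependency_csv <- function(scores_path, lineage_path) {
  scores <- readr::read_csv(scores_path, show_col_types = FALSE,
                            progress = FALSE)
  lineages <- readr::read_csv(lineage_path, show_col_types = FALSE,
                              progress = FALSE)
  id_col <- names(scores)[1]
  long <- scores |>
    tidyr::pivot_longer(-dplyr::all_of(id_col), names_to = "gene",
                        values_to = "score") |>
    rename(cell_line = dplyr::all_of(id_col)) |>
    left_join(lineages, by = "cell_line")
  if (anyNA(long$lineage)) {
    stop("lineage sheet is missing cell line(s): ",
         paste(head(unique(long$cell_line[is.na(long$lineage)]), 5),
               collapse = ", "), call. = FALSE)
  }
  long[, c("gene", "cell_line", "lineage", "score")]
}
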