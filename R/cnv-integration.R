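CNV_CLASS_MAP <- c(`-2` = "deep_del", `-1` = "shallow_del", `0` = "diploid",
                   `1` = "shallow_amp", `2` = "deep_amp")

validate_cnv <- function(cnv) {
  bad <- which(matrix(!(cnv %in% c(-2L, -1L, 0L, 1L, 2L)), nrow(cnv)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("copy-number call out of vocabulary at gene ",
         rownames(cnv)[bad[1, 1]] %||% bad[1, 1], ", sample ",
         colnames(cnv)[bad[1, 2]] %||% bad[1, 2],
         " (value ", cnv[bad[1, , drop = FALSE]], ")", call. = FALSE)
  }
  invisible(cnv)
}

#' Genotype classing from thresholded copy-number calls
#'
#' Direct mapping of GISTIC-style thresholded calls to genotype labels:
#' -2 deep deletion, -1 shallow deletion, 0 diploid, 1 shallow
#' amplification, 2 deep amplification.
#'
#' @param cnv Integer call matrix (genes by samples, values in -2..2).
#' @param gene Gene symbol (a row of `cnv`).
#' @return Tibble with `sample_id`, `call`, `genotype`.
#' @export
genotype_classify <- function(cnv, gene) {
  validate_cnv(cnv)
  if (!gene %in% rownames(cnv)) stop("unknown gene: ", gene, call. = FALSE)
  calls <- cnv[gene, ]
  tibble(sample_id = colnames(cnv), call = as.integer(calls),
         genotype = unname(CNV_CLASS_MAP[as.character(calls)]))
}

#' Per-gene alteration prevalence by class
#'
#' Fraction of samples carrying each alteration class per gene, with the
#' strict high-prevalence flag at > `prevalence_cutoff` (default 10%).
#' Prevalence is computed per class (deep and shallow separately),
#' matching the stratified downstream contrasts.
#'
#' @param cnv Call matrix.
#' @param prevalence_cutoff High-prevalence cutoff (default 0.10).
#' @return Tibble with `gene`, `alteration_class`, `n_samples`,
#'   `prevalence`, `high_prevalence`.
#' @export
scnv_prevalence <- function(cnv, prevalence_cutoff = 0.10) {
  validate_cnv(cnv)
  n <- ncol(cnv)
  classes <- setdiff(unname(CNV_CLASS_MAP), "diploid")
  purrr::map(classes, function(cl) {
    call_val <- as.integer(names(CNV_CLASS_MAP)[CNV_CLASS_MAP == cl])
    tibble(gene = rownames(cnv), alteration_class = cl,
           n_samples = unname(rowSums(cnv == call_val)))
  }) |>
    bind_rows() |>
    mutate(prevalence = .data$n_samples / n,
           high_prevalence = .data$prevalence > prevalence_cutoff)
}

#' Expression contrast of copy-number-altered versus diploid samples
#'
#' Compares expression between samples carrying a given alteration class
#' of `gene` and diploid samples, using the negative-binomial Wald test
#' over the whole matrix restricted to those samples (so dispersion
#' trends are estimated genome-wide) and extracting the row for `gene`.
#' Fewer than `min_group` samples on either side yields a not-testable
#' flag rather than an error.
#'
#' @param cnv Call matrix (genes by tumor samples).
#' @param expr A `rho_expr` containing (at least) the tumor samples of
#'   `cnv`.
#' @param gene Gene to contrast.
#' @param alteration_class One of `deep_amp`, `deep_del`, `shallow_amp`,
#'   `shallow_del`.
#' @param min_group Minimum samples per side (default 2).
#' @return One-row tibble: `gene`, `alteration_class`, `n_altered`,
#'   `n_diploid`, `log2fc_scn_vs_diploid`, `p_scn`, `testable`.
#' @export
scn_vs_diploid_contrast <- function(cnv, expr, gene,
                                    alteration_class = c("deep_amp",
                                                         "deep_del",
                                                         "shallow_amp",
                                                         "shallow_del"),
                                    min_group = 2L) {
  alteration_class <- match.arg(alteration_class)
  validate_cnv(cnv)
  call_val <- as.integer(names(CNV_CLASS_MAP)[CNV_CLASS_MAP ==
                                                alteration_class])
  calls <- cnv[gene, ]
  altered <- colnames(cnv)[calls == call_val]
  diploid <- colnames(cnv)[calls == 0L]
  altered <- intersect(altered, expr$samples$sample_id)
  diploid <- intersect(diploid, expr$samples$sample_id)
  if (length(altered) < min_group || length(diploid) < min_group) {
    return(tibble(gene = gene, alteration_class = alteration_class,
                  n_altered = length(altered), n_diploid = length(diploid),
                  log2fc_scn_vs_diploid = NA_real_, p_scn = NA_real_,
                  testable = FALSE))
  }
  sub <- subset_expression(expr, samples = c(altered, diploid))
  grp <- if_else(sub$samples$sample_id %in% altered, "altered", "diploid")
  de <- nb_differential_expression(sub$counts, groups = grp)
  row <- de[de$gene == gene, ]
  tibble(gene = gene, alteration_class = alteration_class,
         n_altered = length(altered), n_diploid = length(diploid),
         log2fc_scn_vs_diploid = row$log2fc, p_scn = row$pvalue,
         testable = TRUE)
}

#' Copy-number co-occurrence with driver genes
#'
#' Encodes alteration status at the requested depth and direction into
#' binary vectors and tests, for every (pathway gene, driver gene) pair,
#' the enrichment of co-alteration across samples with a one-sided
#' Fisher exact test (alternative "greater"; two-sided available).
#' p-values are BH-adjusted across pairs within the call. Degenerate
#' margins (a gene altered in no sample or in all samples) yield p = 1
#' with a flag.
#'
#' @param cnv Call matrix containing pathway and driver genes.
#' @param pathway_genes,driver_genes Character vectors of row names.
#' @param depth `"deep"` (|call| = 2) or `"shallow"` (|call| = 1).
#' @param direction `"amp"` or `"del"` (same-direction pairs only).
#' @param alternative Fisher alternative (default `"greater"`).
#' @param cohort Cohort label.
#' @return Tibble per pair with the 2x2 table cells, `p`, `adjusted_p`,
#'   `linked` (adjusted p < 0.05), `degenerate`.
#' @export
cooccurrence_with_drivers <- function(cnv, pathway_genes, driver_genes,
                                      depth = c("deep", "shallow"),
                                      direction = c("amp", "del"),
                                      alternative = "greater",
                                      cohort = "C01") {
  depth <- match.arg(depth)
  direction <- match.arg(direction)
  validate_cnv(cnv)
  mag <- if (depth == "deep") 2L else 1L
  sgn <- if (direction == "amp") 1L else -1L
  target_call <- mag * sgn
  alt <- cnv == target_call
  pairs <- tidyr::expand_grid(pathway_gene = pathway_genes,
                              driver_gene = driver_genes)
  rows <- purrr::pmap(pairs, function(pathway_gene, driver_gene) {
    a <- alt[pathway_gene, ]
    b <- alt[driver_gene, ]
    n11 <- sum(a & b); n10 <- sum(a & !b)
    n01 <- sum(!a & b); n00 <- sum(!a & !b)
    degenerate <- sum(a) == 0 || sum(b) == 0 ||
      sum(a) == length(a) || sum(b) == length(b)
    p <- if (degenerate) 1 else
      fisher.test(matrix(c(n11, n10, n01, n00), nrow = 2),
                  alternative = alternative)$p.value
    tibble(pathway_gene = pathway_gene, driver_gene = driver_gene,
           cohort = cohort, depth = depth, direction = direction,
           n_both = n11, n_pathway_only = n10, n_driver_only = n01,
           n_neither = n00, p = p, degenerate = degenerate)
  })
  bind_rows(rows) |>
    mutate(adjusted_p = p.adjust(.data$p, method = "BH"),
           linked = .data$adjusted_p < 0.05)
}

#' Concordance between copy-number and tumor-vs-normal expression shifts
#'
#' Classifies each gene-level association by whether the copy-number
#' contrast and the tumor-vs-normal contrast reinforce each other:
#' `reinforcing_up` for amplifications with both contrasts significant
#' and positive, `reinforcing_down` for deletions with both significant
#' and negative, `opposing` when both are significant with discordant
#' signs, `inert` otherwise. Significance means |log2FC| > `lfc_cutoff`
#' and FDR < `fdr_cutoff` on each axis.
#'
#' @param associations Tibble with `alteration_class`,
#'   `log2fc_scn_vs_diploid`, `fdr_scn`, `log2fc_tumor_vs_normal`,
#'   `fdr_tn`.
#' @param lfc_cutoff,fdr_cutoff Significance thresholds (1 and 0.01).
#' @return Input with a `concordance` column.
#' @export
concordance_classify <- function(associations, lfc_cutoff = 1,
                                 fdr_cutoff = 0.01) {
  associations |>
    mutate(
      sig_scn = !is.na(.data$log2fc_scn_vs_diploid) &
        abs(.data$log2fc_scn_vs_diploid) > lfc_cutoff &
        .data$fdr_scn < fdr_cutoff,
      sig_tn = !is.na(.data$log2fc_tumor_vs_normal) &
        abs(.data$log2fc_tumor_vs_normal) > lfc_cutoff &
        .data$fdr_tn < fdr_cutoff,
      amp = .data$alteration_class %in% c("deep_amp", "shallow_amp"),
      concordance = case_when(
        .data$sig_scn & .data$sig_tn & .data$amp &
          .data$log2fc_scn_vs_diploid > 0 &
          .data$log2fc_tumor_vs_normal > 0 ~ "reinforcing_up",
        .data$sig_scn & .data$sig_tn & !.data$amp &
          .data$log2fc_scn_vs_diploid < 0 &
          .data$log2fc_tumor_vs_normal < 0 ~ "reinforcing_down",
        .data$sig_scn & .data$sig_tn &
          sign(.data$log2fc_scn_vs_diploid) !=
            sign(.data$log2fc_tumor_vs_normal) ~ "opposing",
        TRUE ~ "inert"
      )
    ) |>
    select(-"sig_scn", -"sig_tn", -"amp")
}

#' Integrated copy-number/expression association table
#'
#' For each pathway gene and alteration class with at least `min_group`
#' altered samples: prevalence, the SCN-vs-diploid expression contrast
#' (BH-adjusted across the tested gene-class pairs), the tumor-vs-normal
#' contrast restricted to samples diploid for that gene (mirroring
#' "diploid cancer samples versus healthy controls"), and the
#' concordance class.
#'
#' @param cnv Call matrix over tumor samples.
#' @param expr A `rho_expr` with tumor and normal samples (normalized).
#' @param genes Pathway genes to integrate (default: all rows of `cnv`
#'   present in `expr`).
#' @param prevalence_cutoff High-prevalence flag cutoff (default 0.10).
#' @param min_group Minimum altered samples for testability (default 2).
#' @return Tibble with one row per (gene, alteration class), classed by
#'   [concordance_classify()].
#' @export
scnv_associations <- function(cnv, expr, genes = NULL,
                              prevalence_cutoff = 0.10, min_group = 2L) {
  validate_cnv(cnv)
  if (is.null(genes)) genes <- intersect(rownames(cnv), expr$genes$symbol)
  prev <- scnv_prevalence(cnv[genes, , drop = FALSE],
                          prevalence_cutoff = prevalence_cutoff)
  normals <- expr$samples$sample_id[expr$samples$condition == "normal"]
  scn_rows <- purrr::pmap(prev[, c("gene", "alteration_class")],
                          function(gene, alteration_class) {
    scn_vs_diploid_contrast(cnv, expr, gene, alteration_class,
                            min_group = min_group)
  }) |> bind_rows()
  tn_rows <- purrr::map(genes, function(g) {
    diploid_tumors <- colnames(cnv)[cnv[g, ] == 0L]
    keep <- c(intersect(diploid_tumors, expr$samples$sample_id), normals)
    sub <- subset_expression(expr, samples = keep)
    if (sum(sub$samples$condition == "tumor") < min_group ||
        sum(sub$samples$condition == "normal") < min_group) {
      return(tibble(gene = g, log2fc_tumor_vs_normal = NA_real_,
                    p_tn = NA_real_))
    }
    de <- nb_differential_expression(sub)
    row <- de[de$gene == g, ]
    tibble(gene = g, log2fc_tumor_vs_normal = row$log2fc,
           p_tn = row$pvalue)
  }) |> bind_rows()
  out <- prev |>
    left_join(scn_rows, by = c("gene", "alteration_class")) |>
    left_join(tn_rows, by = "gene") |>
    mutate(fdr_scn = p.adjust(.data$p_scn, method = "BH"),
           fdr_tn = p.adjust(.data$p_tn, method = "BH"))
  concordance_classify(out)
}
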