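# Small in-code fixtures shared across test files.

tiny_catalog <- function() {
  as_catalog(tibble::tibble(
    symbol = c("RHOA", "RAC1", "ARHGEF1", "ARHGAP1", "BCR", "PAK1"),
    categories = list("GTPASE", "GTPASE", "GEF", "GAP", c("GEF", "GAP"),
                      "KINASE_EFFECTOR"),
    coding_length_bp = c(600L, 580L, 2700L, 1500L, 3800L, 1650L),
    gc_fraction = c(0.55, 0.52, 0.48, 0.50, 0.47, 0.45),
    substrate = c("UNKNOWN", "UNKNOWN", "RHOA", "RAC1", "RHOA", "UNKNOWN")
  ))
}

catalog_tsv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "catalog.tsv")
  write_catalog(tiny_catalog(), path)
  path
}

# Expression container with fully controlled counts.
make_expr <- function(counts, condition = NULL, gc = NULL) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  g <- nrow(counts)
  if (is.null(condition)) condition <- rep(c("tumor", "normal"), length.out = n)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", seq_len(g))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%03d", seq_len(n))
  if (is.null(gc)) gc <- seq(0.35, 0.65, length.out = g)
  expression_matrix(
    counts,
    tibble::tibble(sample_id = colnames(counts), condition = condition,
                   cohort = "C01"),
    tibble::tibble(symbol = rownames(counts), gc_fraction = gc)
  )
}

# One mutation record per row from compact per-sample burdens.
burden_table <- function(burdens, cohort = "C01") {
  rows <- lapply(seq_along(burdens), function(i) {
    n <- burdens[i]
    if (n == 0) return(NULL)
    tibble::tibble(sample_id = sprintf("S%03d", i), cohort_id = cohort,
                   gene = sprintf("G%04d", seq_len(n)),
                   variant_class = "missense", position = 1L)
  })
  dplyr::bind_rows(rows)
}
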