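#' Expression matrix container
#'
#' Bundles a gene-by-sample count matrix with its sample sheet (condition
#' and cohort per sample) and per-gene annotation (GC fraction). Counts
#' stay in matrix form — the natural shape for genome-scale count data —
#' while all derived results are returned as tibbles.
#'
#' @param counts Numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = sample ids). No missing cells.
#' @param samples Data frame with columns `sample_id`, `condition`
#'   (`tumor`/`normal`) and `cohort`; one row per column of `counts`.
#' @param genes Data frame with columns `symbol` and `gc_fraction`; one
#'   row per row of `counts`.
#' @param mu Optional matrix of the generating negative-binomial means,
#'   kept by the simulator so that copy-number coupling can redraw counts.
#' @return An object of class `rho_expr`.
#' @export
expression_matrix <- function(counts, samples, genes, mu = NULL) {
  counts <- as.matrix(counts)
  samples <- as_tibble(samples)
  genes <- as_tibble(genes)
  if (anyNA(counts)) stop("counts must not contain missing cells", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (ncol(counts) != nrow(samples)) {
    stop("sample sheet rows must match count columns", call. = FALSE)
  }
  if (nrow(counts) != nrow(genes)) {
    stop("gene table rows must match count rows", call. = FALSE)
  }
  if (is.null(rownames(counts))) rownames(counts) <- genes$symbol
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!all(samples$condition %in% c("tumor", "normal"))) {
    stop("condition must be 'tumor' or 'normal'", call. = FALSE)
  }
  structure(list(counts = counts, samples = samples, genes = genes, mu = mu),
            class = "rho_expr")
}

#' @export
print.rho_expr <- function(x, ...) {
  cat("<rho_expr> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", sum(x$samples$condition == "tumor"), " tumor / ",
      sum(x$samples$condition == "normal"), " normal)\n", sep = "")
  invisible(x)
}

#' @export
dim.rho_expr <- function(x) dim(x$counts)

#' Subset an expression container by genes and/or samples
#'
#' @param expr A `rho_expr`.
#' @param genes Optional character vector of gene symbols to keep.
#' @param samples Optional character vector of sample ids to keep.
#' @return A `rho_expr` restricted to the requested rows/columns.
#' @export
subset_expression <- function(expr, genes = NULL, samples = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(expr$counts)) else
    match(genes, expr$genes$symbol)
  si <- if (is.null(samples)) seq_len(ncol(expr$counts)) else
    match(samples, expr$samples$sample_id)
  if (anyNA(gi)) stop("unknown gene(s) requested", call. = FALSE)
  if (anyNA(si)) stop("unknown sample(s) requested", call. = FALSE)
  expression_matrix(expr$counts[gi, si, drop = FALSE],
                    expr$samples[si, , drop = FALSE],
                    expr$genes[gi, , drop = FALSE],
                    mu = if (!is.null(expr$mu)) expr$mu[gi, si, drop = FALSE])
}

#' Tidy an expression container into long form
#'
#' @param expr A `rho_expr`.
#' @return Tibble with columns `gene`, `sample_id`, `condition`, `cohort`,
#'   `count`.
#' @export
expression_long <- function(expr) {
  tibble(
    gene = rep(expr$genes$symbol, times = ncol(expr$counts)),
    sample_id = rep(expr$samples$sample_id, each = nrow(expr$counts)),
    condition = rep(expr$samples$condition, each = nrow(expr$counts)),
    cohort = rep(expr$samples$cohort, each = nrow(expr$counts)),
    count = as.vector(expr$counts)
  )
}
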