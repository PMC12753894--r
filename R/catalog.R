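#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data %||%
#' @importFrom dplyr mutate filter select arrange summarise group_by ungroup
#'   across left_join inner_join anti_join bind_rows n n_distinct distinct
#'   case_when if_else pull rename count
#' @importFrom tibble tibble as_tibble
#' @importFrom stats ppois p.adjust quantile rnbinom rpois rnorm runif rbinom
#'   median sd cor loess predict pt pnorm t.test fisher.test dhyper
#'   shapiro.test rlnorm rbeta setNames ks.test
#' @importFrom utils head
NULL

# Functional-category vocabulary for pathway catalog entries.
CATALOG_CATEGORIES <- c("GTPASE", "GEF", "GAP", "GDI",
                        "KINASE_EFFECTOR", "NONKINASE_ELEMENT")

SUBSTRATES <- c("RHOA", "RAC1", "CDC42", "UNKNOWN")

#' Load a curated pathway-gene catalog
#'
#' Reads a tab-separated catalog of pathway genes with their functional
#' categories, coding lengths, GC content and (for GEFs/GAPs) GTPase
#' substrate specificity, and validates it. The catalog drives every
#' downstream stage: it defines the gene list whose mutational burden,
#' expression deregulation, copy-number behaviour and essentiality are
#' contrasted with genome background.
#'
#' The file must carry columns `symbol`, `categories` (semicolon-joined
#' subset of GTPASE, GEF, GAP, GDI, KINASE_EFFECTOR, NONKINASE_ELEMENT),
#' `coding_length_bp`, `gc_fraction` and optionally `substrate` (RHOA,
#' RAC1, CDC42 or UNKNOWN; UNKNOWN assumed when absent). Lines starting
#' with `#` are ignored.
#'
#' @param path Path to the catalog TSV.
#' @return A tibble of class `rho_catalog` with columns `symbol`,
#'   `categories` (list column of character vectors), `coding_length_bp`,
#'   `gc_fraction`, `substrate`, in file order.
#' @export
load_catalog <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  required <- c("symbol", "categories", "coding_length_bp", "gc_fraction")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("catalog is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"substrate" %in% names(raw)) raw$substrate <- "UNKNOWN"
  raw$substrate[is.na(raw$substrate)] <- "UNKNOWN"
  cat_tbl <- tibble(
    symbol = as.character(raw$symbol),
    categories = strsplit(as.character(raw$categories), ";", fixed = TRUE),
    coding_length_bp = as.integer(raw$coding_length_bp),
    gc_fraction = as.numeric(raw$gc_fraction),
    substrate = as.character(raw$substrate)
  )
  validate_catalog(cat_tbl)
}

#' Build a pathway catalog from an in-memory table
#'
#' Same validation as [load_catalog()] but starting from a data frame,
#' convenient for simulated catalogs. `categories` may be a list column
#' or a semicolon-joined character column.
#'
#' @param x Data frame with columns `symbol`, `categories`,
#'   `coding_length_bp`, `gc_fraction` and optionally `substrate`.
#' @return A validated `rho_catalog` tibble.
#' @export
as_catalog <- function(x) {
  x <- as_tibble(x)
  if (!is.list(x$categories)) {
    x$categories <- strsplit(as.character(x$categories), ";", fixed = TRUE)
  }
  if (!"substrate" %in% names(x)) x$substrate <- "UNKNOWN"
  x$coding_length_bp <- as.integer(x$coding_length_bp)
  validate_catalog(x[, c("symbol", "categories", "coding_length_bp",
                         "gc_fraction", "substrate")])
}

validate_catalog <- function(x) {
  dup <- unique(x$symbol[duplicated(x$symbol)])
  if (length(dup) > 0) {
    stop("duplicated catalog symbol(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  toks <- unique(unlist(x$categories))
  bad <- setdiff(toks, CATALOG_CATEGORIES)
  if (length(bad) > 0) {
    stop("unknown category token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(x$categories) == 0)) {
    stop("every catalog entry needs at least one category", call. = FALSE)
  }
  bad_sub <- setdiff(unique(x$substrate), SUBSTRATES)
  if (length(bad_sub) > 0) {
    stop("unknown substrate value(s): ", paste(bad_sub, collapse = ", "),
         call. = FALSE)
  }
  regulator <- vapply(x$categories,
                      function(ct) any(ct %in% c("GEF", "GAP")), logical(1))
  offender <- x$symbol[x$substrate != "UNKNOWN" & !regulator]
  if (length(offender) > 0) {
    stop("substrate specificity only applies to GEF/GAP entries: ",
         paste(offender, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$coding_length_bp)) || any(x$coding_length_bp <= 0)) {
    stop("coding_length_bp must be a positive integer for every entry",
         call. = FALSE)
  }
  if (any(!is.finite(x$gc_fraction)) ||
      any(x$gc_fraction < 0 | x$gc_fraction > 1)) {
    stop("gc_fraction must lie in [0, 1]", call. = FALSE)
  }
  class(x) <- unique(c("rho_catalog", class(x)))
  x
}

#' Tally catalog membership per functional category
#'
#' Counts genes per functional category (a gene with several categories
#' counts once in each), the number of genes carrying more than one
#' category, and the number of distinct genes. Because of multi-domain
#' proteins (e.g. exchange factors that also carry a GAP domain), the sum
#' of category counts exceeds the distinct-gene total by exactly the
#' multi-membership corrections.
#'
#' @param catalog A `rho_catalog`.
#' @return One-row tibble with one count column per category,
#'   `dual_membership_count` and `unique_total`.
#' @export
category_census <- function(catalog) {
  counts <- vapply(CATALOG_CATEGORIES, function(ct) {
    sum(vapply(catalog$categories, function(v) ct %in% v, logical(1)))
  }, integer(1))
  out <- as_tibble(as.list(counts))
  out$dual_membership_count <- sum(lengths(catalog$categories) > 1L)
  out$unique_total <- length(unique(catalog$symbol))
  out
}

#' Write a catalog back to TSV
#'
#' Inverse of [load_catalog()]: categories are re-joined with semicolons.
#'
#' @param catalog A `rho_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  flat <- tibble(
    symbol = catalog$symbol,
    categories = vapply(catalog$categories, paste, character(1),
                        collapse = ";"),
    coding_length_bp = catalog$coding_length_bp,
    gc_fraction = catalog$gc_fraction,
    substrate = catalog$substrate
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
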