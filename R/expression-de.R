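#' Sample-correlation (AAIC-style) outlier filter
#'
#' Computes, per sample, the mean pairwise Pearson correlation of its
#' log2(count + 1) profile against all other samples and removes (in a
#' single pass) samples whose mean correlation falls below `min_cor`.
#' An undefined correlation (constant profile) is treated as 0, so a
#' degenerate sample is removed.
#'
#' @param expr A `rho_expr` with at least 3 samples.
#' @param min_cor Retention cutoff on the mean correlation (default 0.6).
#' @return List with `expr` (filtered container) and `report` (tibble:
#'   `sample_id`, `mean_cor`, `removed`).
#' @export
aaic_filter <- function(expr, min_cor = 0.6) {
  if (ncol(expr$counts) < 3) stop("need at least 3 samples", call. = FALSE)
  lc <- log2(expr$counts + 1)
  cm <- suppressWarnings(cor(lc))
  cm[is.na(cm)] <- 0
  diag(cm) <- NA
  mean_cor <- rowMeans(cm, na.rm = TRUE)
  report <- tibble(sample_id = expr$samples$sample_id,
                   mean_cor = unname(mean_cor),
                   removed = unname(mean_cor) < min_cor)
  keep <- report$sample_id[!report$removed]
  list(expr = subset_expression(expr, samples = keep), report = report)
}

#' Remove the lowest-expressed quartile of genes
#'
#' Genes whose mean count falls strictly below the 25th percentile
#' (linear-interpolation percentile, R quantile type 7) of all gene
#' means are dropped.
#'
#' @param expr A `rho_expr`.
#' @return Filtered `rho_expr` (no-op with a warning below 4 genes);
#'   removed symbols are attached as attribute `"genes_removed"`.
#' @export
low_expression_filter <- function(expr) {
  if (nrow(expr$counts) < 4) {
    warning("fewer than 4 genes; low-expression filter skipped",
            call. = FALSE)
    attr(expr, "genes_removed") <- character(0)
    return(expr)
  }
  means <- rowMeans(expr$counts)
  p25 <- quantile(means, 0.25, type = 7, names = FALSE)
  keep <- means >= p25
  out <- subset_expression(expr, genes = expr$genes$symbol[keep])
  attr(out, "genes_removed") <- expr$genes$symbol[!keep]
  out
}

#' Within-lane GC-content normalization
#'
#' Per sample, fits a loess regression of log2(count + 1) on the gene GC
#' fraction and removes the fitted trend (re-centred so the sample's
#' mean log-expression is preserved), then maps back to the count scale
#' (non-negative). After normalization the per-sample correlation
#' between log expression and GC is close to zero even when the input
#' carries a strong smooth GC trend.
#'
#' @param expr A `rho_expr` with per-gene `gc_fraction`.
#' @param span Loess span (default 0.75).
#' @return Normalized `rho_expr` (values are no longer integers).
#' @export
within_lane_gc_normalize <- function(expr, span = 0.75) {
  gc <- expr$genes$gc_fraction
  if (length(unique(gc)) < 2) {
    warning("constant GC vector; within-lane normalization skipped",
            call. = FALSE)
    return(expr)
  }
  lc <- log2(expr$counts + 1)
  out <- lc
  for (j in seq_len(ncol(lc))) {
    fit <- stats::loess(y ~ gc, data = data.frame(y = lc[, j], gc = gc),
                        span = span, degree = 2,
                        family = "gaussian")
    trend <- predict(fit, newdata = data.frame(gc = gc))
    out[, j] <- lc[, j] - trend + mean(trend)
  }
  counts <- pmax(2^out - 1, 0)
  expression_matrix(counts, expr$samples, expr$genes, mu = expr$mu)
}

#' Between-lane full-quantile normalization
#'
#' Forces every sample to share the same sorted value multiset (the mean
#' quantile across samples) while preserving within-sample rank order.
#' Ties receive the mean of the quantile values their ranks span.
#'
#' @param expr A `rho_expr`.
#' @return Normalized `rho_expr`.
#' @export
between_lane_normalize <- function(expr) {
  x <- expr$counts
  target <- rowMeans(apply(x, 2, sort))
  ct <- c(0, cumsum(target))
  out <- x
  for (j in seq_len(ncol(x))) {
    rmin <- rank(x[, j], ties.method = "min")
    rmax <- rank(x[, j], ties.method = "max")
    out[, j] <- (ct[rmax + 1] - ct[rmin]) / (rmax - rmin + 1)
  }
  expression_matrix(out, expr$samples, expr$genes, mu = expr$mu)
}

#' Negative-binomial Wald differential expression
#'
#' Per-gene two-group test under a negative-binomial model with variance
#' mu + alpha * mu^2. Gene-wise dispersions are estimated by adjusted
#' method of moments from within-group variances and shrunk (geometric
#' interpolation, weight `shrink_weight`) toward a loess mean-dispersion
#' trend. The log2 fold-change (first group over second, pseudo-count
#' 0.5) is tested with a Wald statistic whose standard error comes from
#' the NB variance model, referred to a t distribution with n - 2
#' degrees of freedom; p-values are BH-adjusted. Status calls use the
#' strict thresholds |log2FC| > `lfc_cutoff` and FDR < `fdr_cutoff`.
#'
#' @param expr A `rho_expr`, or a numeric gene-by-sample matrix.
#' @param groups Optional two-level grouping vector over samples; when
#'   `expr` is a `rho_expr` the `condition` column is used by default
#'   (tumor vs normal).
#' @param shrink_weight Weight of the trend in the dispersion shrinkage
#'   (0 = raw gene-wise, 1 = pure trend; default 0.5).
#' @param lfc_cutoff,fdr_cutoff Status thresholds (defaults 1 and 0.01).
#' @return Tibble of class `rho_de` with `gene`, `base_mean`, `log2fc`,
#'   `se`, `statistic`, `pvalue`, `fdr`, `status`, `dispersion`,
#'   `zero_group` (TRUE when a group had an all-zero mean and the
#'   fold-change rests on pseudo-counts).
#' @export
nb_differential_expression <- function(expr, groups = NULL,
                                       shrink_weight = 0.5,
                                       lfc_cutoff = 1, fdr_cutoff = 0.01) {
  if (inherits(expr, "rho_expr")) {
    x <- expr$counts
    if (is.null(groups)) groups <- expr$samples$condition
    gene_ids <- expr$genes$symbol
  } else {
    x <- as.matrix(expr)
    gene_ids <- rownames(x) %||% paste0("g", seq_len(nrow(x)))
  }
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("groups must have exactly 2 levels", call. = FALSE)
  # convention: tumor (or first level) over normal
  if (all(sort(lv) == c("normal", "tumor"))) lv <- c("tumor", "normal")
  i1 <- which(groups == lv[1]); i0 <- which(groups == lv[2])
  n1 <- length(i1); n0 <- length(i0)
  if (n1 < 2 || n0 < 2) stop("need >= 2 samples per group", call. = FALSE)
  x1 <- x[, i1, drop = FALSE]; x0 <- x[, i0, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- apply(x1, 1, stats::var); v0 <- apply(x0, 1, stats::var)
  base_mean <- (n1 * m1 + n0 * m0) / (n1 + n0)
  # adjusted method-of-moments dispersion, pooled over groups
  a1 <- (v1 - m1) / m1^2
  a0 <- (v0 - m0) / m0^2
  a1[!is.finite(a1)] <- NA
  a0[!is.finite(a0)] <- NA
  w1 <- n1 - 1; w0 <- n0 - 1
  a_raw <- (w1 * dplyr::coalesce(a1, a0) + w0 * dplyr::coalesce(a0, a1)) /
    (w1 + w0)
  a_raw[is.na(a_raw)] <- 0
  a_raw <- pmax(a_raw, 0)
  disp <- shrink_dispersion(a_raw, base_mean, shrink_weight)
  m1p <- m1 + 0.5; m0p <- m0 + 0.5
  log2fc <- log2(m1p / m0p)
  se <- sqrt(((1 / m1p + disp) / n1 + (1 / m0p + disp) / n0)) / log(2)
  statistic <- log2fc / se
  df <- n1 + n0 - 2
  pvalue <- 2 * pt(-abs(statistic), df = df)
  fdr <- p.adjust(pvalue, method = "BH")
  out <- tibble(
    gene = gene_ids, base_mean = base_mean, log2fc = log2fc, se = se,
    statistic = statistic, pvalue = pvalue, fdr = fdr,
    dispersion = disp,
    zero_group = m1 == 0 | m0 == 0,
    status = case_when(
      log2fc > lfc_cutoff & fdr < fdr_cutoff ~ "up",
      log2fc < -lfc_cutoff & fdr < fdr_cutoff ~ "down",
      TRUE ~ "ns"
    )
  )
  class(out) <- c("rho_de", class(out))
  attr(out, "groups") <- stats::setNames(c(n1, n0), lv)
  attr(out, "thresholds") <- c(lfc = lfc_cutoff, fdr = fdr_cutoff)
  out
}

# Geometric-interpolation shrinkage of raw MoM dispersions toward a
# loess trend on the mean; degenerate inputs fall back gracefully.
shrink_dispersion <- function(a_raw, base_mean, weight, floor = 1e-8) {
  a_floor <- pmax(a_raw, 1e-3)
  ok <- base_mean > 0 & a_raw > 0
  trend <- rep(stats::median(a_floor), length(a_raw))
  if (sum(ok) >= 10) {
    fit <- tryCatch(
      stats::loess(la ~ lm, data = data.frame(la = log(a_raw[ok]),
                                              lm = log(base_mean[ok])),
                   span = 1, degree = 1),
      error = function(e) NULL)
    if (!is.null(fit)) {
      pred <- predict(fit, newdata = data.frame(lm = log(pmax(base_mean,
                                                              1e-8))))
      pred[!is.finite(pred)] <- log(stats::median(a_floor))
      trend <- exp(pred)
    }
  }
  pmax(exp(weight * log(pmax(trend, floor)) +
             (1 - weight) * log(a_floor)), floor)
}

#' @export
tidy.rho_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "rho_de")
  out
}

#' @export
glance.rho_de <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_up = sum(x$status == "up"),
         n_down = sum(x$status == "down"),
         median_dispersion = stats::median(x$dispersion))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Differential-expression count enrichment against random gene lists
#'
#' Compares the number of differentially expressed pathway genes with
#' the distribution of DE counts over length-matched random gene lists
#' (the same resampling null as the mutation-burden test). p is the
#' upper-tail Poisson probability at lambda = background mean.
#'
#' @param de A DE table covering catalog and background genes (columns
#'   `gene`, `status`).
#' @param catalog A `rho_catalog`.
#' @param background Tibble with `symbol`, `coding_length_bp` for the
#'   background universe.
#' @param n_lists Number of random lists (default 1000).
#' @param seed Integer seed for the resampling.
#' @param cohort Cohort label.
#' @return One-row tibble in the [enrichment_test()] shape (statistic
#'   kind `"de_count"`), with per-list counts in attribute `"per_list"`.
#' @export
de_count_enrichment <- function(de, catalog, background, n_lists = 1000L,
                                seed = 1L, cohort = "C01") {
  ensemble <- sample_length_matched_lists(catalog, background,
                                          n_lists = n_lists, seed = seed)
  de_flag <- setNames(de$status != "ns", de$gene)
  miss <- setdiff(unique(as.vector(ensemble$lists)), names(de_flag))
  if (length(miss) > 0) {
    # genes never tested (e.g. filtered out) count as not DE
    de_flag <- c(de_flag, setNames(rep(FALSE, length(miss)), miss))
  }
  per_list <- rowSums(matrix(de_flag[as.vector(ensemble$lists)],
                             nrow = nrow(ensemble$lists)))
  observed <- sum(de_flag[intersect(catalog$symbol, names(de_flag))])
  bg_mean <- mean(per_list); bg_sd <- sd(per_list)
  z <- if (bg_sd == 0) {
    if (observed == bg_mean) 0 else sign(observed - bg_mean) * Inf
  } else (observed - bg_mean) / bg_sd
  p <- ppois(observed - 1, lambda = bg_mean, lower.tail = FALSE)
  out <- tibble(cohort = cohort, statistic_kind = "de_count",
                observed = as.numeric(observed), background_mean = bg_mean,
                background_sd = bg_sd, z = z, p = p,
                shapiro_w = NA_real_, tier = p_tier(p))
  attr(out, "per_list") <- per_list
  out
}

#' Pan-cancer deregulation classing
#'
#' Aggregates per-cohort DE statuses per gene into a pan-cancer profile.
#' Breadth is the fraction of tested cohorts in which the gene is DE;
#' tiers are strict (> 50%, 25-50%, < 25%). Classes: `pan_up` /
#' `pan_down` when one direction strictly dominates and breadth exceeds
#' 0.25; `mixed` when both directions occur without a dominant,
#' breadth-qualified direction; `restricted` for sub-breadth
#' single-direction profiles; `none` when never DE.
#'
#' @param statuses Tibble with `gene`, `cohort`, `status`
#'   (`up`/`down`/`ns`), one row per tested (gene, cohort).
#' @return Tibble per gene: `n_cohorts_tested`, `n_up`, `n_down`,
#'   `breadth_fraction`, `tier`, `class`.
#' @export
pan_cancer_classify <- function(statuses) {
  statuses |>
    group_by(gene = .data$gene) |>
    summarise(n_cohorts_tested = n(),
              n_up = sum(.data$status == "up"),
              n_down = sum(.data$status == "down"),
              .groups = "drop") |>
    mutate(
      breadth_fraction = (.data$n_up + .data$n_down) /
        .data$n_cohorts_tested,
      tier = case_when(.data$breadth_fraction > 0.5 ~ "gt50pct",
                       .data$breadth_fraction > 0.25 ~ "25to50pct",
                       TRUE ~ "lt25pct"),
      class = case_when(
        .data$n_up + .data$n_down == 0 ~ "none",
        .data$n_up > .data$n_down & .data$breadth_fraction > 0.25 ~ "pan_up",
        .data$n_down > .data$n_up & .data$breadth_fraction > 0.25 ~
          "pan_down",
        .data$n_up > 0 & .data$n_down > 0 ~ "mixed",
        TRUE ~ "restricted"
      )
    )
}

#' Substrate-specificity tallies for deregulated GEFs and GAPs
#'
#' For each regulator role (GEF, GAP) and pan-cancer direction, counts
#' genes per GTPase substrate (RHOA, RAC1, CDC42, UNKNOWN) and reports
#' percentages (one decimal) against the full role-direction list size,
#' so genes with unknown substrate stay in the denominator.
#'
#' @param profiles Output of [pan_cancer_classify()].
#' @param catalog A `rho_catalog` carrying `categories` and `substrate`.
#' @param directions Profile classes to tally (default `pan_up` and
#'   `pan_down`).
#' @return Tibble with `role`, `direction`, `substrate`, `n`,
#'   `list_size`, `pct`.
#' @export
substrate_specificity_tally <- function(profiles, catalog,
                                        directions = c("pan_up",
                                                       "pan_down")) {
  roles <- c("GEF", "GAP")
  combos <- tidyr::expand_grid(role = roles, direction = directions,
                               substrate = SUBSTRATES)
  rows <- purrr::pmap(combos, function(role, direction, substrate) {
    in_role <- catalog$symbol[vapply(catalog$categories,
                                     function(v) role %in% v, logical(1))]
    listed <- profiles$gene[profiles$class == direction &
                              profiles$gene %in% in_role]
    subs <- catalog$substrate[match(listed, catalog$symbol)]
    tibble(role = role, direction = direction, substrate = substrate,
           n = sum(subs == substrate), list_size = length(listed),
           pct = if (length(listed) == 0) 0 else
             round(100 * sum(subs == substrate) / length(listed), 1))
  })
  bind_rows(rows)
}
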