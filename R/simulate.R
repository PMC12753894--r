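#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator. The defaults
#' describe a desk-scale cancer cohort: 200 tumor samples (with matched
#' normals for expression), a genome background of 3,000 genes, a somatic
#' rate of 1e-6 mutations per coding bp per sample, a small hypermutated
#' subpopulation at 10x the cohort rate, negative-binomial counts with
#' dispersion 0.1, and a dependency screen of 220 cell lines across 11
#' lineages with scores centred at 0 (sd 0.2) and pan-essential genes
#' shifted by -1.
#'
#' @param seed Integer seed; together with the config it fully determines
#'   every generated table.
#' @param n_samples Tumor samples per cohort (expression adds the same
#'   number of matched normals).
#' @param n_genes Background (non-pathway) genes in the simulated genome.
#' @param n_cohorts Number of replicate cohorts for the mutation table.
#' @param mutation_rate Expected somatic mutations per coding bp per
#'   sample; must be >= 0.
#' @param hypermutator_fraction Fraction of samples drawn as hypermutated,
#'   in \[0, 1).
#' @param hypermutator_multiplier Rate multiplier for hypermutated
#'   samples; must be > 1.
#' @param pathway_enrichment_factor Multiplier on the mutation rate of
#'   catalog genes (1 = null, no pathway excess).
#' @param nb_dispersion Negative-binomial dispersion alpha with variance
#'   mu + alpha * mu^2; must be > 0.
#' @param planted_log2fc Named numeric of tumor-vs-normal log2
#'   fold-changes planted in expression (names = gene symbols).
#' @param gc_bias_strength Amplitude of the per-sample ("lane")
#'   multiplicative GC trend on expression means; 0 disables it.
#' @param cnv_dosage_log2fc_per_copy log2 expression change per
#'   copy-number call unit when coupling calls to expression.
#' @param cnv_class_probs Probabilities of calls -2,-1,0,1,2 (must sum
#'   to 1).
#' @param dependency_shift Score shift planted for lineage-specific
#'   dependency genes (negative = sensitizing).
#' @param dependency_sigma Baseline sd of dependency scores.
#' @param lineage_labels Lineage names for the dependency screen.
#' @param n_lines_per_lineage Cell lines per lineage.
#' @param n_dependency_genes Genes scored in the dependency screen.
#' @param n_pan_essential Number of genes shifted by -1 in every line.
#' @param n_lineage_specific Number of genes receiving
#'   `dependency_shift` in the first lineage only.
#' @param variant_class_probs Probabilities for the variant classes
#'   synonymous, missense, truncating, other.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   per-gene baseline expression mean.
#' @return A list of class `rho_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 200L,
                       n_genes = 3000L,
                       n_cohorts = 1L,
                       mutation_rate = 1e-6,
                       hypermutator_fraction = 0.02,
                       hypermutator_multiplier = 10,
                       pathway_enrichment_factor = 1,
                       nb_dispersion = 0.1,
                       planted_log2fc = numeric(0),
                       gc_bias_strength = 0,
                       cnv_dosage_log2fc_per_copy = 1,
                       cnv_class_probs = c(`-2` = 0.02, `-1` = 0.08,
                                           `0` = 0.80, `1` = 0.08,
                                           `2` = 0.02),
                       dependency_shift = -1,
                       dependency_sigma = 0.2,
                       lineage_labels = c("lung", "breast", "colon", "skin",
                                          "blood", "brain", "kidney",
                                          "liver", "ovary", "pancreas",
                                          "bone"),
                       n_lines_per_lineage = 20L,
                       n_dependency_genes = 200L,
                       n_pan_essential = 20L,
                       n_lineage_specific = 10L,
                       variant_class_probs = c(synonymous = 0.25,
                                               missense = 0.55,
                                               truncating = 0.12,
                                               other = 0.08),
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1) {
  if (mutation_rate < 0) stop("mutation_rate must be >= 0", call. = FALSE)
  if (hypermutator_fraction < 0 || hypermutator_fraction >= 1) {
    stop("hypermutator_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (hypermutator_multiplier <= 1) {
    stop("hypermutator_multiplier must be > 1", call. = FALSE)
  }
  if (pathway_enrichment_factor <= 0) {
    stop("pathway_enrichment_factor must be > 0", call. = FALSE)
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (gc_bias_strength < 0) stop("gc_bias_strength must be >= 0", call. = FALSE)
  if (abs(sum(cnv_class_probs) - 1) > 1e-8) {
    stop("cnv_class_probs must sum to 1", call. = FALSE)
  }
  if (length(cnv_class_probs) != 5) {
    stop("cnv_class_probs needs 5 entries for calls -2..2", call. = FALSE)
  }
  if (abs(sum(variant_class_probs) - 1) > 1e-8) {
    stop("variant_class_probs must sum to 1", call. = FALSE)
  }
  if (length(lineage_labels) == 0) {
    stop("lineage_labels must not be empty", call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    n_genes = as.integer(n_genes), n_cohorts = as.integer(n_cohorts),
    mutation_rate = mutation_rate,
    hypermutator_fraction = hypermutator_fraction,
    hypermutator_multiplier = hypermutator_multiplier,
    pathway_enrichment_factor = pathway_enrichment_factor,
    nb_dispersion = nb_dispersion, planted_log2fc = planted_log2fc,
    gc_bias_strength = gc_bias_strength,
    cnv_dosage_log2fc_per_copy = cnv_dosage_log2fc_per_copy,
    cnv_class_probs = cnv_class_probs,
    dependency_shift = dependency_shift,
    dependency_sigma = dependency_sigma,
    lineage_labels = lineage_labels,
    n_lines_per_lineage = as.integer(n_lines_per_lineage),
    n_dependency_genes = as.integer(n_dependency_genes),
    n_pan_essential = as.integer(n_pan_essential),
    n_lineage_specific = as.integer(n_lineage_specific),
    variant_class_probs = variant_class_probs,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd
  )
  class(cfg) <- "rho_sim_config"
  cfg
}

#' Simulate a background gene universe
#'
#' Draws symbols, coding lengths (log-normal, so the length distribution
#' is right-skewed as in real transcriptomes) and GC fractions for the
#' non-pathway genome used by the resampling machinery.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param prefix Symbol prefix.
#' @return Tibble with `symbol`, `coding_length_bp`, `gc_fraction`.
#' @export
simulate_gene_universe <- function(n_genes, seed = 1L, prefix = "BG") {
  withr::with_seed(as.integer(seed), {
    tibble(
      symbol = sprintf("%s%05d", prefix, seq_len(n_genes)),
      coding_length_bp = as.integer(round(rlnorm(n_genes, log(1500), 0.6)) + 90L),
      gc_fraction = rbeta(n_genes, 18, 22)
    )
  })
}

#' Simulate a pathway catalog
#'
#' Builds a synthetic curated catalog with the six functional categories
#' in realistic proportions, a couple of dual GEF/GAP entries, and
#' substrate labels on regulators.
#'
#' @param n_genes Catalog size.
#' @param seed Integer seed.
#' @return A validated `rho_catalog`.
#' @export
simulate_catalog <- function(n_genes = 100L, seed = 1L) {
  withr::with_seed(as.integer(seed) + 11L, {
    base <- simulate_gene_universe(n_genes, seed = as.integer(seed) + 7L,
                                   prefix = "RP")
    probs <- c(GTPASE = 0.05, GEF = 0.17, GAP = 0.14, GDI = 0.01,
               KINASE_EFFECTOR = 0.13, NONKINASE_ELEMENT = 0.50)
    cats <- sample(names(probs), n_genes, replace = TRUE, prob = probs)
    categories <- as.list(cats)
    # a few dual-domain regulators carrying both exchange and GAP domains
    dual <- which(cats == "GEF")
    if (length(dual) >= 2) {
      for (i in dual[1:2]) categories[[i]] <- c("GEF", "GAP")
    }
    regulator <- vapply(categories, function(v) any(v %in% c("GEF", "GAP")),
                        logical(1))
    substrate <- rep("UNKNOWN", n_genes)
    substrate[regulator] <- sample(c("RHOA", "RAC1", "CDC42", "UNKNOWN"),
                                   sum(regulator), replace = TRUE,
                                   prob = c(0.45, 0.25, 0.15, 0.15))
    as_catalog(tibble(
      symbol = base$symbol, categories = categories,
      coding_length_bp = base$coding_length_bp,
      gc_fraction = base$gc_fraction, substrate = substrate
    ))
  })
}

gene_lengths_from <- function(catalog, background) {
  tibble(
    gene = c(catalog$symbol, background$symbol),
    coding_length_bp = c(catalog$coding_length_bp,
                         background$coding_length_bp),
    pathway = c(rep(TRUE, nrow(catalog)), rep(FALSE, nrow(background)))
  )
}

#' Simulate a somatic mutation table
#'
#' Per (gene, sample) mutation counts are Poisson with mean
#' `mutation_rate * coding_length * enrichment`, where enrichment is
#' `pathway_enrichment_factor` for catalog genes and 1 otherwise.
#' Hypermutated samples (drawn at `hypermutator_fraction`) multiply the
#' rate by `hypermutator_multiplier`. Each mutation gets a variant class
#' from `variant_class_probs` and a uniform 1-based protein position.
#'
#' @param config A `rho_sim_config`.
#' @param catalog A `rho_catalog` of pathway genes.
#' @param background_genes Tibble with `symbol` and `coding_length_bp`
#'   (e.g. from [simulate_gene_universe()]).
#' @return List with `mutations` (tibble: `sample_id`, `cohort_id`,
#'   `gene`, `variant_class`, `position`), `samples` (per-sample sheet
#'   with the planted hypermutator flag) and `truth` (planted effects).
#' @export
simulate_mutations <- function(config, catalog, background_genes) {
  stopifnot(inherits(config, "rho_sim_config"))
  genes <- gene_lengths_from(catalog, background_genes)
  if (any(genes$coding_length_bp <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  withr::with_seed(config$seed + 101L, {
    out <- vector("list", config$n_cohorts)
    sample_sheets <- vector("list", config$n_cohorts)
    for (co in seq_len(config$n_cohorts)) {
      cohort_id <- sprintf("C%02d", co)
      sample_ids <- sprintf("%s-S%04d", cohort_id, seq_len(config$n_samples))
      hyper <- runif(config$n_samples) < config$hypermutator_fraction
      rate_g <- config$mutation_rate * genes$coding_length_bp *
        ifelse(genes$pathway, config$pathway_enrichment_factor, 1)
      lam <- outer(rate_g, ifelse(hyper, config$hypermutator_multiplier, 1))
      counts <- matrix(rpois(length(lam), lam), nrow = nrow(genes))
      idx <- which(counts > 0, arr.ind = TRUE)
      n_rec <- counts[idx]
      total <- sum(n_rec)
      if (total > 0) {
        gi <- rep(idx[, 1], n_rec)
        si <- rep(idx[, 2], n_rec)
        prot_len <- pmax(1L, genes$coding_length_bp[gi] %/% 3L)
        recs <- tibble(
          sample_id = sample_ids[si],
          cohort_id = cohort_id,
          gene = genes$gene[gi],
          variant_class = sample(names(config$variant_class_probs), total,
                                 replace = TRUE,
                                 prob = config$variant_class_probs),
          position = as.integer(ceiling(runif(total) * prot_len))
        )
      } else {
        recs <- tibble(sample_id = character(0), cohort_id = character(0),
                       gene = character(0), variant_class = character(0),
                       position = integer(0))
      }
      out[[co]] <- recs
      sample_sheets[[co]] <- tibble(sample_id = sample_ids,
                                    cohort_id = cohort_id,
                                    hypermutator = hyper)
    }
    mutations <- bind_rows(out)
    samples <- bind_rows(sample_sheets)
    truth <- bind_rows(
      tibble(target = catalog$symbol, effect_type = "mutation_enrichment",
             magnitude = config$pathway_enrichment_factor),
      tibble(target = samples$sample_id[samples$hypermutator],
             effect_type = "hypermutator",
             magnitude = config$hypermutator_multiplier)
    )
    list(mutations = mutations, samples = samples, truth = truth)
  })
}

#' Simulate a tumor/normal expression matrix
#'
#' Counts are negative-binomial with per-gene log-normal baseline means
#' and constant dispersion. Tumor samples multiply the mean of each
#' planted gene by `2^planted_log2fc`. When `gc_bias_strength > 0`,
#' every sample gets a "lane" coefficient in \[-1, 1\] and the log2 mean
#' is shifted by `gc_bias_strength * lane * (gc - mean(gc))`, giving a
#' smooth per-sample GC trend for the within-lane normalization to
#' remove.
#'
#' @param config A `rho_sim_config`; `planted_log2fc` names must be a
#'   subset of `genes$symbol`.
#' @param genes A `rho_catalog` or tibble with `symbol` and
#'   `gc_fraction`.
#' @return List with `expression` (a [expression_matrix()] keeping the
#'   generating means) and `truth`.
#' @export
simulate_expression <- function(config, genes) {
  stopifnot(inherits(config, "rho_sim_config"))
  genes <- as_tibble(genes)[, c("symbol", "gc_fraction")]
  planted <- config$planted_log2fc
  if (length(planted) > 0 && !all(names(planted) %in% genes$symbol)) {
    stop("planted_log2fc names must be simulated genes", call. = FALSE)
  }
  n <- config$n_samples
  withr::with_seed(config$seed + 202L, {
    g <- nrow(genes)
    base_mu <- rlnorm(g, config$baseline_log_mean, config$baseline_log_sd)
    lfc <- setNames(rep(0, g), genes$symbol)
    lfc[names(planted)] <- planted
    condition <- rep(c("tumor", "normal"), each = n)
    sample_id <- c(sprintf("T%04d", seq_len(n)), sprintf("N%04d", seq_len(n)))
    lane <- runif(2 * n, -1, 1)
    gc_centered <- genes$gc_fraction - mean(genes$gc_fraction)
    log2mu <- outer(log2(base_mu), rep(1, 2 * n)) +
      outer(lfc, as.numeric(condition == "tumor")) +
      config$gc_bias_strength * outer(gc_centered, lane)
    mu <- 2^log2mu
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / config$nb_dispersion), nrow = g)
    rownames(counts) <- genes$symbol
    colnames(counts) <- sample_id
    rownames(mu) <- genes$symbol
    colnames(mu) <- sample_id
    expr <- expression_matrix(
      counts,
      tibble(sample_id = sample_id, condition = condition, cohort = "C01"),
      genes, mu = mu
    )
    truth <- bind_rows(
      tibble(target = names(planted), effect_type = "log2fc",
             magnitude = unname(planted)),
      tibble(target = "all_samples", effect_type = "gc_bias",
             magnitude = config$gc_bias_strength)
    )
    list(expression = expr, truth = truth)
  })
}

#' Simulate thresholded copy-number calls coupled to expression
#'
#' Calls in \{-2,...,2\} are drawn i.i.d. per (gene, tumor sample) from
#' `cnv_class_probs`. For cells with a non-zero call, the expression
#' counts are redrawn from the stored generating mean multiplied by
#' `2^(cnv_dosage_log2fc_per_copy * call)`, so copy number has a dosage
#' effect on expression. Optional driver genes are added to the call
#' matrix only, co-altered with their paired pathway gene at a planted
#' odds ratio.
#'
#' @param config A `rho_sim_config`.
#' @param expression The simulation output of [simulate_expression()]
#'   (`rho_expr` with stored means).
#' @param driver_pairs Optional tibble with columns `pathway_gene`,
#'   `driver_gene`, `odds_ratio`, `direction` (`"amp"` or `"del"`).
#' @return List with `cnv` (call matrix, genes + drivers by tumor
#'   samples), `expression` (counts redrawn for altered cells) and
#'   `truth`.
#' @export
simulate_cnv <- function(config, expression, driver_pairs = NULL) {
  stopifnot(inherits(config, "rho_sim_config"),
            inherits(expression, "rho_expr"))
  if (is.null(expression$mu)) {
    stop("expression must carry generating means (simulate_expression output)",
         call. = FALSE)
  }
  tumor <- expression$samples$sample_id[expression$samples$condition == "tumor"]
  genes <- expression$genes$symbol
  withr::with_seed(config$seed + 303L, {
    calls <- matrix(
      sample(c(-2L, -1L, 0L, 1L, 2L), nrow(expression$counts) * length(tumor),
             replace = TRUE, prob = config$cnv_class_probs),
      nrow = nrow(expression$counts),
      dimnames = list(genes, tumor)
    )
    driver_calls <- NULL
    if (!is.null(driver_pairs) && nrow(driver_pairs) > 0) {
      driver_calls <- matrix(0L, nrow(driver_pairs), length(tumor),
                             dimnames = list(driver_pairs$driver_gene, tumor))
      for (i in seq_len(nrow(driver_pairs))) {
        pg <- driver_pairs$pathway_gene[i]
        if (!pg %in% genes) stop("unknown pathway gene in driver_pairs: ", pg,
                                 call. = FALSE)
        dir_sign <- if (driver_pairs$direction[i] == "amp") 1L else -1L
        altered <- sign(calls[pg, ]) == dir_sign
        pa <- max(mean(altered), 1e-6)
        or <- driver_pairs$odds_ratio[i]
        p0 <- pa
        p1 <- or * p0 / (1 + p0 * (or - 1))
        hit <- runif(length(tumor)) < ifelse(altered, p1, p0)
        driver_calls[i, hit] <- 2L * dir_sign
      }
    }
    dosage <- config$cnv_dosage_log2fc_per_copy
    expr <- expression
    if (dosage != 0) {
      ti <- match(tumor, expr$samples$sample_id)
      mu_t <- expr$mu[, ti, drop = FALSE] * 2^(dosage * calls)
      redraw <- calls != 0
      new_counts <- expr$counts[, ti, drop = FALSE]
      new_counts[redraw] <- rnbinom(sum(redraw), mu = mu_t[redraw],
                                    size = 1 / config$nb_dispersion)
      expr$counts[, ti] <- new_counts
      expr$mu[, ti] <- mu_t
    }
    truth <- bind_rows(
      tibble(target = "all_genes", effect_type = "cnv_dosage_log2fc_per_copy",
             magnitude = dosage),
      if (!is.null(driver_pairs) && nrow(driver_pairs) > 0) {
        tibble(target = paste(driver_pairs$pathway_gene,
                              driver_pairs$driver_gene, sep = "|"),
               effect_type = "driver_cooccurrence_or",
               magnitude = driver_pairs$odds_ratio)
      }
    )
    list(cnv = rbind(calls, driver_calls), expression = expr, truth = truth)
  })
}

#' Simulate a dependency screen
#'
#' Baseline scores are Normal(0, `dependency_sigma`). The first
#' `n_pan_essential` genes are shifted by -1 in every cell line; the next
#' `n_lineage_specific` genes are shifted by `dependency_shift` in the
#' first lineage only.
#'
#' @param config A `rho_sim_config`.
#' @return List with `scores` (gene-by-line matrix), `lines` (tibble:
#'   `cell_line`, `lineage`) and `truth`.
#' @export
simulate_dependency <- function(config) {
  stopifnot(inherits(config, "rho_sim_config"))
  if (length(config$lineage_labels) == 0) {
    stop("lineage_labels must not be empty", call. = FALSE)
  }
  withr::with_seed(config$seed + 404L, {
    lines <- tibble(
      cell_line = sprintf("CL%04d", seq_len(config$n_lines_per_lineage *
                                              length(config$lineage_labels))),
      lineage = rep(config$lineage_labels,
                    each = config$n_lines_per_lineage)
    )
    genes <- sprintf("DEP%04d", seq_len(config$n_dependency_genes))
    scores <- matrix(rnorm(length(genes) * nrow(lines),
                           sd = config$dependency_sigma),
                     nrow = length(genes),
                     dimnames = list(genes, lines$cell_line))
    pan <- genes[seq_len(min(config$n_pan_essential, length(genes)))]
    scores[pan, ] <- scores[pan, ] - 1
    n_spec <- min(config$n_lineage_specific,
                  length(genes) - length(pan))
    spec <- genes[length(pan) + seq_len(n_spec)]
    target_lines <- lines$cell_line[lines$lineage == config$lineage_labels[1]]
    scores[spec, target_lines] <- scores[spec, target_lines] +
      config$dependency_shift
    truth <- bind_rows(
      tibble(target = pan, effect_type = "pan_essential", magnitude = -1),
      tibble(target = spec,
             effect_type = paste0("lineage_shift:",
                                  config$lineage_labels[1]),
             magnitude = config$dependency_shift)
    )
    list(scores = scores, lines = lines, truth = truth)
  })
}

#' Long-format view of a dependency screen
#'
#' @param dep Output of [simulate_dependency()] or a list with `scores`
#'   and `lines` in the same shape.
#' @return Tibble with `gene`, `cell_line`, `lineage`, `score`.
#' @export
dependency_long <- function(dep) {
  tibble(
    gene = rep(rownames(dep$scores), times = ncol(dep$scores)),
    cell_line = rep(colnames(dep$scores), each = nrow(dep$scores)),
    score = as.vector(dep$scores)
  ) |>
    left_join(dep$lines, by = "cell_line")
}
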