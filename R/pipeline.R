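#' Default analysis thresholds
#'
#' The pipeline's decision thresholds, collected in one place: the 4.5x
#' hypermutator rule, the 0.6 sample-correlation cutoff, |log2FC| > 1
#' with FDR < 0.01 for differential expression (also used for the
#' copy-number contrasts), q < 0.01 for positive selection, the > 30%
#' in-cluster fraction and > 3% hotspot prevalence tiers, > 10%
#' alteration prevalence, adjusted p < 0.05 for co-occurrence, the
#' dependency rules (score < -0.5 in > 10% of lines; |median diff| >
#' 0.5 with FDR < 0.01), 1,000 resampling lists and 10,000 GSEA
#' permutations with a maximum set size of 800.
#'
#' @return Named list of thresholds.
#' @export
rho_thresholds <- function() {
  list(
    hypermutator_multiplier = 4.5,
    aaic_min_cor = 0.6,
    lfc_cutoff = 1,
    de_fdr = 0.01,
    q_cutoff = 0.01,
    hotspot_fraction = 0.30,
    hotspot_prevalence = 0.03,
    scnv_prevalence = 0.10,
    cooccurrence_fdr = 0.05,
    chronos_threshold = -0.5,
    essential_fraction = 0.10,
    vulnerability_median_diff = 0.5,
    vulnerability_fdr = 0.01,
    enrichment_fdr = 0.05,
    coexpression_fdr = 0.05,
    n_lists = 1000L,
    n_perm = 10000L,
    max_set_size = 800L
  )
}

#' Validate a bundle of pipeline input files
#'
#' Schema and invariant checks for every recognized input format.
#' Report-only: problems are returned, not raised.
#'
#' @param paths Named list of file paths; recognized names are
#'   `catalog`, `background_genes`, `mutations`, `counts`, `samples`,
#'   `cnv`, `dependency_scores`, `dependency_lineages`, `drivers`.
#' @return Tibble with `input`, `level` (`error`/`warning`), `message`;
#'   zero rows when everything validates.
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  note <- function(input, level, msg) {
    issues[[length(issues) + 1]] <<- tibble(input = input, level = level,
                                            message = msg)
  }
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) note(nm, "error", "file does not exist")
  }
  if (!is.null(paths$catalog) && file.exists(paths$catalog)) {
    tryCatch(load_catalog(paths$catalog),
             error = function(e) note("catalog", "error",
                                      conditionMessage(e)))
  }
  if (!is.null(paths$mutations) && file.exists(paths$mutations)) {
    tryCatch({
      mut <- read_mutations(paths$mutations)
      if (nrow(mut) == 0) note("mutations", "warning", "no records")
    }, error = function(e) note("mutations", "error", conditionMessage(e)))
  }
  if (!is.null(paths$counts) && file.exists(paths$counts)) {
    tryCatch({
      m <- read_matrix_tsv(paths$counts)
      neg <- which(m < 0, arr.ind = TRUE)
      if (nrow(neg) > 0) {
        note("counts", "error",
             paste0("negative count for gene ", rownames(m)[neg[1, 1]],
                    ", sample ", colnames(m)[neg[1, 2]]))
      }
      if (any(m != round(m))) {
        note("counts", "warning", "non-integer counts present")
      }
    }, error = function(e) note("counts", "error", conditionMessage(e)))
  }
  if (!is.null(paths$cnv) && file.exists(paths$cnv)) {
    tryCatch({
      m <- read_matrix_tsv(paths$cnv)
      bad <- which(matrix(!(m %in% c(-2, -1, 0, 1, 2)), nrow(m)),
                   arr.ind = TRUE)
      if (nrow(bad) > 0) {
        note("cnv", "error",
             paste0("call out of vocabulary for gene ",
                    rownames(m)[bad[1, 1]], ", sample ",
                    colnames(m)[bad[1, 2]], " (value ",
                    m[bad[1, , drop = FALSE]], ")"))
      }
    }, error = function(e) note("cnv", "error", conditionMessage(e)))
  }
  if (!is.null(paths$dependency_scores) &&
      file.exists(paths$dependency_scores) &&
      !is.null(paths$dependency_lineages) &&
      file.exists(paths$dependency_lineages)) {
    tryCatch(read_dependency_csv(paths$dependency_scores,
                                 paths$dependency_lineages),
             error = function(e) note("dependency_scores", "error",
                                      conditionMessage(e)))
  }
  if (length(issues) == 0) {
    return(tibble(input = character(0), level = character(0),
                  message = character(0)))
  }
  bind_rows(issues)
}

#' Read a gene-by-sample matrix TSV
#'
#' First column is the gene symbol; remaining columns are samples.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(d[, -1])
  mode(m) <- "numeric"
  rownames(m) <- as.character(d[[1]])
  m
}

#' Write a gene-by-sample matrix TSV
#'
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the gene column (default "symbol").
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "symbol") {
  d <- as_tibble(m, rownames = id_col)
  readr::write_tsv(d, path, progress = FALSE)
  invisible(path)
}

#' Write a full synthetic input bundle to disk
#'
#' Generates a coherent set of pipeline inputs (catalog, background
#' genes, mutations, expression counts + sample sheet, copy-number
#' calls, driver list, dependency screen) from one simulation
#' configuration, along with the ground-truth sidecar of every planted
#' effect.
#'
#' @param config A `rho_sim_config`.
#' @param dir Output directory (created if needed).
#' @param n_catalog_genes Catalog size (default 100).
#' @param driver_pairs Optional driver co-occurrence table for
#'   [simulate_cnv()].
#' @return Named list of the written file paths.
#' @export
write_simulation_bundle <- function(config, dir, n_catalog_genes = 100L,
                                    driver_pairs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- simulate_catalog(n_catalog_genes, seed = config$seed)
  background <- simulate_gene_universe(config$n_genes,
                                       seed = config$seed + 1L)
  mut <- simulate_mutations(config, catalog, background)
  expr_genes <- bind_rows(
    tibble(symbol = catalog$symbol, gc_fraction = catalog$gc_fraction),
    tibble(symbol = background$symbol,
           gc_fraction = background$gc_fraction)
  )
  ex <- simulate_expression(config, expr_genes)
  cn <- simulate_cnv(config, ex$expression, driver_pairs = driver_pairs)
  dep <- simulate_dependency(config)
  paths <- list(
    catalog = file.path(dir, "catalog.tsv"),
    background_genes = file.path(dir, "background_genes.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    cnv = file.path(dir, "cnv_calls.tsv"),
    drivers = file.path(dir, "drivers.txt"),
    dependency_scores = file.path(dir, "dependency_scores.csv"),
    dependency_lineages = file.path(dir, "dependency_lineages.csv"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  write_catalog(catalog, paths$catalog)
  readr::write_tsv(background, paths$background_genes, progress = FALSE)
  readr::write_tsv(mut$mutations, paths$mutations, progress = FALSE)
  write_matrix_tsv(cn$expression$counts, paths$counts)
  readr::write_tsv(cn$expression$samples, paths$samples, progress = FALSE)
  write_matrix_tsv(cn$cnv, paths$cnv)
  writeLines(if (!is.null(driver_pairs)) unique(driver_pairs$driver_gene)
             else character(0), paths$drivers)
  scores_wide <- as_tibble(t(dep$scores), rownames = "cell_line")
  readr::write_csv(scores_wide, paths$dependency_scores, progress = FALSE)
  readr::write_csv(dep$lines, paths$dependency_lineages, progress = FALSE)
  truth <- bind_rows(mut$truth, ex$truth, cn$truth, dep$truth)
  readr::write_tsv(truth, paths$truth, progress = FALSE)
  paths
}

#' Run the integrated pipeline on an input bundle
#'
#' Executes the enabled stages in their fixed order — mutation burden
#' (hypermutator filter, load/prevalence, resampling enrichment),
#' expression (sample-correlation filter, lowest-quartile filter,
#' within-lane GC and between-lane quantile normalization, NB
#' differential expression, DE-count enrichment), copy-number
#' integration (prevalence, contrasts, concordance, driver
#' co-occurrence) and dependency statistics — writing one TSV per result
#' and a JSON manifest with the package version, seed, thresholds,
#' per-stage row counts and input/output checksums. Re-running with the
#' same inputs and seed is byte-reproducible.
#'
#' @param config List (or path to a YAML file) with elements `inputs`
#'   (named paths as in [validate_inputs()]), `outdir`, optional
#'   `stages` (subset of `mutation`, `expression`, `cnv`,
#'   `dependency`), optional `seed` (default 1) and optional
#'   `thresholds` overriding [rho_thresholds()] entries.
#' @return Invisibly, a list with the per-stage result tables and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("inputs", "outdir", "stages", "seed", "thresholds")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stages <- config$stages %||% c("mutation", "expression", "cnv",
                                 "dependency")
  bad_stage <- setdiff(stages, c("mutation", "expression", "cnv",
                                 "dependency"))
  if (length(bad_stage) > 0) {
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  if ("cnv" %in% stages && !"expression" %in% stages) {
    stop("stage 'cnv' depends on stage 'expression'; enable both",
         call. = FALSE)
  }
  seed <- as.integer(config$seed %||% 1L)
  th <- utils::modifyList(rho_thresholds(), config$thresholds %||% list())
  inputs <- config$inputs
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  issues <- validate_inputs(inputs)
  if (any(issues$level == "error")) {
    stop("input validation failed: ", issues$input[issues$level ==
                                                     "error"][1], ": ",
         issues$message[issues$level == "error"][1], call. = FALSE)
  }
  catalog <- load_catalog(inputs$catalog)
  background <- readr::read_tsv(inputs$background_genes,
                                show_col_types = FALSE, progress = FALSE)
  results <- list()
  counts_log <- list()
  outputs <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(outdir, name)
    readr::write_tsv(tbl, path, progress = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  if ("mutation" %in% stages) {
    mutations <- read_mutations(inputs$mutations)
    filt <- filter_hypermutators(mutations,
                                 multiplier = th$hypermutator_multiplier)
    n_samples <- n_distinct(filt$retained$sample_id)
    message("mutation stage: ", nrow(mutations), " records in, ",
            nrow(filt$retained), " retained after removing ",
            sum(filt$report$hypermutator_flag), " hypermutated sample(s)")
    path_load <- gene_load(filt$retained, catalog$symbol,
                           n_samples = n_samples)
    bg_load <- gene_load(filt$retained, background$symbol,
                         n_samples = n_samples)
    ensemble <- sample_length_matched_lists(catalog, background,
                                            n_lists = th$n_lists,
                                            seed = seed)
    enr <- bind_rows(
      enrichment_test(path_load, ensemble, bg_load, "load"),
      enrichment_test(path_load, ensemble, bg_load, "prevalence")
    ) |> adjust_enrichment(fdr_cutoff = th$enrichment_fdr)
    results$burden_report <- filt$report
    results$gene_load <- path_load
    results$mutation_enrichment <- enr
    emit(filt$report, "burden_report.tsv")
    emit(path_load, "gene_load.tsv")
    emit(enr, "mutation_enrichment.tsv")
    counts_log$mutation <- c(records_in = nrow(mutations),
                             records_retained = nrow(filt$retained))
  }

  expr_norm <- NULL
  if ("expression" %in% stages) {
    counts <- read_matrix_tsv(inputs$counts)
    samples <- readr::read_tsv(inputs$samples, show_col_types = FALSE,
                               progress = FALSE)
    gc_lookup <- bind_rows(
      tibble(symbol = catalog$symbol, gc_fraction = catalog$gc_fraction),
      tibble(symbol = background$symbol,
             gc_fraction = background$gc_fraction)
    ) |> distinct(.data$symbol, .keep_all = TRUE)
    genes <- tibble(symbol = rownames(counts)) |>
      left_join(gc_lookup, by = "symbol")
    if (anyNA(genes$gc_fraction)) {
      stop("counts matrix contains gene(s) without GC annotation",
           call. = FALSE)
    }
    expr <- expression_matrix(counts, samples, genes)
    qc <- aaic_filter(expr, min_cor = th$aaic_min_cor)
    filtered <- low_expression_filter(qc$expr)
    message("expression stage: ", ncol(expr$counts), " samples in, ",
            sum(qc$report$removed), " removed by the correlation filter; ",
            length(attr(filtered, "genes_removed")),
            " low-expression gene(s) dropped")
    expr_norm <- filtered |>
      within_lane_gc_normalize() |>
      between_lane_normalize()
    de <- nb_differential_expression(expr_norm,
                                     lfc_cutoff = th$lfc_cutoff,
                                     fdr_cutoff = th$de_fdr)
    de_enr <- de_count_enrichment(de, catalog, background,
                                  n_lists = th$n_lists, seed = seed + 1L)
    results$qc_report <- qc$report
    results$de_results <- de
    results$de_enrichment <- de_enr
    emit(qc$report, "qc_report.tsv")
    emit(tidy(de), "de_results.tsv")
    emit(de_enr, "de_enrichment.tsv")
    counts_log$expression <- c(samples_in = ncol(expr$counts),
                               samples_retained = ncol(filtered$counts),
                               genes_tested = nrow(de))
  }

  if ("cnv" %in% stages) {
    cnv <- read_matrix_tsv(inputs$cnv)
    mode(cnv) <- "integer"
    assoc <- scnv_associations(cnv, expr_norm,
                               genes = intersect(rownames(cnv),
                                                 catalog$symbol),
                               prevalence_cutoff = th$scnv_prevalence)
    results$scnv_associations <- assoc
    emit(assoc, "scnv_associations.tsv")
    counts_log$cnv <- c(genes_integrated = n_distinct(assoc$gene))
    if (!is.null(inputs$drivers) && file.exists(inputs$drivers)) {
      drivers <- readLines(inputs$drivers)
      drivers <- drivers[nzchar(drivers)]
      if (length(drivers) > 0) {
        cooc <- bind_rows(
          cooccurrence_with_drivers(cnv,
                                    intersect(rownames(cnv),
                                              catalog$symbol),
                                    intersect(drivers, rownames(cnv)),
                                    depth = "deep", direction = "amp"),
          cooccurrence_with_drivers(cnv,
                                    intersect(rownames(cnv),
                                              catalog$symbol),
                                    intersect(drivers, rownames(cnv)),
                                    depth = "deep", direction = "del")
        )
        results$driver_cooccurrence <- cooc
        emit(cooc, "driver_cooccurrence.tsv")
      }
    }
  }

  if ("dependency" %in% stages) {
    dep <- read_dependency_csv(inputs$dependency_scores,
                               inputs$dependency_lineages)
    ess <- pan_cancer_essential(dep, threshold = th$chronos_threshold,
                                fraction = th$essential_fraction)
    vuln <- lineage_vulnerability(
      dep, diff_cutoff = th$vulnerability_median_diff,
      fdr_cutoff = th$vulnerability_fdr)
    message("dependency stage: ", n_distinct(dep$gene), " genes over ",
            n_distinct(dep$cell_line), " cell lines; ",
            sum(ess$pan_essential), " pan-essential")
    results$essentiality <- ess
    results$vulnerability <- vuln
    emit(ess, "essentiality.tsv")
    emit(vuln, "lineage_vulnerability.tsv")
    counts_log$dependency <- c(genes = n_distinct(dep$gene),
                               cell_lines = n_distinct(dep$cell_line))
  }

  manifest <- list(
    package = "rhopath",
    version = as.character(utils::packageVersion("rhopath")),
    seed = seed,
    stages = as.list(stages),
    thresholds = th,
    row_counts = purrr::map(counts_log, as.list),
    input_checksums = {
      f <- unlist(inputs)
      f <- f[file.exists(f)]
      as.list(stats::setNames(unname(tools::md5sum(f)), basename(f)))
    },
    output_checksums = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                               basename(outputs)))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
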