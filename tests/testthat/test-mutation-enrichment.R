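test_that("hypermutator rule removes only samples above 4.5x the cohort mean", {
  tbl <- burden_table(c(2, 2, 2, 2, 100))
  res <- filter_hypermutators(tbl)
  expect_equal(res$report$cohort_mean, rep(21.6, 5))
  expect_equal(sum(res$report$hypermutator_flag), 1)
  expect_equal(res$report$sample_id[res$report$hypermutator_flag], "S005")
  expect_equal(dplyr::n_distinct(res$retained$sample_id), 4)

  even <- filter_hypermutators(burden_table(c(5, 5, 5, 5)))
  expect_false(any(even$report$hypermutator_flag))
  expect_error(filter_hypermutators(burden_table(integer(0))), "no samples")
})

test_that("hypermutator flags are invariant to scaling every burden", {
  base <- c(3, 1, 8, 2, 40, 4)
  f1 <- filter_hypermutators(burden_table(base))$report
  f2 <- filter_hypermutators(burden_table(base * 7))$report
  expect_equal(f1$hypermutator_flag[order(f1$sample_id)],
               f2$hypermutator_flag[order(f2$sample_id)])
})

test_that("gene load counts protein-altering records; prevalence counts samples", {
  tbl <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s3", "s4"),
    cohort_id = "C01",
    gene = c("A", "A", "A", "A", "A", "B"),
    variant_class = c("missense", "missense", "missense", "missense",
                      "missense", "synonymous"),
    position = 1L
  )
  gl <- gene_load(tbl, c("A", "B", "C"), n_samples = 10)
  expect_equal(gl$load, c(5L, 0L, 0L))
  expect_equal(gl$prevalence, c(0.3, 0, 0))

  # brute-force oracle on a random table
  withr::with_seed(31, {
    rnd <- tibble::tibble(
      sample_id = sample(sprintf("s%02d", 1:12), 200, replace = TRUE),
      cohort_id = "C01",
      gene = sample(LETTERS[1:6], 200, replace = TRUE),
      variant_class = sample(c("synonymous", "missense", "truncating",
                               "other"), 200, replace = TRUE),
      position = 1L
    )
  })
  gl <- gene_load(rnd, LETTERS[1:6], n_samples = 12)
  for (g in LETTERS[1:6]) {
    sub <- rnd[rnd$gene == g & rnd$variant_class != "synonymous", ]
    expect_equal(gl$load[gl$gene == g], nrow(sub))
    expect_equal(gl$prevalence[gl$gene == g],
                 length(unique(sub$sample_id)) / 12)
  }
})

test_that("length-matched lists reproduce the pathway length histogram", {
  cat_tbl <- simulate_catalog(50, seed = 41)
  # disjoint background carrying the exact same length multiset, 5 copies
  bg <- tibble::tibble(
    symbol = sprintf("CP%04d", seq_len(5 * 50)),
    coding_length_bp = rep(cat_tbl$coding_length_bp, 5),
    gc_fraction = 0.5
  )
  ens <- sample_length_matched_lists(cat_tbl, bg, n_lists = 20, seed = 3)
  bin_of <- function(lens) {
    table(cut(log10(lens), breaks = ens$bin_edges, include.lowest = TRUE))
  }
  ref <- bin_of(cat_tbl$coding_length_bp)
  len_lookup <- setNames(bg$coding_length_bp, bg$symbol)
  for (l in seq_len(nrow(ens$lists))) {
    expect_equal(bin_of(len_lookup[ens$lists[l, ]]), ref)
    expect_equal(anyDuplicated(ens$lists[l, ]), 0L)
  }
  ens2 <- sample_length_matched_lists(cat_tbl, bg, n_lists = 20, seed = 3)
  expect_identical(ens$lists, ens2$lists)
})

test_that("insufficient background genes in a bin is a named error", {
  cat_tbl <- simulate_catalog(50, seed = 42)
  tiny_bg <- tibble::tibble(symbol = sprintf("B%02d", 1:30),
                            coding_length_bp = rep(100L, 30),
                            gc_fraction = 0.5)
  expect_error(sample_length_matched_lists(cat_tbl, tiny_bg, n_lists = 5,
                                           seed = 1),
               "bin")
})

test_that("pooled sampled lengths match the pathway length distribution", {
  cat_tbl <- simulate_catalog(100, seed = 43)
  bg <- simulate_gene_universe(4000, seed = 44)
  ens <- sample_length_matched_lists(cat_tbl, bg, n_lists = 50, seed = 4)
  len_lookup <- setNames(bg$coding_length_bp, bg$symbol)
  pooled <- as.numeric(len_lookup[as.vector(ens$lists)])
  ks <- suppressWarnings(
    ks.test(log10(cat_tbl$coding_length_bp), log10(pooled))$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("enrichment p equals the Poisson upper tail and z the standardization", {
  # constant background: every list totals 100
  bg_load <- tibble::tibble(gene = sprintf("B%03d", 1:200),
                            load = 1L, n_mutated_samples = 1L)
  lists <- t(replicate(50, sample(bg_load$gene, 100)))
  ens <- structure(list(lists = lists, bin_edges = NULL, bin_counts = NULL,
                        seed = 1L, list_size = 100L),
                   class = "rho_ensemble")
  obs300 <- tibble::tibble(gene = "PW", load = 300L,
                           n_mutated_samples = 300L)
  res <- enrichment_test(obs300, ens, bg_load, "load")
  oracle <- sum(dpois(300:10000, lambda = 100))
  expect_equal(res$p, oracle, tolerance = 1e-12)
  expect_equal(res$z, Inf) # sd 0, observed above the constant mean
  expect_equal(res$background_mean, 100)

  obs_eq <- tibble::tibble(gene = "PW", load = 100L,
                           n_mutated_samples = 100L)
  res_eq <- enrichment_test(obs_eq, ens, bg_load, "load")
  expect_equal(res_eq$z, 0)
  expect_gte(res_eq$p, 0.5)
})

test_that("ensemble statistics are exchangeable under list reordering", {
  cat_tbl <- simulate_catalog(30, seed = 51)
  bg <- simulate_gene_universe(600, seed = 52)
  cfg <- sim_config(seed = 53, n_samples = 50)
  ms <- simulate_mutations(cfg, cat_tbl, bg)
  ns <- dplyr::n_distinct(ms$mutations$sample_id)
  pl <- gene_load(ms$mutations, cat_tbl$symbol, n_samples = ns)
  bl <- gene_load(ms$mutations, bg$symbol, n_samples = ns)
  ens <- sample_length_matched_lists(cat_tbl, bg, n_lists = 40, seed = 5)
  r1 <- enrichment_test(pl, ens, bl, "load")
  ens$lists <- ens$lists[rev(seq_len(nrow(ens$lists))), ]
  r2 <- enrichment_test(pl, ens, bl, "load")
  expect_equal(r1$p, r2$p)
  expect_equal(r1$z, r2$z)
})

test_that("BH adjustment is applied across cohorts with fdr >= p", {
  res <- dplyr::bind_rows(
    tibble::tibble(cohort = "A", statistic_kind = "load", observed = 10,
                   background_mean = 5, background_sd = 1, z = 5,
                   p = 0.001, shapiro_w = NA, tier = "p<0.01"),
    tibble::tibble(cohort = "B", statistic_kind = "load", observed = 6,
                   background_mean = 5, background_sd = 1, z = 1,
                   p = 0.4, shapiro_w = NA, tier = "ns")
  )
  adj <- adjust_enrichment(res)
  expect_true(all(adj$fdr >= adj$p))
  expect_equal(adj$fdr, p.adjust(res$p, "BH"))
})

test_that("MAF-style headers map onto the four-class vocabulary", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "maf.tsv")
  readr::write_tsv(tibble::tibble(
    Tumor_Sample_Barcode = c("s1", "s1", "s2", "s3"),
    Hugo_Symbol = c("RHOA", "RAC1", "RHOA", "ECT2"),
    Variant_Classification = c("Missense_Mutation", "Silent",
                               "Nonsense_Mutation", "RNA")
  ), p)
  mut <- read_mutations(p, cohort = "BLCA")
  expect_equal(mut$variant_class,
               c("missense", "synonymous", "truncating", "other"))
  expect_equal(unique(mut$cohort_id), "BLCA")
})
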