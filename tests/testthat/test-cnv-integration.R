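test_that("genotype classing maps the five call levels and rejects others", {
  cnv <- matrix(c(-2L, -1L, 0L, 1L, 2L, 0L), nrow = 2,
                dimnames = list(c("G1", "G2"), c("s1", "s2", "s3")))
  g1 <- genotype_classify(cnv, "G1")
  expect_equal(g1$genotype, c("deep_del", "diploid", "deep_amp"))
  g2 <- genotype_classify(cnv, "G2")
  expect_equal(g2$genotype, c("shallow_del", "shallow_amp", "diploid"))

  withr::with_seed(91, {
    rnd <- matrix(sample(-2:2, 60, replace = TRUE), 6, 10,
                  dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  })
  map <- c(`-2` = "deep_del", `-1` = "shallow_del", `0` = "diploid",
           `1` = "shallow_amp", `2` = "deep_amp")
  for (g in rownames(rnd)) {
    expect_equal(genotype_classify(rnd, g)$genotype,
                 unname(map[as.character(rnd[g, ])]))
  }
  bad <- cnv; bad["G1", "s2"] <- 3L
  expect_error(genotype_classify(bad, "G1"), "G1.*s2")
})

test_that("prevalence is computed per alteration class with the strict 10% flag", {
  cnv <- matrix(0L, 2, 20, dimnames = list(c("A", "B"), paste0("s", 1:20)))
  cnv["A", 1:3] <- 2L   # 15% deep amp
  cnv["A", 4:5] <- -1L  # 10% shallow del: not > 10%
  prev <- scnv_prevalence(cnv)
  expect_true(prev$high_prevalence[prev$gene == "A" &
                                     prev$alteration_class == "deep_amp"])
  expect_false(prev$high_prevalence[prev$gene == "A" &
                                      prev$alteration_class == "shallow_del"])
  expect_equal(prev$prevalence[prev$gene == "A" &
                                 prev$alteration_class == "deep_amp"], 0.15)
})

test_that("one-sided Fisher p equals the hypergeometric tail sum", {
  hyper_tail <- function(n11, n10, n01, n00) {
    # P(X >= n11) for X ~ Hypergeom(row1 = n11+n10, row2 = n01+n00,
    # col1 draws = n11+n01)
    m <- n11 + n10; n <- n01 + n00; k <- n11 + n01
    sum(dhyper(n11:min(m, k), m, n, k))
  }
  p_pkg <- fisher.test(matrix(c(25, 5, 15, 55), 2),
                       alternative = "greater")$p.value
  expect_equal(p_pkg, hyper_tail(25, 5, 15, 55), tolerance = 1e-12)

  withr::with_seed(92, {
    for (i in 1:200) {
      tab <- rmultinom(1, 60, runif(4, 0.05, 0.5))
      p1 <- fisher.test(matrix(tab, 2), alternative = "greater")$p.value
      p2 <- hyper_tail(tab[1], tab[2], tab[3], tab[4])
      expect_equal(p1, p2, tolerance = 1e-12)
    }
  })
})

test_that("driver co-occurrence flags planted pairs and handles degeneracy", {
  withr::with_seed(93, {
    n <- 150
    shared <- runif(n) < 0.3
    cnv <- rbind(
      PW1 = ifelse(shared | runif(n) < 0.05, 2L, 0L),
      PW2 = ifelse(runif(n) < 0.2, 2L, 0L),
      PW3 = 0L,
      DRV = ifelse(shared | runif(n) < 0.05, 2L, 0L)
    )
    colnames(cnv) <- paste0("s", 1:n)
  })
  cooc <- cooccurrence_with_drivers(cnv, c("PW1", "PW2", "PW3"), "DRV",
                                    depth = "deep", direction = "amp")
  expect_true(cooc$linked[cooc$pathway_gene == "PW1"])
  expect_false(cooc$linked[cooc$pathway_gene == "PW2"])
  pw3 <- cooc[cooc$pathway_gene == "PW3", ]
  expect_equal(pw3$p, 1)
  expect_true(pw3$degenerate)
  expect_equal(cooc$adjusted_p, p.adjust(cooc$p, "BH"))
})

test_that("independent alterations are rarely called linked", {
  withr::with_seed(94, {
    hits <- 0L; tests <- 0L
    for (rep in 1:20) {
      n <- 120
      cnv <- rbind(
        matrix(ifelse(runif(5 * n) < 0.15, 2L, 0L), 5, n,
               dimnames = list(paste0("PW", 1:5), paste0("s", 1:n))),
        DRV = ifelse(runif(n) < 0.15, 2L, 0L)
      )
      cooc <- cooccurrence_with_drivers(cnv, paste0("PW", 1:5), "DRV",
                                        depth = "deep", direction = "amp")
      hits <- hits + sum(cooc$linked)
      tests <- tests + nrow(cooc)
    }
  })
  # one-sided test at adjusted 0.05 under independence
  expect_lte(hits / tests, 0.05 + 1.96 * sqrt(0.05 * 0.95 / tests))
})

test_that("SCN-vs-diploid contrast recovers dosage and flags untestable genes", {
  genes <- simulate_gene_universe(200, seed = 95)[, c("symbol", "gc_fraction")]
  cfg <- sim_config(seed = 96, n_samples = 80, nb_dispersion = 0.1,
                    cnv_dosage_log2fc_per_copy = 1,
                    cnv_class_probs = c(`-2` = 0.03, `-1` = 0.05,
                                        `0` = 0.72, `1` = 0.05, `2` = 0.15))
  ex <- simulate_expression(cfg, genes)
  cn <- simulate_cnv(cfg, ex$expression)
  g <- genes$symbol[1]
  res <- scn_vs_diploid_contrast(cn$cnv, cn$expression, g, "deep_amp")
  expect_true(res$testable)
  expect_lt(abs(res$log2fc_scn_vs_diploid - 2), 0.6) # dosage 1 x 2 copies

  all_dip <- matrix(0L, 1, 80, dimnames = list(g, colnames(cn$cnv)))
  res0 <- scn_vs_diploid_contrast(all_dip, cn$expression, g, "deep_amp")
  expect_false(res0$testable)
  expect_true(is.na(res0$log2fc_scn_vs_diploid))
})

test_that("concordance labels match a brute-force rule over the full grid", {
  oracle <- function(class, lfc_scn, fdr_scn, lfc_tn, fdr_tn) {
    sig_scn <- !is.na(lfc_scn) && abs(lfc_scn) > 1 && fdr_scn < 0.01
    sig_tn <- !is.na(lfc_tn) && abs(lfc_tn) > 1 && fdr_tn < 0.01
    amp <- class %in% c("deep_amp", "shallow_amp")
    if (sig_scn && sig_tn && amp && lfc_scn > 0 && lfc_tn > 0)
      return("reinforcing_up")
    if (sig_scn && sig_tn && !amp && lfc_scn < 0 && lfc_tn < 0)
      return("reinforcing_down")
    if (sig_scn && sig_tn && sign(lfc_scn) != sign(lfc_tn))
      return("opposing")
    "inert"
  }
  grid <- expand.grid(
    alteration_class = c("deep_amp", "shallow_amp", "deep_del",
                         "shallow_del"),
    log2fc_scn_vs_diploid = c(-1.5, -0.5, 0, 0.5, 1.5),
    fdr_scn = c(1e-4, 0.5),
    log2fc_tumor_vs_normal = c(-2, 0, 2),
    fdr_tn = c(1e-5, 0.5),
    stringsAsFactors = FALSE
  )
  out <- concordance_classify(tibble::as_tibble(grid))
  for (r in seq_len(nrow(out))) {
    expect_equal(out$concordance[r],
                 oracle(grid$alteration_class[r],
                        grid$log2fc_scn_vs_diploid[r], grid$fdr_scn[r],
                        grid$log2fc_tumor_vs_normal[r], grid$fdr_tn[r]))
  }
  # the deletion-reinforced case
  myh11 <- concordance_classify(tibble::tibble(
    alteration_class = "deep_del", log2fc_scn_vs_diploid = -1.5,
    fdr_scn = 1e-4, log2fc_tumor_vs_normal = -2, fdr_tn = 1e-5))
  expect_equal(myh11$concordance, "reinforcing_down")
})
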