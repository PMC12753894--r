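test_that("sample-correlation filter removes uncorrelated and degenerate samples", {
  withr::with_seed(71, {
    # shared gene-level structure makes real samples highly correlated
    mu <- rlnorm(100, log(50), 1.2)
    base <- matrix(rnbinom(100 * 20, mu = mu, size = 10), 100, 20)
    noise <- matrix(rnbinom(100, mu = sample(mu), size = 10), ncol = 1)
  })
  m <- cbind(base, noise)
  ex <- make_expr(m, condition = rep("tumor", 21))
  res <- aaic_filter(ex)
  expect_true(res$report$removed[21])
  expect_false(any(res$report$removed[1:20]))

  ident <- make_expr(cbind(1:10, 1:10, 1:10), condition = rep("tumor", 3))
  res2 <- aaic_filter(ident)
  expect_false(any(res2$report$removed))
  expect_equal(res2$report$mean_cor, rep(1, 3))

  const <- make_expr(cbind(1:10, 1:10, rep(5, 10)),
                     condition = rep("tumor", 3))
  res3 <- aaic_filter(const)
  expect_true(res3$report$removed[3]) # undefined correlation treated as 0
  expect_error(aaic_filter(make_expr(cbind(1:5, 1:5),
                                     condition = rep("tumor", 2))),
               "3 samples")
})

test_that("lowest-quartile filter uses the interpolated 25th percentile", {
  m <- matrix(rep(1:8, times = 4), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:4)))
  ex <- make_expr(m, condition = c("tumor", "tumor", "normal", "normal"))
  out <- low_expression_filter(ex)
  expect_setequal(attr(out, "genes_removed"), c("g1", "g2")) # P25 = 2.75
  expect_equal(nrow(out$counts), 6)

  flat <- make_expr(matrix(5, 6, 4),
                    condition = c("tumor", "tumor", "normal", "normal"))
  expect_equal(nrow(low_expression_filter(flat)$counts), 6)

  withr::with_seed(72, {
    rnd <- matrix(rpois(50 * 6, 30), 50, 6)
  })
  ex_r <- make_expr(rnd, condition = rep(c("tumor", "normal"), 3))
  out_r <- low_expression_filter(ex_r)
  means <- rowMeans(rnd)
  oracle <- rownames(ex_r$counts)[means >= quantile(means, 0.25, type = 7)]
  expect_setequal(out_r$genes$symbol, oracle)

  small <- make_expr(matrix(1:9, 3, 3), condition = rep("tumor", 3))
  expect_warning(low_expression_filter(small), "fewer than 4")
})

test_that("GC normalization removes a planted smooth trend", {
  genes <- simulate_gene_universe(400, seed = 73)[, c("symbol", "gc_fraction")]
  cfg <- sim_config(seed = 74, n_samples = 15, gc_bias_strength = 8)
  ex <- simulate_expression(cfg, genes)$expression
  # planted bias leaves strong per-sample GC correlations somewhere
  pre <- apply(log2(ex$counts + 1), 2, function(y)
    suppressWarnings(cor(y, ex$genes$gc_fraction, method = "spearman")))
  expect_gt(max(abs(pre)), 0.2)
  norm <- within_lane_gc_normalize(ex)
  post <- apply(log2(norm$counts + 1), 2, function(y)
    suppressWarnings(cor(y, norm$genes$gc_fraction, method = "spearman")))
  expect_lt(max(abs(post)), 0.1)
})

test_that("GC normalization is gene-permutation equivariant and guards degeneracy", {
  genes <- simulate_gene_universe(120, seed = 75)[, c("symbol", "gc_fraction")]
  cfg <- sim_config(seed = 76, n_samples = 5, gc_bias_strength = 1)
  ex <- simulate_expression(cfg, genes)$expression
  norm <- within_lane_gc_normalize(ex)
  perm <- withr::with_seed(77, sample(nrow(ex$counts)))
  ex_p <- expression_matrix(ex$counts[perm, ], ex$samples,
                            ex$genes[perm, ])
  norm_p <- within_lane_gc_normalize(ex_p)
  expect_equal(norm_p$counts, norm$counts[perm, ], tolerance = 1e-10)

  const_gc <- make_expr(matrix(rpois(40, 20), 10, 4), gc = rep(0.5, 10),
                        condition = rep(c("tumor", "normal"), 2))
  expect_warning(out <- within_lane_gc_normalize(const_gc), "constant GC")
  expect_identical(out$counts, const_gc$counts)
})

test_that("full-quantile normalization equalizes sample distributions", {
  # scalar-multiple samples collapse to identical columns
  x <- matrix(c(1, 4, 2, 8, 3, 12, 7, 28), nrow = 4, byrow = TRUE)
  ex <- make_expr(x, condition = c("tumor", "normal"))
  bn <- between_lane_normalize(ex)
  expect_equal(bn$counts[, 1], bn$counts[, 2])

  withr::with_seed(78, {
    r <- matrix(rnorm(60 * 5, 100, 15), 60, 5) # continuous: tie-free
  })
  ex_r <- make_expr(pmax(r, 0), condition = rep("tumor", 5))
  bn_r <- between_lane_normalize(ex_r)
  target <- rowMeans(apply(ex_r$counts, 2, sort))
  for (j in 1:5) {
    expect_equal(unname(sort(bn_r$counts[, j])), target, tolerance = 1e-12)
    expect_equal(rank(bn_r$counts[, j]), rank(ex_r$counts[, j]))
  }
  skip_if_not_installed("limma")
  expect_equal(unname(bn_r$counts),
               unname(limma::normalizeQuantiles(ex_r$counts)),
               tolerance = 1e-10)
})

test_that("quantile normalization gives tied values the mean of their span", {
  x <- cbind(c(1, 1, 1, 10), c(2, 4, 6, 8))
  ex <- make_expr(x, condition = c("tumor", "normal"))
  bn <- between_lane_normalize(ex)
  target <- rowMeans(apply(x, 2, sort))
  expect_equal(unname(bn$counts[1:3, 1]), rep(mean(target[1:3]), 3))
  expect_equal(unname(bn$counts[4, 1]), target[4])
})

test_that("NB test is exactly antisymmetric in the group labels", {
  withr::with_seed(79, {
    m <- matrix(rnbinom(200 * 12, mu = 80, size = 10), 200, 12)
  })
  ex <- make_expr(m, condition = rep(c("tumor", "normal"), each = 6))
  de <- nb_differential_expression(ex)
  ex_sw <- make_expr(m, condition = rep(c("normal", "tumor"), each = 6))
  de_sw <- nb_differential_expression(ex_sw)
  expect_equal(de$log2fc, -de_sw$log2fc)
  expect_equal(de$pvalue, de_sw$pvalue)

  # mirrored groups: fold-change identically zero
  mm <- cbind(m[, 1:6], m[, 1:6])
  ex_mm <- make_expr(mm, condition = rep(c("tumor", "normal"), each = 6))
  expect_true(all(nb_differential_expression(ex_mm)$log2fc == 0))
})

test_that("NB test recovers planted fold-changes at the stated thresholds", {
  planted <- sprintf("BG%05d", 1:40)
  cfg <- sim_config(seed = 80, n_samples = 20, nb_dispersion = 0.1,
                    planted_log2fc = setNames(rep(c(2, -2), 20), planted))
  genes <- simulate_gene_universe(400, seed = 81)[, c("symbol", "gc_fraction")]
  ex <- simulate_expression(cfg, genes)$expression
  de <- nb_differential_expression(ex)
  hit <- de$status[match(planted, de$gene)]
  expect_gte(mean(hit != "ns"), 0.9)
  called <- de$gene[de$status != "ns"]
  expect_lte(mean(!called %in% planted), 0.05)
  est <- de$log2fc[match(planted[seq(1, 40, 2)], de$gene)]
  expect_gte(mean(abs(est - 2) < 0.3), 0.9)
  expect_true(all(de$fdr >= de$pvalue))
  # FDR monotone in p
  ord <- order(de$pvalue)
  expect_true(all(diff(de$fdr[ord]) >= -1e-12))
})

test_that("DE-count enrichment matches its Poisson tail and finds planted excess", {
  cat_tbl <- simulate_catalog(40, seed = 82)
  bg <- simulate_gene_universe(800, seed = 83)
  no_de <- tibble::tibble(gene = c(cat_tbl$symbol, bg$symbol),
                          status = "ns")
  r0 <- de_count_enrichment(no_de, cat_tbl, bg, n_lists = 50, seed = 1)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p, 1)

  planted <- no_de
  planted$status[planted$gene %in% cat_tbl$symbol[1:15]] <- "up"
  r1 <- de_count_enrichment(planted, cat_tbl, bg, n_lists = 200, seed = 2)
  expect_equal(r1$observed, 15)
  expect_lt(r1$p, 0.001)
})

test_that("pan-cancer classes agree with an exhaustive rule oracle", {
  oracle <- function(n_up, n_down, n_tested) {
    breadth <- (n_up + n_down) / n_tested
    if (n_up + n_down == 0) return("none")
    if (n_up > n_down && breadth > 0.25) return("pan_up")
    if (n_down > n_up && breadth > 0.25) return("pan_down")
    if (n_up > 0 && n_down > 0) return("mixed")
    "restricted"
  }
  cases <- list()
  for (len in 1:6) {
    grid <- expand.grid(rep(list(c("up", "down", "ns")), len),
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      v <- unlist(grid[i, ], use.names = FALSE)
      cases[[length(cases) + 1]] <- tibble::tibble(
        gene = paste0("case", length(cases)),
        cohort = paste0("c", seq_len(len)), status = v)
    }
  }
  statuses <- dplyr::bind_rows(cases)
  prof <- pan_cancer_classify(statuses)
  for (r in seq_len(nrow(prof))) {
    expect_equal(prof$class[r],
                 oracle(prof$n_up[r], prof$n_down[r],
                        prof$n_cohorts_tested[r]),
                 info = paste("gene", prof$gene[r]))
  }
  # breadth tiers are strict
  wide <- pan_cancer_classify(tibble::tibble(
    gene = "ECT2", cohort = paste0("c", 1:20),
    status = c(rep("up", 11), rep("ns", 9))))
  expect_equal(wide$class, "pan_up")
  expect_equal(wide$tier, "gt50pct")
})

test_that("substrate tallies report percentages over the full list size", {
  profiles <- tibble::tibble(
    gene = c(sprintf("DN%02d", 1:12), sprintf("UP%02d", 1:11)),
    n_cohorts_tested = 20, n_up = c(rep(0, 12), rep(8, 11)),
    n_down = c(rep(8, 12), rep(0, 11)), breadth_fraction = 0.4,
    tier = "25to50pct", class = c(rep("pan_down", 12), rep("pan_up", 11))
  )
  cat_tbl <- as_catalog(tibble::tibble(
    symbol = profiles$gene,
    categories = rep(list("GAP"), 23),
    coding_length_bp = 1000L, gc_fraction = 0.5,
    substrate = c(rep("RHOA", 6), rep("RAC1", 1), rep("UNKNOWN", 5),
                  rep("RAC1", 4), rep("RHOA", 2), rep("UNKNOWN", 5))
  ))
  tally <- substrate_specificity_tally(profiles, cat_tbl)
  down_rhoa <- tally[tally$role == "GAP" & tally$direction == "pan_down" &
                       tally$substrate == "RHOA", ]
  expect_equal(down_rhoa$n, 6)
  expect_equal(down_rhoa$pct, 50) # 6 of the 12 downregulated GAPs
  up_rac1 <- tally[tally$role == "GAP" & tally$direction == "pan_up" &
                     tally$substrate == "RAC1", ]
  expect_equal(up_rac1$n, 4)
  expect_equal(up_rac1$pct, 36.4) # 4 of the 11 upregulated GAPs

  empty <- substrate_specificity_tally(profiles[0, ], cat_tbl)
  expect_true(all(empty$n == 0) && all(empty$pct == 0))
})
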