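Package: rhopath
Title: Pan-Cancer Multi-Omic Analysis of RHO GTPase Pathway Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a pan-cancer analysis
    pipeline for curated RHO GTPase pathway gene lists: mutation-burden
    enrichment against length-matched resampled gene backgrounds with
    Z-scores and Poisson tail tests, post-classification of positive
    selection and mutation-hotspot calls, negative-binomial differential
    expression with GC-content and full-quantile normalization and
    pan-cancer deregulation classing, copy-number to expression
    integration with driver co-occurrence testing, cross-cohort Spearman
    co-expression summaries, pre-ranked gene set enrichment with
    permutation-based normalized enrichment scores, and CRISPR dependency
    screen vulnerability statistics. Includes a seeded synthetic cohort
    generator with planted effects for parameter-recovery and calibration
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    generics,
    fgsea,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    e1071
Config/testthat/edition: 3
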