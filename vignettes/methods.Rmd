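---
title: "Statistical methods behind rhopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind rhopath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhopath)
```

`rhopath` profiles a curated list of RHO GTPase pathway genes — the
GTPases themselves, their GEF/GAP/GDI regulators, kinase effectors and
non-kinase signaling elements — across cancer cohorts along four axes:
somatic mutation burden, transcript deregulation, copy-number dosage,
and CRISPR knockout dependency. This vignette explains each model, the
parameters that matter, the numerical conventions, and what the
synthetic cohorts used by the test suite do and do not establish.

## Mutation burden against a length-matched resampling null

Longer genes accumulate more somatic mutations, so a pathway list's raw
burden cannot be compared against arbitrary gene sets. The null model
is built by resampling: pathway genes are binned by the deciles of
their log10 coding length, and each of `n_lists` (default 1,000) random
lists reproduces the pathway's per-bin counts exactly, drawing
background genes without replacement within a list and independently
across lists. Pathway genes are excluded from the background pool. The
binning rule (10 bins on pathway-list deciles, R type-7 quantiles) is a
package choice; any smooth matching of the length distribution would
serve, and a two-sample KS check in the test suite confirms the pooled
sampled lengths track the pathway lengths.

Two aggregate statistics are supported: total non-synonymous **load**
(missense + truncating + other; synonymous mutations are excluded by
default because the question concerns protein-altering burden, and the
selection analysis downstream treats synonymous events as neutral) and
**prevalence**, aggregated as the total count of mutated samples per
gene so that the fraction scale becomes an expected count. The observed
value is reported two ways: as a Z-score against the resampled mean and
standard deviation (an effect size), and as the upper-tail Poisson
probability P(X >= observed) with lambda set to the background mean.
Combining a Z-transformation with a Poisson test is redundant in
principle; the package resolves the ambiguity by keeping the Z-score
descriptive and deriving the p-value solely from the Poisson tail,
which is well defined for count aggregates and conservative for
overdispersed ones. A Shapiro–Wilk statistic on the background
distribution is attached as a diagnostic but never gates the test.
Benjamini–Hochberg adjustment across cohorts (significance at adjusted
p < 0.05) is applied by `adjust_enrichment()`.

Hypermutated samples — total burden strictly above 4.5x the cohort mean,
the mean computed once over all samples rather than iteratively — are
removed before any burden statistic. The rule is scale-invariant, which
the suite checks by multiplying all burdens by a constant.

## Positive selection and hotspot post-classification

The package does not estimate dN/dS or detect positional clusters; it
consumes the q-value and cluster tables such tools emit and contributes
the classification layer. A gene is under significant positive
selection at `qglobal < 0.01` (strict); `qmis` and `qtrunc` then split
calls into missense-selected, truncation-selected or both. A globally
significant gene with neither sub-signal significant is logically
possible but not classifiable; it is surfaced with a warning and
classed `none`. Hotspot summaries compute the fraction of a gene's
missense and truncating mutations inside clusters (0 when the class has
no mutations) and the fraction of cohort samples carrying at least one
in-cluster mutation, flagged at the strict > 30% and > 3% tiers.
Prevalence is computed per cohort; pooling across cohorts is left to
the caller, since the tiers are cohort-level claims.

## Expression: QC, normalization, and the NB Wald test

The expression pipeline runs in a fixed order: sample-correlation
filter, lowest-quartile gene filter, within-lane GC normalization,
between-lane full-quantile normalization, then the test. The
correlation filter computes each sample's mean Pearson correlation of
log2(count + 1) against all other samples and removes samples below
0.6 in a single pass; the mean (rather than minimum) pairwise
correlation is the package's reading of the usual array-correlation QC,
and an undefined correlation (constant profile) counts as 0 so a
degenerate sample is always removed. Gene filtering removes genes whose
mean count falls strictly below the interpolated 25th percentile of
gene means. GC normalization fits, per sample, a loess curve
(span 0.75, degree 2) of log2(count + 1) on gene GC fraction and
removes the fitted trend re-centred to preserve the sample's mean; the
contract, checked on simulations with a planted smooth GC trend, is a
post-normalization |Spearman| below 0.1 between log expression and GC.
Full-quantile normalization forces every sample onto the mean sorted
profile while preserving within-sample ranks; tied values receive the
mean of the quantile values their ranks span (this differs from
interpolation-at-average-rank implementations only at ties of three or
more, and the suite cross-checks the tie-free case against
`limma::normalizeQuantiles`).

The test itself is a from-scratch negative-binomial Wald test rather
than a port of any particular package's machinery: with variance
mu + alpha mu^2, gene-wise dispersions come from an adjusted
method-of-moments estimator pooled over the two groups, are floored,
and are shrunk toward a loess mean–dispersion trend by geometric
interpolation with weight 0.5 (configurable; 0 = raw, 1 = pure trend).
The log2 fold-change uses a pseudo-count of 0.5 for stability at low
counts, and its Wald statistic — standard error from the NB variance
model evaluated at the group means — is referred to a t distribution
with n1 + n2 - 2 degrees of freedom, which absorbs part of the
dispersion-estimation noise; null simulations at 20 + 20 samples and
dispersion 0.1 put the empirical type-I rate within the binomial
confidence band of the nominal level. Calls use the strict thresholds
|log2FC| > 1 and BH FDR < 0.01. Acceptance is by calibration and
recovery on planted effects, not numeric parity with any existing
implementation.

Pan-cancer classing aggregates per-cohort statuses per gene: breadth is
the DE fraction of tested cohorts, tiered strictly at > 50% and
25–50%; a gene is `pan_up`/`pan_down` when one direction strictly
dominates and breadth exceeds 0.25, `mixed` when both directions occur
without a breadth-qualified dominant one, `none` when never DE, and
`restricted` otherwise. The `restricted` class is deliberately a
catch-all for sub-breadth single-direction profiles (including the
boundary case of a gene DE in exactly a quarter of cohorts), so that
the five classes partition all profiles. Substrate tallies report
percentages against the full role-direction list size, keeping
regulators of unknown substrate in the denominator.

## Copy-number integration

Thresholded calls map directly onto genotypes (-2 deep deletion …
+2 deep amplification). Prevalence and contrasts are computed per
alteration class — deep and shallow, amplification and deletion,
separately — because dosage effects differ by depth; the high-prevalence
flag is strict at > 10% per class (a pooled definition would only
loosen it). The expression contrast compares altered versus diploid
samples with the same NB Wald test, run matrix-wide on the sample
subset so the dispersion trend is estimated from all genes, and BH is
applied across the tested gene-class pairs. The tumor-vs-normal axis of
the concordance plot is computed on samples diploid for the gene in
question versus normals, so the two axes are not mechanically coupled.
Concordance requires both contrasts significant (|log2FC| > 1,
FDR < 0.01) with signs matching the alteration direction; discordant
significant signs are `opposing`, everything else `inert`.

Driver co-occurrence encodes alteration status into binary vectors per
depth and direction and applies a one-sided (enrichment) Fisher exact
test per pathway-driver pair; the question is co-occurrence, so the
upper tail is the default, with the two-sided test available through
the `alternative` argument. Degenerate margins (a gene altered in no or
all samples) return p = 1 with a flag rather than an error. The driver
list is an input file, not a bundled database, to avoid pinning an
external resource version.

## Co-expression and pre-ranked GSEA

Spearman correlations use average ranks. For cohorts of at most 9
samples the p-value is exact — all n! rank permutations, robust to ties
— and above that the t approximation on n - 2 degrees of freedom is
used. Significance for the cross-cohort summary is BH FDR < 0.05
within a cohort; the threshold is a package decision (the tier figures
it feeds encode significance continuously) and is configurable.
Cross-cohort tiers are strict at > 25% and > 50% of tested cohorts,
with the dominant sign decided by majority among significant cohorts
and `mixed` on ties.

The GSEA enrichment score is the classic weighted Kolmogorov–Smirnov
running-sum extremum with weight exponent 1: hit increments
proportional to |score|, miss increments uniform. The null is
gene-label permutation — `n_perm` (default 10,000) uniform placements
of the set on the ranking — which is the standard pre-ranked
convention; NES divides ES by the mean |ES*| of same-sign permutations,
and the p-value is one-tailed with the +1 correction. FDR is BH on the
permutation p-values rather than an NES-histogram estimate: simpler,
calibrated, and monotone in p. Sets are intersected with the ranked
universe and kept between 5 (an unstated-but-necessary floor; smaller
sets make the permutation null degenerate) and 800 genes. The test
suite verifies the permutation p against exhaustive enumeration of all
placements on a 20-gene ranking and the ES = +/-1 extremes for
singleton sets at the top and bottom of the ranking.

## Dependency screens

A gene is pan-cancer essential when its score is strictly below -0.5 in
strictly more than 10% of lines. Lineage vulnerability compares each
lineage (minimum 3 lines, a floor chosen so a median is meaningful)
against all remaining lines: the median difference is the effect size,
and the p-value comes from Welch's unequal-variance two-sample test.
Welch is the default because lineage subgroups are small and
heteroscedastic; Student's pooled test is available by option. Flags
require |median difference| > 0.5 and BH FDR < 0.01 over all
gene-lineage tests, with the direction (sensitizing when the lineage
median is lower) reported separately so knockouts that increase
proliferation are visible. Constant scores on both sides with equal
medians give p = 1 by convention.

## The synthetic cohort generator

`sim_config()` fixes the study conditions: 200 tumor samples per
cohort, a 3,000-gene background universe with log-normal coding
lengths and beta-distributed GC, somatic rate 1e-6 mutations per
coding bp per sample, 2% hypermutated samples at 10x the rate,
negative-binomial counts (dispersion 0.1, log-normal baseline means),
thresholded copy-number calls with configurable class probabilities
and a dosage effect of 1 log2 unit per call unit, and a 220-line
dependency screen (11 lineages of 20) with scores Normal(0, 0.2),
pan-essential genes shifted by -1 and lineage-specific genes shifted by
the planted amount. Every planted effect is recorded in a ground-truth
sidecar so recovery tests never re-derive truth from the data. GC bias
enters as a per-sample "lane" coefficient in [-1, 1] multiplying a
smooth GC-centred trend on the log2 mean, giving the within-lane
normalization a real signal to remove; its default strength is 0 so
that bias, like fold-changes, is an effect the user plants explicitly.
Copy-number calls couple to expression by redrawing counts from the
stored generating means scaled by 2^(dosage x call), so a zero dosage
leaves expression untouched. All generators are seeded and
byte-deterministic.

What the generator does **not** emulate: mutational signatures and
trinucleotide context, linked copy-number segments, library-size
variation beyond the GC lane effect, correlated gene-gene expression
structure, batch effects, and single-cell sparsity. Passing recovery
and calibration tests on these cohorts therefore demonstrates that the
statistics are implemented correctly and behave as designed under
their assumed models — not that the pipeline is robust to every
artefact of real tumor data.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale, chosen to
keep a full run within a few minutes on one CPU while leaving the
binomial confidence bands meaningful: 200 replicate cohorts of 200
samples (484 pathway + 3,000 background genes, 1,000 resampled lists
each) for the null calibration of the burden test; 100 replicates for
its power at a two-fold excess; 50 replicates of 20 + 20 samples and
400 genes for DE recovery; 1,000 random 2x2 tables for the
Fisher/hypergeometric identity; all 15,504 placements of a 5-gene set
on a 20-gene ranking for GSEA exactness; three 100-sample dosage
simulations for copy-number concordance; and 30 null dependency
matrices for the vulnerability flag rate.

Other conventions worth knowing: percentile calculations use linear
interpolation (R quantile type 7); fold-changes use pseudo-count 0.5;
ties in `top_processes()` break by set name for determinism; z is
reported as signed infinity when the resampled background has zero
variance but the observed value differs from its mean; unknown genes
queried against a mutation table get load 0 rather than an error; and
the pipeline manifest records seed, thresholds, per-stage row counts
and MD5 checksums of all inputs and outputs, so byte-identical re-runs
are verifiable.

## Known limitations

The NB Wald test is approximate for very small groups (below ~5 per
arm) and, like all moment-based dispersion estimators, loses power for
genes with extreme dispersion; the within-lane step assumes the GC
trend is smooth and sample-specific; the co-occurrence test conditions
on margins and ignores tumor purity; and the dependency statistics
treat cell lines as exchangeable within a lineage. The package
deliberately does not implement dN/dS estimation, positional cluster
detection, segment-level copy-number calling, or gene-ontology
curation — those are consumed as inputs.
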