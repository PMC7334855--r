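---
title: "Models and methods behind tissuemark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tissuemark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuemark)
options(tissuemark.quiet = TRUE)
```

tissuemark connects three layers of evidence: regulatory annotation
(histone-mark peaks, possibly transferred from another genome), molecular
tissue specificity (histone signal, expression, promoter methylation), and
genotype–phenotype association (GWAS or selection-scan summary statistics).
This vignette describes each model, the tunable parameters, the synthetic
data that exercises them, and the numerical and design choices made where
the problem left them open.

## Interval transfer through alignment chains

A UCSC chain file describes colinear ungapped alignment blocks between a
source and a target assembly. `parse_chain()` expands the `size dt dq`
data lines into explicit blocks, converts negative-strand target
coordinates to the forward strand, and validates the header arithmetic
(block plus gap sums must match the header spans).

`map_interval()` intersects an interval with every chain's blocks and keeps
the chain with the most overlapped bases. The lift succeeds when that
chain covers at least `min_map_ratio` of the interval (default **0.5**) on
a single target chromosome and strand; the target is the minimal interval
spanning the mapped pieces. Two guards reject pathological lifts: a
spanning target longer than `max_span_factor` (default **2**) times the
source indicates a long target gap inside the peak, and bases scattered
over several chains with none dominant are reported `split_rejected`
rather than silently stitched. These acceptance rules are deliberate,
documented surrogates for a mapper whose exact BED acceptance policy is
not published; both knobs are arguments.

`transfer_efficiency()` is the *count* fraction of peaks that mapped. A
base-pair-weighted variant is available behind `bp_weighted = TRUE`;
both are computable because the two definitions genuinely differ when peak
lengths vary.

## From peaks to a features × samples matrix

Promoter windows run from `promoter_up` = **1000 bp** upstream to
`promoter_down` = **500 bp** downstream of the TSS (a 1.5 kb window). The
TSS of a `-` strand gene is its annotation end, and the window mirrors
accordingly. Gene-body windows are the annotated span, kept only for genes
of at least `min_gene_len` = **750 bp**.

"Signal intensity in a window" is not operationally defined in most peak
formats, so `aggregate_promoter_signal()` exposes three modes:

* `signal_fraction` (default): `signalValue x (overlap bp / peak length)` —
  the share of each peak's signal mass that falls inside the window;
* `occupancy`: the count of overlapping peaks;
* `signal_bp`: `signalValue x overlap bp`.

The default approximates per-base signal mass and keeps the worked
arithmetic transparent (a peak of length 200 and signal 10 overlapping
100 bp contributes 5.0). Note one consequence: only `signal_bp` is
invariant to splitting a peak into abutting halves; the default treats a
peak's signalValue as a per-peak quantity, which is how narrowPeak files
report it. Gene-body aggregation divides the `signal x overlap` sum by
gene length in kb, removing the length advantage of long genes.

Tissue labels come from sample metadata; the *exclusion class* of each
tissue (the broader grouping removed from the comparison group, e.g. an
immune–blood class containing B cells, T cells and thymus) is a
user-supplied two-column mapping, not hard-coded: tissue groupings are
data, and different atlases group differently.

## The tissue-specificity t-statistic

For each feature, signal across samples is fitted by ordinary least squares:

y = μ + X b (+ Z c) + e

with X = +1 for tested-tissue samples and −1 for the rest, after removing
same-class samples. The t-statistic b/se(b) measures specificity; with no
covariates it is algebraically the pooled two-sample t, which the tests
verify to 1e−10 against the closed form. Covariates (age, sex, study)
enter as reference-level dummies; the tissue t is invariant to the
reference choice. A factor that becomes constant within the retained
samples (a frequent side effect of exclusion) is dropped from the design;
genuinely collinear factors are an error naming the terms.

Numerical conventions:

* zero-residual-variance features return t = 0 rather than NaN, so
  degenerate features rank last and matrices stay dense;
* expression matrices are standardized per sample (each sample's gene
  vector to mean 0, sd 1) before fitting. Per-sample scaling removes
  library-size and composition scale while preserving the cross-gene
  contrasts that later correlation analyses rely on; a pooled per-tissue
  variant is available via `scope = "tissue"` because the choice is not
  forced by the model;
* methylation uses the coverage-weighted level Σ meth / Σ total over the
  CpGs of a window — a window with one covered read at one CpG should not
  count as much as ten deep CpGs — and inverted coding (−1 tested), so
  tissue-specific *hypo*methylation scores positive. Windows with no
  covered CpG in a sample are `NA` and are dropped pairwise per fit:
  zero-filling would assert complete unmethylation, a biological claim
  absence of coverage cannot support.

`select_top_fraction()` takes the ceiling of k × n features by descending
t (k = 3%, 5%, 10% are the conventional cutoffs; 5% the default), breaking
ties by feature id for determinism.

## Sum-based marker-set enrichment and the circular null

Given genome-ordered marker statistics and a region set, the observed
statistic is the sum of squared statistics over markers inside the set
(membership: 1-based position − 1 inside a half-open interval). Squaring
is the default summand because enrichment should be sign-agnostic;
absolute-value and identity summands are selectable.

The null rotates the whole statistic vector rigidly by a uniform offset in
{1, …, m−1}: rotation preserves the local correlation structure along the
genome, which is precisely what naive marker-label permutation destroys
and what this scheme is designed to respect. Per-chromosome independent
rotation is available as a flag. The empirical p uses the add-one rule
(#{null ≥ T} + 1)/(n_null + 1) — strictly positive and conservatively
valid. `exhaustive = TRUE` enumerates all m − 1 offsets; sampling uses
`n_perm` (default **10,000**) seeded draws, so results are bit-reproducible.

One caution when comparing the two modes: the exhaustive add-one p equals
(k+1)/m while the sampled p converges to k/(m−1), so the two differ by up
to ~1/m even with infinite permutations. Convergence checks therefore
compare exceedance fractions, which are exactly binomial.

Profiles assemble one test per trait × tissue cell as −log10 p, with
Benjamini–Hochberg q-values computed matrix-wide by default (matching the
one-heatmap-per-mark presentation; per-trait correction is a flag) and
cells below `fdr_alpha` = **0.05** starred. Empty marker sets give missing
cells, never p = 1. A selection-signature scan enters the same machinery
as a GWAS table whose `stat` column is the scan statistic.

## Concordance analyses

`modality_correlation()` correlates specificity t-vectors over shared
features for every tissue pair of two modalities; `trait_correlation()`
correlates −log10 p profiles over explicitly mapped tissue pairs. Both use
Pearson r with a two-sided p from the t-transform with n − 2 degrees of
freedom (the concrete test is stated because profile-correlation p-values
are often reported without one), BH over all cells, and pairwise-complete
observations with n recorded per cell. Perfectly collinear vectors are
assigned the smallest representable positive p so BH input stays in (0, 1].

`overlap_permutation_test()` re-places each query segment independently
and uniformly among all positions where it fits inside a workspace
interval, lengths preserved, and scores total bp of intersection with the
annotation. This is the simplest uniform sampler; composition-matched
(isochore-aware) placement is out of scope and noted as a limitation. For
a single segment, `exhaustive = TRUE` enumerates every placement and the
41/91 worked example in the tests is computed that way.

## What the synthetic data emulates — and what it does not

`simulation_spec()` freezes every distributional constant; generators are
pure functions of (spec, seed) via isolated RNG scopes, and all outputs
round-trip through the package readers.

* **Genome**: 2 chromosomes × 5 Mb; genes 1–5 kb, random strand, packed in
  8 kb slots so genes and promoter windows never overlap. Real genomes
  have overlapping and nested genes; the pipeline tolerates them but the
  planted ground truth is cleaner without.
* **Peaks**: every promoter carries a background peak with
  Lognormal(0, 0.5) signal (positive, right-skewed, like narrowPeak
  signalValues) and ±200 bp boundary jitter. Planted tissue-specific
  features (4% of genes per tissue, disjoint across tissues) have their
  signal multiplied so the expected shift is `effect_delta` = **3**
  within-group sds, using the lognormal moment closed form. Specificity is
  fitted on the raw scale, as is conventional for histone signal.
* **Tissues**: 10 tissues × 5 samples; the first two share an exclusion
  class to exercise same-class exclusion.
* **Expression**: gene baselines Normal(5, 2), unit residuals, a small
  per-study batch effect, and planted effects of the same delta. The
  expression-planted set overlaps the histone-planted set with co-planting
  probability w = rho / (f·tau² / (1 + f·tau²)), where f is the planted
  fraction and tau the planted t scale — the closed form linking overlap
  to expected t-correlation — so the realized cross-modality correlation
  targets `rho_modality` = **0.6**. With f = 0.04 the maximum attainable
  correlation is 0.62, which is why the planted fraction is 4%.
* **Methylation**: 10 CpGs per promoter, coverage Poisson(10) floored at
  one read, Beta(2, 8) levels in planted tissue promoters and Beta(8, 2)
  elsewhere.
* **GWAS**: 2000 evenly spaced markers; Normal(0, 1) statistics with mean
  `enrich_delta` = **2** inside planted regions. AR(1) local correlation
  (φ = 0.6) can be switched on to stress the circular null's purpose;
  default off for analytic transparency.

Passing tests on these data show the estimators do what they claim under
known ground truth. They do not show robustness to what the generator
omits: LD beyond AR(1), peak-calling artefacts, unbalanced sample sizes,
batch-confounded tissues, assembly errors in chains, or overlapping genes.

## Problem sizes and determinism

The test suite runs the statistical checks at the sizes stated in them:
1000 random partitions for the t equivalence; 200 random configurations
(m ≤ 500) for the rotation-null oracle with 10,000 sampled rotations each;
1000 null and 200 planted replicates (m = 2000, |set| = 100) for size and
power; 1000–2000 genes for recovery and cross-modality checks; 20
expression draws for the null-correlation check. These sizes give
comfortable Monte-Carlo margins for the bounds being asserted. All
randomness flows from explicit seeds; `run_pipeline()` writes a manifest
with md5 digests, and rerunning an identical configuration reproduces it
byte for byte.

## Known limitations

* The chain mapper targets desk-scale chains; it holds all blocks in
  memory and does not implement netting or reciprocal-best filtering,
  which are assumed done upstream.
* The enrichment test treats markers as exchangeable under rotation;
  strong long-range structure (e.g. assortative marker density) is only
  partially protected by rigid rotation.
* Replicate peak files for one tissue are treated as separate samples;
  merging policy is left to the caller.
* The overlap test's uniform sampler ignores sequence composition.
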