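# tissuemark

Comparative epigenomics toolkit for linking regulatory annotation to
genotype–phenotype association at the summary-data level. The package is
aimed at researchers who want to (i) borrow histone-mark annotation from a
well-annotated genome by transferring peak coordinates through pairwise
alignment chains, (ii) score tissue specificity of any molecular signal
(ChIP-seq histone intensity, RNA-seq expression, WGBS promoter
methylation), (iii) ask which tissues are relevant to a complex trait by
testing whether GWAS or selection-scan signal concentrates in
tissue-specific regions, and (iv) compare those tissue–trait association
profiles across data modalities, traits, or species.

## The statistics at the core

**Tissue-specificity t-statistic.** For each feature (gene promoter or gene
body), signal *y* across samples is modelled by ordinary least squares as

    y = μ + X b (+ Z c) + e

where *X* codes samples of the tested tissue as +1 and the comparison
samples as −1, and *Z* optionally carries categorical covariates (age, sex,
study). Tissue specificity is *t = b / se(b)*. Samples from the same
exclusion class as the tested tissue (e.g. T cells and thymus when testing
B cells) are removed from the comparison group. With no covariates this *t*
is algebraically the pooled two-sample t-statistic. For promoter
methylation the coding is inverted (−1 for the tested tissue) so that
tissue-specific *hypo*methylation scores positive. The top *k* = 3%, 5% or
10% of features by *t* define the tissue-specific set.

**Sum-based marker-set enrichment with a circular null.** For a trait with
genome-ordered marker statistics *s₁…s_m* and a region set containing
markers *S*, the observed statistic is T = Σ_{i∈S} s_i². The null rotates
the statistic vector rigidly around the genome circle: offset *k* gives
Σ_{i∈S} s²_{(i+k) mod m}. Rigid rotation preserves the local correlation of
statistics (the LD-like structure the permutation must respect). The
empirical p-value uses the add-one rule (#{null ≥ T} + 1)/(n_null + 1).
Benjamini–Hochberg q-values over the trait × tissue matrix mark significant
cells, and −log₁₀ p profiles are compared across traits or species by
Pearson correlation.

**Interval transfer.** UCSC chain files are parsed into ungapped alignment
blocks; an interval maps if a single chain covers ≥ 50% of its bases on one
target chromosome and strand (configurable), with the target taken as the
minimal spanning interval of the mapped pieces. Transfer efficiency is the
fraction of peaks that map.

All inputs can be generated by the synthetic-data module
(`simulation_spec()`, `generate_*()`), which plants known tissue-specific
features, GWAS enrichment, and cross-modality correlation, so every stage
is testable without external downloads.

## Worked example

Simulate a small multi-tissue study, score tissue specificity, and test a
GWAS trait planted in one tissue's specific regions:

```r
library(tissuemark)

spec  <- simulation_spec(seed = 42, n_genes = 300, chrom_len = 1.5e6,
                         n_tissues = 5, samples_per_tissue = 4,
                         n_markers = 3000)
genes <- generate_genome_annotation(spec)
pk    <- generate_peak_samples(spec, genes)
win   <- promoter_windows(genes)
sm    <- build_signal_matrix(pk$samples, win, "promoter",
                             class_map = pk$truth$class_map)
sm
#> <signal_matrix> 300 features x 20 samples (promoter, H3K4me3)
#> tissues: T01, T02, T03, T04, T05

R   <- specificity_matrix(sm)
top <- select_top_fraction(R, "T03", k = 0.05, win)
head(top, 3)
#> # A tibble: 3 × 6
#>   feature_id     t chrom  start    end strand
#>   <chr>      <dbl> <chr>  <int>  <int> <chr>
#> 1 g00223      7.53 chr2  707118 708618 +
#> 2 g00090      5.07 chr1  897923 899423 +
#> 3 g00220      4.38 chr2  685937 687437 -

gw   <- generate_gwas_summary(spec, list(trait_T03 = top[, c("chrom","start","end")]))
prof <- enrichment_profile(
  gw$gwas,
  purrr::map(purrr::set_names(unique(sm$samples$tissue)),
             ~ select_top_fraction(R, .x, 0.05, win)),
  cfg = run_config(seed = 42, n_perm = 2000))
dplyr::arrange(tibble::as_tibble(prof), p_emp)
#> # A tibble: 5 × 8
#>   trait     tissue T_obs n_set    p_emp neglog10p       q significant
#>   <chr>     <chr>  <dbl> <int>    <dbl>     <dbl>   <dbl> <lgl>
#> 1 trait_T03 T03     81.8    19 0.000500   3.30    0.00250 TRUE
#> 2 trait_T03 T04     31.8    23 0.0920     1.04    0.230   FALSE
#> 3 trait_T03 T01     13.8    21 0.868      0.0614  0.989   FALSE
#> 4 trait_T03 T02     14.4    22 0.872      0.0595  0.989   FALSE
#> 5 trait_T03 T05     10.0    22 0.989      0.00480 0.989   FALSE
```

The trait planted in T03's tissue-specific regions is the only significant
cell (q < 0.05): the marker statistics inside T03's top-5% promoter windows
sum to far more than any genome rotation, while the other tissues' region
sets show rotation-typical sums. `autoplot(prof)` draws the trait × tissue
heatmap with FDR stars; `run_pipeline()` chains the whole analysis
(simulate → liftover → aggregate → specificity → enrich → correlate) from
one YAML configuration, and `inst/exec/tissuemark` exposes it on the
command line.

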