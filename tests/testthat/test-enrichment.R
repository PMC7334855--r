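test_that("marker membership follows the half-open convention and set semantics", {
  g <- tiny_gwas(rep(0, 5), spacing = 50L)  # pos 50,100,...,250
  # region [99,200): marker pos 100 (0-based 99) in, pos 200 (0-based 199) in,
  # pos 250 out
  set <- build_marker_set(g, tibble::tibble(chrom = "chr1", start = 99L,
                                            end = 200L))
  expect_equal(set$indices, c(1L, 2L, 3L))
  # boundary: region [100, 200) excludes pos 100 (0-based 99)
  set2 <- build_marker_set(g, tibble::tibble(chrom = "chr1", start = 100L,
                                             end = 200L))
  expect_equal(set2$indices, c(2L, 3L))
  # overlapping regions count a marker once
  set3 <- build_marker_set(g, tibble::tibble(chrom = "chr1",
                                             start = c(99L, 90L),
                                             end = c(200L, 150L)))
  expect_equal(set3$indices, c(1L, 2L, 3L))
  # all markers
  set4 <- build_marker_set(g, tibble::tibble(chrom = "chr1", start = 0L,
                                             end = 300L))
  expect_equal(set4$n_set, 5L)
})

test_that("the sum statistic is the sum of squared statistics over the set", {
  g <- tiny_gwas(c(3, -1, 2))
  all_set <- build_marker_set(g, tibble::tibble(chrom = "chr1", start = 0L,
                                                end = 100L))
  expect_equal(sum_statistic(g$stat, all_set), 14)
  expect_equal(sum_statistic(rep(0, 3), all_set), 0)
  expect_equal(sum_statistic(g$stat, all_set, summand = "abs"), 6)
})

test_that("exhaustive rotation reproduces the hand enumeration", {
  g <- tiny_gwas(c(3, 1, 1, 1, 0))
  set <- build_marker_set(g, tibble::tibble(chrom = "chr1", start = 5L,
                                            end = 15L))
  expect_equal(set$indices, 0L)
  st <- circular_permutation_pvalue(g$stat, set, exhaustive = TRUE)
  expect_equal(st$T_obs, 9)
  expect_equal(sort(st$null_T), c(0, 1, 1, 1))
  expect_equal(st$p_emp, 0.2)
})

test_that("a set of all markers is rotation-invariant with p = 1", {
  g <- tiny_gwas(c(1, 2, 3))
  set <- build_marker_set(g, tibble::tibble(chrom = "chr1", start = 0L,
                                            end = 100L))
  expect_warning(st <- circular_permutation_pvalue(g$stat, set), "p = 1")
  expect_equal(st$p_emp, 1)
  # empty set is an upstream error
  empty <- build_marker_set(g, tibble::tibble(chrom = "chr1", start = 90L,
                                              end = 95L))
  expect_error(circular_permutation_pvalue(g$stat, empty), "empty")
})

test_that("exhaustive p equals a brute-force loop and sampling converges to it", {
  withr::with_seed(71, {
    for (rep in 1:25) {
      m <- sample(20:120, 1)
      stats <- rnorm(m)
      n_set <- sample(2:max(3, m %/% 10), 1)
      idx <- sort(sample(0:(m - 1), n_set))
      set <- structure(list(indices = idx, m = m, n_set = n_set),
                       class = "marker_set")
      ex <- circular_permutation_pvalue(stats, set, exhaustive = TRUE)
      expect_identical(ex$p_emp, brute_rotation_p(stats, idx, m))
      sam <- circular_permutation_pvalue(stats, set, n_perm = 4000, seed = rep)
      # binomial noise plus the add-one discretization gap (at most ~1/m)
      tol <- 4 * sqrt(ex$p_emp * (1 - ex$p_emp) / 4000) + 1 / m + 1e-3
      expect_lt(abs(sam$p_emp - ex$p_emp), tol)
    }
  })
})

test_that("identical seeds give bit-identical results; seeds differ otherwise", {
  withr::with_seed(81, stats <- rnorm(200))
  set <- structure(list(indices = c(3L, 50L, 120L), m = 200L, n_set = 3L),
                   class = "marker_set")
  a <- circular_permutation_pvalue(stats, set, n_perm = 500, seed = 42)
  b <- circular_permutation_pvalue(stats, set, n_perm = 500, seed = 42)
  expect_identical(a$null_T, b$null_T)
  expect_identical(a$p_emp, b$p_emp)
  c <- circular_permutation_pvalue(stats, set, n_perm = 500, seed = 43)
  expect_false(identical(a$null_T, c$null_T))
})

test_that("BH q-values match the hand-worked step-up and preserve order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.5, 0.5)), c(0.5, 0.5))
  # input order preserved
  expect_equal(bh_fdr(c(0.04, 0.01, 0.02)), c(0.04, 0.03, 0.03))
  expect_error(bh_fdr(c(0, 0.5)), "0, 1")
  expect_true(all(bh_fdr(c(0.3, NA, 0.6)) >= c(0.3, NA, 0.6), na.rm = TRUE))
})

test_that("the enrichment profile matrix carries -log10 p and FDR stars", {
  g <- tiny_gwas(c(3, 1, 1, 1, 0))
  cfg <- run_config(seed = 1, n_perm = 100)
  prof <- enrichment_profile(
    list(traitX = g),
    list(tisA = tibble::tibble(chrom = "chr1", start = 5L, end = 15L)),
    cfg = cfg, exhaustive = TRUE)
  expect_equal(prof$p_emp, 0.2)
  expect_equal(prof$neglog10p, -log10(0.2), tolerance = 1e-12)
  pm <- profile_matrix(prof)
  expect_equal(unname(pm["traitX", "tisA"]), -log10(0.2), tolerance = 1e-12)
  # empty marker set -> missing cell, not p = 1
  prof2 <- enrichment_profile(
    list(traitX = g),
    list(tisA = tibble::tibble(chrom = "chr1", start = 5L, end = 15L),
         tisB = tibble::tibble(chrom = "chr1", start = 60L, end = 70L)),
    cfg = cfg, exhaustive = TRUE)
  expect_true(is.na(prof2$p_emp[prof2$tissue == "tisB"]))
  # marker-order mismatch across traits is an error
  g2 <- tiny_gwas(c(1, 1, 1), spacing = 7L)
  expect_error(enrichment_profile(
    list(a = g, b = g2),
    list(tisA = tibble::tibble(chrom = "chr1", start = 5L, end = 15L)),
    cfg = cfg), "marker order")
})

test_that("a planted trait is the profile maximum over tissues", {
  spec <- simulation_spec(seed = 13, n_genes = 200, chrom_len = 1e6,
                          n_markers = 2000, n_tissues = 4)
  genes <- generate_genome_annotation(spec)
  win <- promoter_windows(genes)
  planted_sets <- tissuemark:::sim_planted_features(spec, genes)
  planted <- sim_class_map(spec)$tissue[1]
  truth_regions <- win[win$gene_id %in% planted_sets[[planted]], ]
  regions_by_tissue <- purrr::map(
    setNames(sim_class_map(spec)$tissue, sim_class_map(spec)$tissue),
    function(tt) win[win$gene_id %in% planted_sets[[tt]], ])
  gw <- generate_gwas_summary(spec, list(trait1 = truth_regions))
  prof <- enrichment_profile(gw$gwas, regions_by_tissue,
                             cfg = run_config(seed = 1, n_perm = 500))
  expect_equal(prof$tissue[which.max(prof$neglog10p)], planted)
})

test_that("per-chromosome rotation keeps the seed-determinism contract", {
  withr::with_seed(91, stats <- rnorm(100))
  set <- structure(list(indices = c(5L, 60L), m = 100L, n_set = 2L),
                   class = "marker_set")
  a <- circular_permutation_pvalue(stats, set, n_perm = 200, seed = 7,
                                   per_chromosome = c(50L, 50L))
  b <- circular_permutation_pvalue(stats, set, n_perm = 200, seed = 7,
                                   per_chromosome = c(50L, 50L))
  expect_identical(a$null_T, b$null_T)
})
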