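make_spec_result <- function(t_matrix) {
  tibble::tibble(
    feature_id = rep(rownames(t_matrix), times = ncol(t_matrix)),
    tissue = rep(colnames(t_matrix), each = nrow(t_matrix)),
    b = 0, se = 1, t = as.vector(t_matrix), n_used = 10L
  )
}

test_that("self-correlation of a specificity result has an exact unit diagonal", {
  withr::with_seed(7, {
    tm <- matrix(rnorm(60), 20, 3,
                 dimnames = list(sprintf("g%02d", 1:20), c("a", "b", "c")))
  })
  A <- make_spec_result(tm)
  cm <- modality_correlation(A, A, q_star = 0.05)
  diag_cells <- cm[cm$tissue_a == cm$tissue_b, ]
  expect_equal(diag_cells$r, rep(1, 3))
  expect_true(all(diag_cells$significant))
  expect_error(modality_correlation(A[1:2, ], A[1:2, ]), "3 shared")
})

test_that("Pearson r and t-transform p match the stats:: oracle", {
  withr::with_seed(17, {
    x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  })
  cell <- tissuemark:::pearson_cell(x, y)
  ct <- cor.test(x, y)
  expect_equal(cell$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cell$p, ct$p.value, tolerance = 1e-12)
  # direct covariance/variance oracle
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cell$r, r_manual, tolerance = 1e-12)
})

test_that("planted cross-modality correlation is recovered on the diagonal", {
  withr::with_seed(27, {
    n <- 2000
    shared <- matrix(rnorm(n * 2), n, 2)
    ta <- sqrt(0.6) * shared + sqrt(0.4) * matrix(rnorm(n * 2), n, 2)
    tb <- sqrt(0.6) * shared + sqrt(0.4) * matrix(rnorm(n * 2), n, 2)
    dimnames(ta) <- dimnames(tb) <- list(sprintf("g%04d", 1:n), c("t1", "t2"))
  })
  cm <- modality_correlation(make_spec_result(ta), make_spec_result(tb))
  diag_r <- cm$r[cm$tissue_a == cm$tissue_b]
  expect_true(all(abs(diag_r - 0.6) < 0.1))
})

test_that("independent modalities produce no significant star in most seeds", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      ta <- matrix(rnorm(500 * 3), 500, 3,
                   dimnames = list(sprintf("g%03d", 1:500), c("x", "y", "z")))
      tb <- matrix(rnorm(500 * 3), 500, 3,
                   dimnames = list(sprintf("g%03d", 1:500), c("x", "y", "z")))
    })
    any(modality_correlation(make_spec_result(ta),
                             make_spec_result(tb))$significant)
  }, logical(1))
  expect_lte(sum(hits), 1)
})

test_that("trait profile correlations handle identity, opposition and mapping", {
  mk_profile <- function(vals, traits, tissues) {
    df <- tidyr::expand_grid(trait = traits, tissue = tissues)
    df$p_emp <- 10^(-vals)
    df$T_obs <- 1; df$n_set <- 5L
    df$neglog10p <- vals
    df$q <- bh_fdr(df$p_emp)
    df$significant <- df$q < 0.05
    class(df) <- c("enrichment_profile", class(df))
    df
  }
  P <- mk_profile(c(1, 0, 1, 0), "tA", c("w", "x", "y", "z"))
  Q <- mk_profile(c(0, 1, 0, 1), "tB", c("w", "x", "y", "z"))
  cm <- trait_correlation(P, Q)
  expect_equal(cm$r, -1)
  self <- trait_correlation(P, P)
  expect_equal(self$r, 1)
  # symmetric when P = Q with several traits
  P2 <- mk_profile(c(1, 0, 2, 0.5, 3, 1, 0.2, 2.5), c("t1", "t2"),
                   c("w", "x", "y", "z"))
  cm2 <- trait_correlation(P2, P2)
  r_ij <- cm2$r[cm2$trait_p == "t1" & cm2$trait_q == "t2"]
  r_ji <- cm2$r[cm2$trait_p == "t2" & cm2$trait_q == "t1"]
  expect_equal(r_ij, r_ji)
  # unmapped labels are an error listing them
  expect_error(trait_correlation(P, Q, tibble::tibble(tissue_p = "nope",
                                                      tissue_q = "w")),
               "nope")
})

test_that("overlap test matches the exhaustive placement enumeration", {
  q <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
  a <- tibble::tibble(chrom = "chr1", start = 0L, end = 50L)
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  ex <- overlap_permutation_test(q, a, w, exhaustive = TRUE)
  expect_equal(ex$observed_bp, 10)
  expect_equal(ex$p_emp, 41 / 91)
  # sampled mode approximates the enumeration
  sam <- overlap_permutation_test(q, a, w, n_perm = 4000, seed = 3)
  expect_lt(abs(sam$p_emp - 41 / 91), 0.05)
})

test_that("degenerate overlap situations give p = 1", {
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  q <- tibble::tibble(chrom = "chr1", start = 10L, end = 20L)
  # annotation covering the whole workspace
  full <- overlap_permutation_test(q, w, w, n_perm = 200, seed = 1)
  expect_equal(full$p_emp, 1)
  # zero observed overlap
  a <- tibble::tibble(chrom = "chr1", start = 50L, end = 60L)
  q0 <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
  z <- overlap_permutation_test(q0, a, w, n_perm = 200, seed = 1)
  expect_equal(z$p_emp, 1)
  # segment longer than every workspace interval
  expect_error(overlap_permutation_test(
    tibble::tibble(chrom = "chr1", start = 0L, end = 200L), a, w), "longer")
})

test_that("overlap test is bit-reproducible at a fixed seed", {
  withr::with_seed(37, {
    q <- tibble::tibble(chrom = "chr1", start = sort(sample.int(900, 5)),
                        end = 0L)
    q$end <- q$start + 20L
  })
  a <- tibble::tibble(chrom = "chr1", start = c(100L, 500L),
                      end = c(200L, 650L))
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  r1 <- overlap_permutation_test(q, a, w, n_perm = 500, seed = 99)
  r2 <- overlap_permutation_test(q, a, w, n_perm = 500, seed = 99)
  expect_identical(r1$null_bp, r2$null_bp)
  expect_identical(r1$p_emp, r2$p_emp)
})

test_that("overlap-test p is uniform on its grid under a random query", {
  # one 10 bp query placed at random in the workspace; p against a fixed
  # annotation should be roughly uniform over replicates
  a <- tibble::tibble(chrom = "chr1", start = 0L, end = 300L)
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  ps <- withr::with_seed(47, {
    vapply(1:200, function(i) {
      s <- sample.int(990, 1) - 1L
      q <- tibble::tibble(chrom = "chr1", start = s, end = s + 10L)
      overlap_permutation_test(q, a, w, exhaustive = TRUE)$p_emp
    }, numeric(1))
  })
  expect_gt(mean(ps < 0.31), 0.2)
  expect_lt(mean(ps < 0.31), 0.45)
})
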