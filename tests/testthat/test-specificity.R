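test_that("the +/-1-coded OLS t equals the pooled two-sample t", {
  f <- fit_specificity_model(c(4, 5, 6, 1, 2, 3),
                             tested = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(f$b, 1.5)
  expect_equal(f$t, 3 / sqrt(2 / 3), tolerance = 1e-10)
  # symmetric means give b = 0, t = 0
  f0 <- fit_specificity_model(c(1, 3, 2, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(f0$b, 0)
  expect_equal(f0$t, 0)
  # constant y: degenerate rule
  fc <- fit_specificity_model(rep(2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fc$t, 0)
})

test_that("OLS t matches the closed-form pooled t over random inputs", {
  withr::with_seed(101, {
    for (rep in 1:300) {
      n <- sample(6:30, 1)
      n1 <- sample(2:(n - 3), 1)
      tested <- sample(rep(c(TRUE, FALSE), c(n1, n - n1)))
      y <- rnorm(n, sd = runif(1, 0.5, 3))
      f <- fit_specificity_model(y, tested)
      expect_equal(f$t, pooled_t_oracle(y, tested), tolerance = 1e-10)
    }
  })
})

test_that("inverting the coding negates b and t exactly", {
  withr::with_seed(5, {
    y <- rnorm(12)
    tested <- rep(c(TRUE, FALSE), c(4, 8))
  })
  fs <- fit_specificity_model(y, tested, coding = "standard")
  fi <- fit_specificity_model(y, tested, coding = "inverted")
  expect_identical(fi$b, -fs$b)
  expect_identical(fi$t, -fs$t)
})

test_that("degenerate partitions and rank-deficient designs are errors", {
  expect_error(fit_specificity_model(1:4, rep(TRUE, 4)), "nonempty")
  cov_bad <- data.frame(batch = c("a", "a", "b", "b", "b", "b"),
                        dup = c("a", "a", "b", "b", "b", "b"))
  expect_error(
    fit_specificity_model(rnorm(6), rep(c(TRUE, FALSE), c(2, 4)),
                          covariates = cov_bad),
    "collinear")
})

test_that("covariate adjustment recovers the tissue effect under batch shifts", {
  withr::with_seed(21, {
    tested <- rep(c(TRUE, FALSE), c(5, 15))
    batch <- sample(c("A", "B"), 20, replace = TRUE)
    y <- 2 * ifelse(tested, 1, -1) + 3 * (batch == "B") + rnorm(20, sd = 0.5)
  })
  f_adj <- fit_specificity_model(y, tested, covariates = data.frame(batch))
  lm_fit <- lm(y ~ code + batch,
               data = data.frame(y, code = ifelse(tested, 1, -1), batch))
  expect_equal(f_adj$b, unname(coef(lm_fit)["code"]), tolerance = 1e-10)
  expect_equal(f_adj$t,
               unname(summary(lm_fit)$coefficients["code", "t value"]),
               tolerance = 1e-10)
})

test_that("same-class exclusion removes confounded samples and restores t", {
  # 3 tissues; B and C share a class. Testing B should drop C's samples.
  meta <- tibble::tibble(
    sample_id = sprintf("s%d", 1:9),
    tissue = rep(c("A", "B", "C"), each = 3),
    class = rep(c("A", "immune", "immune"), each = 3)
  )
  withr::with_seed(31, {
    vals <- matrix(rnorm(18), 2, 9,
                   dimnames = list(c("f1", "f2"), meta$sample_id))
  })
  M <- signal_matrix(vals, meta)
  R <- specificity_matrix(M, class_exclusion = TRUE)
  expect_equal(unique(R$n_used[R$tissue == "B"]), 6L)  # A(3) + B(3)
  expect_equal(unique(R$n_used[R$tissue == "A"]), 9L)  # own class only
  # oracle: manual fit on the reduced sample set
  keep <- meta$tissue %in% c("A", "B")
  f <- fit_specificity_model(vals["f1", keep], meta$tissue[keep] == "B")
  expect_equal(R$t[R$tissue == "B" & R$feature_id == "f1"], f$t,
               tolerance = 1e-12)
  # exclusion monotonicity: adding a same-class confounded sample and then
  # excluding it reproduces the original t exactly
  R_off <- specificity_matrix(M, class_exclusion = FALSE)
  expect_false(isTRUE(all.equal(R$t[R$tissue == "B"],
                                R_off$t[R_off$tissue == "B"])))
})

test_that("the vectorized matrix path agrees with per-feature fits", {
  meta <- tibble::tibble(sample_id = sprintf("s%d", 1:10),
                         tissue = rep(c("X", "Y"), each = 5))
  withr::with_seed(41, {
    vals <- matrix(rnorm(50), 5, 10,
                   dimnames = list(sprintf("f%d", 1:5), meta$sample_id))
  })
  M <- signal_matrix(vals, meta)
  R <- specificity_matrix(M)
  for (i in 1:5) {
    f <- fit_specificity_model(vals[i, ], meta$tissue == "X")
    expect_equal(R$t[R$tissue == "X" & R$feature_id == rownames(vals)[i]],
                 f$t, tolerance = 1e-12)
  }
})

test_that("a feature planted in one tissue has its maximal t there", {
  meta <- tibble::tibble(sample_id = sprintf("s%d", 1:15),
                         tissue = rep(c("A", "B", "C"), each = 5))
  withr::with_seed(51, {
    vals <- matrix(rnorm(45), 3, 15,
                   dimnames = list(c("g1", "g2", "g3"), meta$sample_id))
  })
  vals["g2", meta$tissue == "B"] <- vals["g2", meta$tissue == "B"] + 4
  R <- specificity_matrix(signal_matrix(vals, meta))
  g2 <- R[R$feature_id == "g2", ]
  expect_equal(g2$tissue[which.max(g2$t)], "B")
})

test_that("expression standardization gives each sample mean 0 and sd 1", {
  E <- cbind(s1 = c(1, 2, 3), s2 = c(10, 30, 20))
  rownames(E) <- c("g1", "g2", "g3")
  sm <- standardize_expression(E, tibble::tibble(sample_id = c("s1", "s2"),
                                                 tissue = c("a", "b")))
  expect_equal(unname(sm$values[, "s1"]), c(-1, 0, 1))
  expect_equal(colMeans(sm$values), c(s1 = 0, s2 = 0))
  expect_equal(apply(sm$values, 2, sd), c(s1 = 1, s2 = 1))
  # idempotence
  sm2 <- standardize_expression(sm)
  expect_equal(sm2$values, sm$values)
  # constant column rejected
  expect_error(standardize_expression(
    cbind(s1 = c(1, 1, 1)), tibble::tibble(sample_id = "s1", tissue = "a")),
    "zero-variance")
})

test_that("weighted methylation is coverage-weighted, not a CpG mean", {
  expect_equal(weighted_methylation(c(3, 7), c(10, 10)), 0.5)
  expect_equal(weighted_methylation(c(1, 0), c(1, 9)), 0.1)
  expect_equal(weighted_methylation(5, 5), 1.0)
  expect_true(is.na(weighted_methylation(integer(0), integer(0))))
  expect_true(is.na(weighted_methylation(0, 0)))
})

test_that("methylation specificity uses inverted coding (hypomethylation positive)", {
  meta <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
                         tissue = rep(c("liver", "other"), c(2, 6)))
  withr::with_seed(61, {
    vals <- matrix(rbeta(16, 8, 2), 2, 8,
                   dimnames = list(c("g1", "g2"), meta$sample_id))
  })
  vals["g1", meta$tissue == "liver"] <- c(0.08, 0.12)
  M <- signal_matrix(vals, meta, mark = "WGBS")
  R <- methylation_specificity(M, tissues = "liver")
  expect_gt(R$t[R$feature_id == "g1"], 2)
  # antisymmetry with the standard coding
  Rs <- specificity_matrix(M, coding = "standard", tissues = "liver")
  expect_equal(R$t, -Rs$t, tolerance = 1e-12)
  # uniform methylation -> t near 0 relative to the planted feature
  expect_lt(abs(R$t[R$feature_id == "g2"]), abs(R$t[R$feature_id == "g1"]))
})

test_that("methylation windows without CpG coverage are dropped pairwise", {
  genes <- tiny_genes()
  win <- promoter_windows(genes)
  cpgs <- tibble::tibble(
    chrom = "chr1",
    pos = c(4500L, 4600L, 27600L),
    meth_reads = c(1L, 0L, 9L), total_reads = c(1L, 9L, 10L),
    sample_id = c("w1", "w1", "w1"), tissue = "liver"
  )
  M <- build_methylation_matrix(cpgs, win)
  expect_equal(M$values["gA", "w1"], 0.1)  # (1+0)/(1+9)
  expect_equal(M$values["gB", "w1"], 0.9)
  expect_true(is.na(M$values["gC", "w1"]))
})

test_that("top-fraction selection uses ceil(k n) with id tie-breaking", {
  R <- tibble::tibble(feature_id = c("f1", "f2", "f3", "f4"),
                      tissue = "A", b = 0, se = 1,
                      t = c(3.1, 2.0, -1.0, 0.5), n_used = 10L)
  win <- tibble::tibble(gene_id = paste0("f", 1:4), chrom = "chr1",
                        start = 1:4 * 100L, end = 1:4 * 100L + 50L,
                        strand = "+", kind = "promoter")
  top <- select_top_fraction(R, "A", 0.5, win)
  expect_equal(top$feature_id, c("f1", "f2"))
  expect_equal(top$start, c(100L, 200L))
  expect_equal(nrow(select_top_fraction(R, "A", 1.0, win)), 4)
  # ties resolved by id order
  R2 <- dplyr::mutate(R, t = c(1, 1, 0, 0))
  expect_equal(select_top_fraction(R2, "A", 0.25, win)$feature_id, "f1")
  expect_error(select_top_fraction(R, "A", 0.1, win), "selects none")
})
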