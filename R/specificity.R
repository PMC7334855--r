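#' Tissue-specificity linear model for one feature
#'
#' Fits, by ordinary least squares, `y = mu + x b (+ covariates) + e` where
#' `x` codes the tested group as +1 and the comparison group as -1
#' (`coding = "standard"`). The t-statistic `t = b / se(b)` measures tissue
#' specificity of the feature. With no covariates this t is algebraically the
#' pooled equal-variance two-sample t between the groups. For signals where
#' specificity means a *low* value (promoter methylation),
#' `coding = "inverted"` assigns -1 to the tested group so that specific
#' hypomethylation yields a positive t; this exactly negates `b` and `t`.
#'
#' Features with zero residual variance return `t = 0` (degenerate-fit
#' convention: such features rank last rather than producing `NaN`).
#'
#' @param y numeric signal vector over the samples used in the fit
#'   (same-class exclusion is applied by the caller, see
#'   [specificity_matrix()]).
#' @param tested logical vector: `TRUE` for samples of the tested tissue.
#' @param coding `"standard"` (+1 tested) or `"inverted"` (-1 tested).
#' @param covariates optional data frame of categorical covariates (age,
#'   sex, study, ...) aligned to `y`; entered as reference-level dummies.
#' @return An object of class `specificity_fit` with elements `b`, `se`,
#'   `t`, `n_used`, `df`, `coding`. [tidy()] and [glance()] methods exist.
#' @export
#' @examples
#' f <- fit_specificity_model(c(4, 5, 6, 1, 2, 3),
#'                            tested = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' f$t  # pooled two-sample t, about 3.674
fit_specificity_model <- function(y, tested,
                                  coding = c("standard", "inverted"),
                                  covariates = NULL) {
  coding <- match.arg(coding)
  stopifnot(length(tested) == length(y))
  if (all(tested) || !any(tested)) {
    abort("tested and comparison groups must both be nonempty")
  }
  if (length(y) < 3) abort("need at least 3 samples")
  X <- specificity_design(tested, coding, covariates, length(y))
  fit <- ols_multi(X, matrix(y, ncol = 1))
  structure(
    list(b = fit$b[1], se = fit$se[1], t = fit$t[1],
         n_used = length(y), df = fit$df, coding = coding),
    class = "specificity_fit"
  )
}

# design matrix: intercept, +/-1 tissue code, covariate dummies
specificity_design <- function(tested, coding, covariates, n) {
  code <- ifelse(tested, 1, -1)
  if (coding == "inverted") code <- -code
  X <- cbind(`(Intercept)` = 1, tissue = code)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    covariates[] <- lapply(covariates, function(col) {
      if (is.character(col) || is.factor(col)) factor(col) else col
    })
    # a factor constant within the retained samples carries no information
    # (a frequent side effect of same-class exclusion); drop it
    keep <- vapply(covariates, function(col) length(unique(col)) > 1,
                   logical(1))
    covariates <- covariates[, keep, drop = FALSE]
    if (ncol(covariates) > 0) {
      Z <- stats::model.matrix(~., data = covariates)[, -1, drop = FALSE]
      X <- cbind(X, Z)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1, ncol(X))]]
    abort(paste0("design is rank-deficient; collinear terms: ",
                 paste(dropped, collapse = ", ")))
  }
  X
}

# multi-response OLS returning per-response b, se, t for the tissue column.
# Y: n x F. Zero-residual-variance responses get t = 0.
ols_multi <- function(X, Y) {
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  if (df < 1) abort("no residual degrees of freedom")
  xtx_inv <- chol2inv(chol(crossprod(X)))
  coefs <- xtx_inv %*% crossprod(X, Y)
  resid <- Y - X %*% coefs
  rss <- colSums(resid^2)
  scale <- pmax(colSums(Y^2), 1)
  degenerate <- rss <= 1e-12 * scale
  s2 <- rss / df
  se <- sqrt(s2 * xtx_inv[2, 2])
  b <- coefs[2, ]
  t <- ifelse(degenerate | se == 0, 0, b / se)
  list(b = b, se = se, t = t, df = df)
}

#' @export
print.specificity_fit <- function(x, ...) {
  cat(sprintf("<specificity_fit> b = %.4g, se = %.4g, t = %.4g (n = %d, %s coding)\n",
              x$b, x$se, x$t, x$n_used, x$coding))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.specificity_fit <- function(x, ...) {
  tibble::tibble(term = "tissue", estimate = x$b, std.error = x$se,
                 statistic = x$t,
                 p.value = 2 * pt(-abs(x$t), df = x$df))
}

#' @export
glance.specificity_fit <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, df.residual = x$df, coding = x$coding)
}

#' Tissue-specificity t-statistics for every feature and tissue
#'
#' For each tissue in turn, samples whose exclusion class matches the tested
#' tissue's class — other than the tested samples themselves — are removed,
#' and the +/-1-coded model of [fit_specificity_model()] is fitted to every
#' feature at once. Removing same-class samples (e.g. T cells and thymus
#' when testing B cells) prevents biologically related tissues from diluting
#' the comparison group.
#'
#' Features with missing values (methylation windows without CpG coverage)
#' are fitted on their complete samples only.
#'
#' @param M a `signal_matrix`.
#' @param coding `"standard"` or `"inverted"` (see [fit_specificity_model()]).
#' @param covariates optional data frame of per-sample covariates aligned to
#'   the columns of `M`.
#' @param class_exclusion apply same-class exclusion (default `TRUE`).
#' @param tissues tissues to test; defaults to all tissues in `M`.
#' @return Tibble: `feature_id`, `tissue`, `b`, `se`, `t`, `n_used`.
#' @export
specificity_matrix <- function(M, coding = c("standard", "inverted"),
                               covariates = NULL, class_exclusion = TRUE,
                               tissues = NULL) {
  coding <- match.arg(coding)
  stopifnot(inherits(M, "signal_matrix"))
  meta <- M$samples
  tissues <- tissues %||% unique(meta$tissue)
  # precondition: each tested tissue keeps >= 2 comparison samples
  offenders <- purrr::keep(tissues, function(tt) {
    cls <- meta$class[meta$tissue == tt][1]
    sum(meta$class != cls) < 2
  })
  if (length(offenders) > 0) {
    abort(paste0("tissue(s) with < 2 samples outside their exclusion class: ",
                 paste(offenders, collapse = ", ")))
  }
  purrr::map_dfr(tissues, function(tt) {
    is_tested <- meta$tissue == tt
    cls <- meta$class[is_tested][1]
    use <- if (class_exclusion) is_tested | meta$class != cls else
      rep(TRUE, nrow(meta))
    y <- M$values[, use, drop = FALSE]
    tested <- is_tested[use]
    cov_use <- if (is.null(covariates)) NULL else
      as.data.frame(covariates)[use, , drop = FALSE]
    X <- specificity_design(tested, coding, cov_use, sum(use))
    complete <- !apply(y, 1, anyNA)
    out <- tibble::tibble(
      feature_id = rownames(M$values), tissue = tt,
      b = NA_real_, se = NA_real_, t = NA_real_, n_used = NA_integer_
    )
    if (any(complete)) {
      fit <- ols_multi(X, t(y[complete, , drop = FALSE]))
      out$b[complete] <- fit$b
      out$se[complete] <- fit$se
      out$t[complete] <- fit$t
      out$n_used[complete] <- sum(use)
    }
    for (i in which(!complete)) {
      ok <- !is.na(y[i, ])
      if (sum(ok) < 3 || all(tested[ok]) || !any(tested[ok])) {
        tm_log(sprintf("feature %s dropped for tissue %s: too few samples",
                       out$feature_id[i], tt), level = "WARN")
        next
      }
      f <- fit_specificity_model(y[i, ok], tested[ok], coding,
                                 if (is.null(cov_use)) NULL else
                                   cov_use[ok, , drop = FALSE])
      out$b[i] <- f$b; out$se[i] <- f$se; out$t[i] <- f$t
      out$n_used[i] <- f$n_used
    }
    out
  })
}

#' Standardize an expression matrix
#'
#' Centers and scales log2-transformed expression so each sample's gene
#' vector has mean 0 and standard deviation 1 (`scope = "sample"`, the
#' default: removes library-size and composition scale while keeping
#' cross-gene contrasts). `scope = "tissue"` pools the samples of each
#' tissue and standardizes their columns with the pooled mean and sd.
#'
#' @param E genes x samples matrix of log2FPKM, or a `signal_matrix`.
#' @param samples sample metadata tibble (ignored when `E` is a
#'   `signal_matrix`).
#' @param scope `"sample"` or `"tissue"`.
#' @return A `signal_matrix` of standardized expression.
#' @export
standardize_expression <- function(E, samples = NULL,
                                   scope = c("sample", "tissue")) {
  scope <- match.arg(scope)
  if (inherits(E, "signal_matrix")) {
    samples <- E$samples
    E <- E$values
  }
  if (nrow(E) < 2) abort("need at least 2 genes to standardize")
  if (anyNA(E) || any(!is.finite(E))) abort("expression matrix must be finite")
  if (scope == "sample") {
    mu <- colMeans(E)
    sdv <- apply(E, 2, sd)
    if (any(sdv == 0)) {
      abort(paste0("zero-variance sample(s): ",
                   paste(colnames(E)[sdv == 0], collapse = ", ")))
    }
    V <- sweep(sweep(E, 2, mu), 2, sdv, "/")
  } else {
    V <- E
    for (tt in unique(samples$tissue)) {
      cols <- samples$tissue == tt
      vals <- E[, cols, drop = FALSE]
      s <- sd(as.vector(vals))
      if (s == 0) abort(paste0("zero-variance tissue: ", tt))
      V[, cols] <- (vals - mean(vals)) / s
    }
  }
  signal_matrix(V, samples, kind = "expression", mark = "RNA")
}

#' Coverage-weighted methylation level of a window
#'
#' The weighted methylation level is the total methylated read count divided
#' by the total read count over all CpGs in the window — weighting each CpG
#' by its coverage rather than averaging per-CpG ratios.
#'
#' @param meth_reads,total_reads integer vectors over the CpGs in a window.
#' @return A number in \[0, 1\], or `NA` for an empty window.
#' @export
#' @examples
#' weighted_methylation(c(1, 0), c(1, 9))  # 0.1, not the naive mean 0.5
weighted_methylation <- function(meth_reads, total_reads) {
  stopifnot(length(meth_reads) == length(total_reads))
  keep <- total_reads > 0
  if (!any(keep)) return(NA_real_)
  sum(meth_reads[keep]) / sum(total_reads[keep])
}

#' Per-sample weighted methylation over promoter windows
#'
#' Builds a features x samples methylation `signal_matrix` from per-CpG
#' counts. Windows with no covered CpG in a sample are `NA` (dropped
#' pairwise during specificity fitting, with a log line): zero would assert
#' complete unmethylation, which absence of coverage does not support.
#'
#' @param cpgs CpG tibble from [read_methylation_counts()] (all samples).
#' @param windows promoter windows.
#' @param class_map optional tissue-to-class map, see [build_signal_matrix()].
#' @return A `signal_matrix` with values in \[0, 1\] or `NA`.
#' @export
build_methylation_matrix <- function(cpgs, windows, class_map = NULL) {
  sample_ids <- unique(cpgs$sample_id)
  meta <- cpgs |>
    dplyr::distinct(.data$sample_id, .data$tissue)
  if (is.null(class_map)) meta$class <- meta$tissue else {
    meta$class <- class_map$class[match(meta$tissue, class_map$tissue)]
    if (anyNA(meta$class)) abort("tissue not in class map")
  }
  w <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start + 1L,
                                               windows$end))
  values <- matrix(NA_real_, nrow(windows), length(sample_ids),
                   dimnames = list(windows$gene_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    cs <- cpgs[cpgs$sample_id == sample_ids[j], ]
    # CpG pos is 1-based; a CpG is in the window iff pos-1 in [start, end)
    p <- GenomicRanges::GRanges(cs$chrom, IRanges::IRanges(cs$pos, cs$pos))
    hits <- GenomicRanges::findOverlaps(w, p)
    wi <- S4Vectors::queryHits(hits)
    pi <- S4Vectors::subjectHits(hits)
    if (length(wi) == 0) next
    m <- rowsum(cs$meth_reads[pi], wi)
    tot <- rowsum(cs$total_reads[pi], wi)
    values[as.integer(rownames(m)), j] <- m[, 1] / tot[, 1]
  }
  n_missing <- sum(is.na(values))
  if (n_missing > 0) {
    tm_log(sprintf("%d window/sample cell(s) without CpG coverage -> NA",
                   n_missing))
  }
  signal_matrix(values, meta[match(sample_ids, meta$sample_id), ],
                kind = "promoter", mark = "WGBS")
}

#' Tissue-specific hypomethylation t-statistics
#'
#' [specificity_matrix()] with inverted coding: the tested tissue is coded
#' -1 so that specifically *low* promoter methylation gives a positive t,
#' mirroring the negative association between promoter methylation and
#' transcription.
#'
#' @inheritParams specificity_matrix
#' @return Tibble as from [specificity_matrix()].
#' @export
methylation_specificity <- function(M, covariates = NULL,
                                    class_exclusion = TRUE, tissues = NULL) {
  specificity_matrix(M, coding = "inverted", covariates = covariates,
                     class_exclusion = class_exclusion, tissues = tissues)
}

#' Select the top fraction of tissue-specific features
#'
#' Takes the `ceiling(k * n)` features with the largest t for a tissue
#' (defaults to the top 5%; 3% and 10% are the other conventional cutoffs),
#' breaking ties by feature id. The features' genomic windows are attached
#' so the set can be used as regions for enrichment testing.
#'
#' @param R specificity tibble from [specificity_matrix()].
#' @param tissue tissue to select for.
#' @param k fraction in (0, 1\].
#' @param windows window tibble supplying the features' regions.
#' @return Tibble: `feature_id`, `t`, `chrom`, `start`, `end`, `strand`,
#'   with attributes `tissue` and `k`.
#' @export
select_top_fraction <- function(R, tissue, k = 0.05, windows) {
  if (!(k > 0 && k <= 1)) abort("`k` must lie in (0, 1]")
  Rt <- R[R$tissue == tissue & !is.na(R$t), ]
  n <- nrow(Rt)
  if (n * k < 1) abort(sprintf("k = %g of %d features selects none", k, n))
  n_top <- ceiling(k * n)
  ord <- order(-Rt$t, Rt$feature_id)
  top <- Rt[ord[seq_len(n_top)], c("feature_id", "t")]
  idx <- match(top$feature_id, windows$gene_id)
  if (anyNA(idx)) {
    abort(paste0("features without windows: ",
                 paste(top$feature_id[is.na(idx)], collapse = ", ")))
  }
  out <- dplyr::bind_cols(top, windows[idx, c("chrom", "start", "end", "strand")])
  attr(out, "tissue") <- tissue
  attr(out, "k") <- k
  out
}

#' Write a top-feature set as BED6 with t in the score column
#' @param x tibble from [select_top_fraction()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_top_features_bed <- function(x, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, x$start, x$end,
                   x$feature_id, format(x$t, trim = TRUE), x$strand)
  writeLines(lines, path)
  invisible(path)
}
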