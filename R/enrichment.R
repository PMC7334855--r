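#' Build a marker set from GWAS markers and a region set
#'
#' A marker (1-based position `pos`) belongs to the set iff `pos - 1` falls
#' in `[start, end)` of any region (the half-open BED convention). Markers
#' covered by several overlapping regions are counted once. The set is
#' represented by the markers' circular ranks (the `index` column of the
#' ordered GWAS table).
#'
#' @param gwas GWAS tibble from [read_gwas_summary()]/[as_gwas_table()].
#' @param regions tibble of intervals (`chrom`, `start`, `end`).
#' @return A list of class `marker_set`: `indices` (sorted 0-based circular
#'   ranks), `m` (total markers), `n_set`.
#' @export
build_marker_set <- function(gwas, regions) {
  stopifnot("index" %in% names(gwas))
  m <- nrow(gwas)
  if (nrow(regions) == 0) {
    return(structure(list(indices = integer(0), m = m, n_set = 0L),
                     class = "marker_set"))
  }
  r <- GenomicRanges::reduce(GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end)))
  p <- GenomicRanges::GRanges(gwas$chrom, IRanges::IRanges(gwas$pos, gwas$pos))
  hits <- GenomicRanges::findOverlaps(p, r)
  idx <- sort(unique(gwas$index[S4Vectors::queryHits(hits)]))
  structure(list(indices = as.integer(idx), m = m, n_set = length(idx)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d of %d markers\n", x$n_set, x$m))
  invisible(x)
}

#' Sum-based marker-set statistic
#'
#' The observed enrichment statistic: the sum of squared per-marker
#' association statistics over the markers in the set. Squaring makes the
#' statistic sign-agnostic; `"abs"` and `"neglog10p"` transforms of the
#' supplied vector are available as alternative summand conventions.
#'
#' @param stats per-marker statistic vector in circular order (length `m`).
#' @param set a `marker_set`.
#' @param summand `"square"` (default), `"abs"`, or `"identity"` (sum the
#'   vector as given, e.g. pre-computed -log10 p).
#' @return The sum over the set.
#' @export
sum_statistic <- function(stats, set, summand = c("square", "abs",
                                                  "identity")) {
  summand <- match.arg(summand)
  stopifnot(length(stats) == set$m)
  v <- switch(summand, square = stats^2, abs = abs(stats), identity = stats)
  sum(v[set$indices + 1L])
}

# rotation sums for all offsets 1..m-1: exact, vectorized via an index matrix
rotation_sums <- function(v, indices, m, offsets) {
  idx <- outer(indices, offsets, function(i, k) (i + k) %% m) + 1L
  colSums(matrix(v[idx], nrow = length(indices)))
}

#' Circular-rotation empirical p-value for a marker set
#'
#' The null distribution rotates the genome-ordered statistic vector rigidly
#' relative to the set membership: offset `k` replaces each set member `i`
#' by marker `(i + k) mod m`. Rigid rotation preserves the local correlation
#' structure of the statistics, which is what this permutation scheme is
#' designed to respect. `n_perm` offsets are drawn uniformly from
#' `{1, ..., m-1}` (or all `m - 1` offsets once when `exhaustive = TRUE`),
#' and the empirical p-value uses the add-one rule
#' `p = (#\{null >= observed\} + 1) / (n_null + 1)`, which is strictly
#' positive and conservatively valid. A set containing every marker is
#' rotation-invariant and returns p = 1 with a warning.
#'
#' @param stats per-marker statistic vector in circular order.
#' @param set a `marker_set`.
#' @param n_perm number of sampled rotations (ignored when exhaustive).
#' @param seed integer seed; fully determines the sampled offsets.
#' @param exhaustive use every offset once instead of sampling.
#' @param summand see [sum_statistic()].
#' @param per_chromosome optional integer vector of chromosome sizes (marker
#'   counts, in circular order) to rotate each chromosome independently
#'   instead of the whole genome rigidly.
#' @return A list of class `sum_test`: `T_obs`, `null_T`, `p_emp`, `n_perm`,
#'   `seed`, `exhaustive`, `n_set`, `m`.
#' @export
#' @examples
#' gw <- as_gwas_table(tibble::tibble(
#'   marker_id = paste0("m", 1:5), chrom = "chr1",
#'   pos = c(10, 20, 30, 40, 50), stat = c(3, 1, 1, 1, 0)), "chr1")
#' set <- build_marker_set(gw, tibble::tibble(chrom = "chr1", start = 5, end = 15))
#' circular_permutation_pvalue(gw$stat, set, exhaustive = TRUE)$p_emp  # 0.2
circular_permutation_pvalue <- function(stats, set, n_perm = 10000L,
                                        seed = 1L, exhaustive = FALSE,
                                        summand = "square",
                                        per_chromosome = NULL) {
  m <- set$m
  if (m < 2) abort("need at least 2 markers")
  if (set$n_set == 0) abort("empty marker set; report the cell as missing")
  summand <- match.arg(summand, c("square", "abs", "identity"))
  v <- switch(summand, square = stats^2, abs = abs(stats), identity = stats)
  T_obs <- sum(v[set$indices + 1L])
  if (set$n_set == m) {
    warn("set contains every marker; rotation-invariant, p = 1")
    return(structure(list(T_obs = T_obs, null_T = T_obs, p_emp = 1,
                          n_perm = 0L, seed = seed, exhaustive = exhaustive,
                          n_set = set$n_set, m = m), class = "sum_test"))
  }
  if (!is.null(per_chromosome)) {
    stopifnot(sum(per_chromosome) == m)
    null_T <- perchrom_rotation_null(v, set$indices, per_chromosome,
                                     n_perm, seed)
  } else if (exhaustive) {
    null_T <- rotation_sums(v, set$indices, m, seq_len(m - 1))
  } else {
    offsets <- withr::with_seed(seed,
                                sample.int(m - 1L, n_perm, replace = TRUE))
    null_T <- rotation_sums(v, set$indices, m, offsets)
  }
  p_emp <- (sum(null_T >= T_obs) + 1) / (length(null_T) + 1)
  structure(list(T_obs = T_obs, null_T = null_T, p_emp = p_emp,
                 n_perm = length(null_T), seed = seed,
                 exhaustive = exhaustive, n_set = set$n_set, m = m),
            class = "sum_test")
}

# independent rotation per chromosome (optional null variant)
perchrom_rotation_null <- function(v, indices, sizes, n_perm, seed) {
  starts <- cumsum(c(0L, head(sizes, -1)))
  chrom_of <- findInterval(indices, starts)
  withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      k <- vapply(sizes, function(s) sample.int(s, 1L) - 1L, integer(1))
      off <- k[chrom_of]
      local_i <- indices - starts[chrom_of]
      rot <- starts[chrom_of] + (local_i + off) %% sizes[chrom_of]
      sum(v[rot + 1L])
    }, numeric(1))
  })
}

#' @export
print.sum_test <- function(x, ...) {
  cat(sprintf("<sum_test> T_obs = %.4g, p = %.4g (%d of %d markers, %s)\n",
              x$T_obs, x$p_emp, x$n_set, x$m,
              if (x$exhaustive) "exhaustive rotations"
              else sprintf("%d rotations", x$n_perm)))
  invisible(x)
}

#' @export
tidy.sum_test <- function(x, ...) {
  tibble::tibble(T_obs = x$T_obs, p_emp = x$p_emp, n_set = x$n_set,
                 m = x$m, n_perm = x$n_perm,
                 null_mean = mean(x$null_T), null_sd = sd(x$null_T))
}

#' @export
glance.sum_test <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, seed = x$seed, exhaustive = x$exhaustive)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH correction with monotonicity enforcement (delegating to
#' [stats::p.adjust()]); input order is preserved. Values outside (0, 1\]
#' are an error.
#'
#' @param pvals numeric vector of p-values; `NA`s pass through.
#' @return q-values in input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] <= 0 | pvals[ok] > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Trait x tissue enrichment profile
#'
#' Runs the circular-rotation sum test for every (trait, tissue) pair and
#' assembles the matrix of -log10 empirical p-values with matrix-wide BH
#' q-values (`fdr_scope = "matrix"`, matching one heatmap per mark/cutoff;
#' `"trait"` corrects within each trait instead). Cells whose marker set is
#' empty are reported missing, not p = 1.
#'
#' @param gwas_by_trait named list of GWAS tibbles sharing one marker order.
#' @param sets_by_tissue named list of region tibbles (e.g. from
#'   [select_top_fraction()]).
#' @param cfg a [run_config()]; supplies `n_perm`, `seed`, `fdr_alpha`.
#' @param exhaustive use exhaustive rotations (small m only).
#' @param fdr_scope `"matrix"` or `"trait"`.
#' @return Tibble of class `enrichment_profile`: `trait`, `tissue`, `T_obs`,
#'   `n_set`, `p_emp`, `neglog10p`, `q`, `significant`.
#' @export
enrichment_profile <- function(gwas_by_trait, sets_by_tissue,
                               cfg = run_config(), exhaustive = FALSE,
                               fdr_scope = c("matrix", "trait")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(length(gwas_by_trait) > 0, length(sets_by_tissue) > 0)
  key <- function(g) paste(g$chrom, g$pos, collapse = ";")
  keys <- vapply(gwas_by_trait, key, character(1))
  if (length(unique(keys)) != 1) {
    abort("marker order differs across traits; all GWAS tables must share it")
  }
  g0 <- gwas_by_trait[[1]]
  sets <- purrr::map(sets_by_tissue, ~ build_marker_set(g0, .x))
  grid <- tidyr::expand_grid(trait = names(gwas_by_trait),
                             tissue = names(sets_by_tissue))
  rows <- purrr::pmap_dfr(grid, function(trait, tissue) {
    set <- sets[[tissue]]
    if (set$n_set == 0) {
      tm_log(sprintf("empty marker set for tissue %s; cell missing", tissue),
             level = "WARN")
      return(tibble::tibble(trait = trait, tissue = tissue, T_obs = NA_real_,
                            n_set = 0L, p_emp = NA_real_))
    }
    st <- circular_permutation_pvalue(
      gwas_by_trait[[trait]]$stat, set, n_perm = cfg$n_perm,
      seed = cfg$seed, exhaustive = exhaustive)
    tibble::tibble(trait = trait, tissue = tissue, T_obs = st$T_obs,
                   n_set = st$n_set, p_emp = st$p_emp)
  })
  rows$neglog10p <- -log10(rows$p_emp)
  if (fdr_scope == "matrix") {
    rows$q <- bh_fdr(rows$p_emp)
  } else {
    rows <- rows |>
      dplyr::group_by(.data$trait) |>
      dplyr::mutate(q = bh_fdr(.data$p_emp)) |>
      dplyr::ungroup()
  }
  rows$significant <- !is.na(rows$q) & rows$q < cfg$fdr_alpha
  class(rows) <- c("enrichment_profile", class(rows))
  attr(rows, "fdr_alpha") <- cfg$fdr_alpha
  rows
}

#' Wide -log10 p matrix of an enrichment profile
#' @param profile tibble from [enrichment_profile()].
#' @return traits x tissues matrix of -log10 empirical p.
#' @export
profile_matrix <- function(profile) {
  wide <- tidyr::pivot_wider(
    profile[, c("trait", "tissue", "neglog10p")],
    names_from = "tissue", values_from = "neglog10p")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$trait
  m
}
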