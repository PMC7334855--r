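#' Pearson correlation with t-transform p-values
#'
#' Core helper shared by the correlation operations: Pearson r between two
#' vectors with pairwise-complete observations, two-sided p from
#' `t = r sqrt((n-2) / (1-r^2))` with `n - 2` degrees of freedom. Cells with
#' fewer than 3 shared observations are missing.
#'
#' @param x,y numeric vectors.
#' @return list with `r`, `p`, `n`.
#' @keywords internal
pearson_cell <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x[ok], y[ok])
  if (is.na(r)) return(list(r = r, p = NA_real_, n = n))
  if (abs(r) >= 1) {
    # perfectly collinear vectors: smallest representable positive p so that
    # downstream BH input stays in (0, 1]
    return(list(r = r, p = .Machine$double.xmin, n = n))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- max(2 * pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
  list(r = r, p = p, n = n)
}

correlation_grid <- function(A, B, row_labels, col_labels, get_a, get_b) {
  grid <- tidyr::expand_grid(row = row_labels, col = col_labels)
  out <- purrr::pmap_dfr(grid, function(row, col) {
    cell <- pearson_cell(get_a(row), get_b(col))
    tibble::tibble(row = row, col = col, r = cell$r, p = cell$p, n = cell$n)
  })
  out$q <- bh_fdr(out$p)
  out
}

#' Correlate tissue-specificity t-statistics between two modalities
#'
#' For every tissue pair (tissue of modality A x tissue of modality B),
#' computes the Pearson correlation of the two t-statistic vectors over
#' their shared features — e.g. histone-mark specificity vs expression
#' specificity, where a high diagonal indicates that the transferred marks
#' capture tissue-specific expression. BH correction is applied over all
#' cells; `significant` stars cells with q below `q_star` (default 0.001,
#' the heatmap convention for these comparisons).
#'
#' @param A,B specificity tibbles from [specificity_matrix()].
#' @param q_star FDR threshold for the star column.
#' @param positive_only star only positive correlations (default `TRUE`).
#' @return Tibble of class `correlation_matrix`: `tissue_a`, `tissue_b`,
#'   `r`, `p`, `q`, `n`, `significant`.
#' @export
modality_correlation <- function(A, B, q_star = 0.001,
                                 positive_only = TRUE) {
  shared <- intersect(unique(A$feature_id), unique(B$feature_id))
  if (length(shared) < 3) abort("fewer than 3 shared features")
  ta <- tidyr::pivot_wider(A[A$feature_id %in% shared, c("feature_id", "tissue", "t")],
                           names_from = "tissue", values_from = "t")
  tb <- tidyr::pivot_wider(B[B$feature_id %in% shared, c("feature_id", "tissue", "t")],
                           names_from = "tissue", values_from = "t")
  ta <- ta[match(shared, ta$feature_id), ]
  tb <- tb[match(shared, tb$feature_id), ]
  out <- correlation_grid(
    A, B, setdiff(names(ta), "feature_id"), setdiff(names(tb), "feature_id"),
    function(tt) ta[[tt]], function(tt) tb[[tt]])
  names(out)[1:2] <- c("tissue_a", "tissue_b")
  out$significant <- !is.na(out$q) & out$q < q_star &
    (!positive_only | out$r > 0)
  class(out) <- c("correlation_matrix", class(out))
  out
}

#' Correlate trait enrichment profiles across tissue panels
#'
#' Each trait is summarized by its vector of -log10 enrichment p-values
#' across tissues; trait pairs (one from each profile, e.g. cattle x human)
#' are correlated over explicitly mapped comparable tissues. Missing cells
#' (empty marker sets) are dropped pairwise with `n` recorded.
#'
#' @param P,Q enrichment profiles from [enrichment_profile()].
#' @param tissue_map tibble with columns `tissue_p`, `tissue_q` pairing
#'   comparable tissue labels; defaults to identical labels shared by both.
#' @param q_star FDR threshold for the star column (default 0.05).
#' @return Tibble of class `correlation_matrix`: `trait_p`, `trait_q`, `r`,
#'   `p`, `q`, `n`, `significant`.
#' @export
trait_correlation <- function(P, Q, tissue_map = NULL, q_star = 0.05) {
  if (is.null(tissue_map)) {
    shared <- intersect(unique(P$tissue), unique(Q$tissue))
    tissue_map <- tibble::tibble(tissue_p = shared, tissue_q = shared)
  }
  miss_p <- setdiff(tissue_map$tissue_p, unique(P$tissue))
  miss_q <- setdiff(tissue_map$tissue_q, unique(Q$tissue))
  if (length(miss_p) + length(miss_q) > 0) {
    abort(paste0("unmapped tissue labels: ",
                 paste(c(miss_p, miss_q), collapse = ", ")))
  }
  if (nrow(tissue_map) < 3) abort("fewer than 3 mapped tissue pairs")
  pm <- profile_matrix(P)[, tissue_map$tissue_p, drop = FALSE]
  qm <- profile_matrix(Q)[, tissue_map$tissue_q, drop = FALSE]
  out <- correlation_grid(
    P, Q, rownames(pm), rownames(qm),
    function(tr) pm[tr, ], function(tr) qm[tr, ])
  names(out)[1:2] <- c("trait_p", "trait_q")
  out$significant <- !is.na(out$q) & out$q < q_star
  class(out) <- c("correlation_matrix", class(out))
  out
}

#' Interval-overlap permutation test
#'
#' Tests whether a set of query segments overlaps an annotation more than
#' expected by chance within a workspace. Each permutation re-places every
#' query segment independently and uniformly at random among all positions
#' where it fits inside a single workspace interval (lengths preserved,
#' overlaps among placed segments allowed) and records the total bp of
#' intersection with the annotation. The empirical p is the add-one upper
#' tail. With `exhaustive = TRUE` (single query segment only) all placements
#' are enumerated and p is the exact fraction of placements with overlap at
#' least the observed.
#'
#' @param query,annotation peak-set tibbles (or any `chrom`/`start`/`end`
#'   tibbles).
#' @param workspace tibble of intervals within which placement happens.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param exhaustive enumerate all placements (one query segment).
#' @return List of class `overlap_test`: `observed_bp`, `null_bp`, `p_emp`,
#'   `fold` (observed / mean null), `n_perm`, `seed`.
#' @export
overlap_permutation_test <- function(query, annotation, workspace,
                                     n_perm = 10000L, seed = 1L,
                                     exhaustive = FALSE) {
  seg_len <- query$end - query$start
  ws_len <- workspace$end - workspace$start
  if (any(seg_len > max(ws_len))) {
    abort("a query segment is longer than every workspace interval")
  }
  ann <- GenomicRanges::reduce(GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(annotation$start + 1L, annotation$end)))
  overlap_bp <- function(chrom, start, end) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
    hits <- GenomicRanges::findOverlaps(gr, ann)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    sum(pmin(end[qh], GenomicRanges::end(ann)[sh]) -
          pmax(start[qh], GenomicRanges::start(ann)[sh] - 1L))
  }
  observed <- sum(vapply(seq_len(nrow(query)), function(i) {
    overlap_bp(query$chrom[i], query$start[i], query$end[i])
  }, numeric(1)))
  if (exhaustive) {
    if (nrow(query) != 1) abort("exhaustive mode handles one query segment")
    L <- seg_len[1]
    placements <- purrr::pmap_dfr(workspace, function(chrom, start, end, ...) {
      n_pos <- (end - start) - L + 1
      if (n_pos < 1) return(tibble::tibble())
      tibble::tibble(chrom = chrom, start = start + seq_len(n_pos) - 1)
    })
    gr <- GenomicRanges::GRanges(
      placements$chrom, IRanges::IRanges(placements$start + 1L,
                                         placements$start + L))
    hits <- GenomicRanges::findOverlaps(gr, ann)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    bp <- pmin(placements$start[qh] + L, GenomicRanges::end(ann)[sh]) -
      pmax(placements$start[qh], GenomicRanges::start(ann)[sh] - 1L)
    null_bp <- rep(0, nrow(placements))
    if (length(qh) > 0) {
      agg <- rowsum(bp, qh)
      null_bp[as.integer(rownames(agg))] <- agg[, 1]
    }
    p_emp <- mean(null_bp >= observed)
    return(structure(list(observed_bp = observed, null_bp = null_bp,
                          p_emp = p_emp, fold = observed / mean(null_bp),
                          n_perm = length(null_bp), seed = seed),
                     class = "overlap_test"))
  }
  # one uniform placement = pick a position among all valid (interval, start)
  n_pos_by_seg <- lapply(seg_len, function(L) pmax(ws_len - L + 1, 0))
  null_bp <- withr::with_seed(seed, {
    draws <- purrr::map_dfr(seq_along(seg_len), function(s) {
      n_pos <- n_pos_by_seg[[s]]
      total <- sum(n_pos)
      if (total < 1) abort("no valid placement for a query segment")
      u <- sample.int(total, n_perm, replace = TRUE)
      wi <- findInterval(u - 1, cumsum(c(0, n_pos)),
                         rightmost.closed = FALSE)
      off <- u - cumsum(c(0, n_pos))[wi] - 1
      tibble::tibble(perm = seq_len(n_perm),
                     chrom = workspace$chrom[wi],
                     start = workspace$start[wi] + off,
                     end = workspace$start[wi] + off + seg_len[s])
    })
    gr <- GenomicRanges::GRanges(draws$chrom,
                                 IRanges::IRanges(draws$start + 1L, draws$end))
    ov <- GenomicRanges::findOverlaps(gr, ann)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    bp <- pmin(draws$end[qh], GenomicRanges::end(ann)[sh]) -
      pmax(draws$start[qh], GenomicRanges::start(ann)[sh] - 1L)
    per_perm <- rep(0, n_perm)
    if (length(qh) > 0) {
      agg <- rowsum(bp, draws$perm[qh])
      per_perm[as.integer(rownames(agg))] <- agg[, 1]
    }
    per_perm
  })
  p_emp <- (sum(null_bp >= observed) + 1) / (n_perm + 1)
  structure(list(observed_bp = observed, null_bp = null_bp, p_emp = p_emp,
                 fold = if (mean(null_bp) > 0) observed / mean(null_bp)
                 else NA_real_,
                 n_perm = n_perm, seed = seed),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("<overlap_test> observed %g bp, fold = %.3g, p = %.4g (%d perms)\n",
              x$observed_bp, x$fold, x$p_emp, x$n_perm))
  invisible(x)
}

#' @export
tidy.overlap_test <- function(x, ...) {
  tibble::tibble(observed_bp = x$observed_bp, null_mean = mean(x$null_bp),
                 fold = x$fold, p_emp = x$p_emp, n_perm = x$n_perm)
}
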