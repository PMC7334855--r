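#' Strand-aware promoter windows
#'
#' The promoter of a gene is the window from `up` bp upstream to `down` bp
#' downstream of its TSS (defaults: -1000 / +500, i.e. a 1.5 kb window).
#' For a `+` strand gene with TSS at `start` this is `[TSS-up, TSS+down)`;
#' for a `-` strand gene the TSS is the annotation `end` and the window is
#' mirrored to `[TSS-down, TSS+up)`. Windows are clipped to
#' `[0, chrom_len)` when chromosome lengths are supplied.
#'
#' @param genes gene tibble from [read_gene_annotation()].
#' @param up,down bp up-/downstream of the TSS.
#' @param chrom_len optional named vector of chromosome lengths.
#' @return A window tibble: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `kind = "promoter"`.
#' @export
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 5000,
#'                     end = 9000, strand = "+", biotype = "protein_coding")
#' promoter_windows(g)  # [4000, 5500)
promoter_windows <- function(genes, up = 1000L, down = 500L,
                             chrom_len = NULL) {
  tss <- gene_tss(genes)
  start <- ifelse(genes$strand == "+", tss - up, tss - down)
  end <- ifelse(genes$strand == "+", tss + down, tss + up)
  start <- pmax(start, 0L)
  if (!is.null(chrom_len)) {
    lens <- chrom_len[genes$chrom]
    if (anyNA(lens)) {
      abort(paste0("chromosome length missing for: ",
                   paste(unique(genes$chrom[is.na(lens)]), collapse = ", ")))
    }
    end <- pmin(end, lens)
  }
  tibble::tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = as.integer(start), end = as.integer(end),
    strand = genes$strand, kind = "promoter"
  )
}

#' Gene-body windows
#'
#' The gene-body window of a gene is its full annotated span. Genes shorter
#' than `min_len` bp (default 750) are excluded.
#'
#' @param genes gene tibble.
#' @param min_len minimum gene length in bp.
#' @return A window tibble with `kind = "genebody"`.
#' @export
genebody_windows <- function(genes, min_len = 750L) {
  keep <- (genes$end - genes$start) >= min_len
  if (any(!keep)) {
    tm_log(sprintf("excluded %d gene(s) shorter than %d bp",
                   sum(!keep), min_len))
  }
  g <- genes[keep, ]
  tibble::tibble(
    gene_id = g$gene_id, chrom = g$chrom,
    start = as.integer(g$start), end = as.integer(g$end),
    strand = g$strand, kind = "genebody"
  )
}

# shared overlap engine: per-window sum of signal x weight over peaks
window_overlap <- function(peaks, windows) {
  if (nrow(peaks) == 0 || nrow(windows) == 0) {
    return(tibble::tibble(win = integer(), peak = integer(),
                          ov_bp = integer()))
  }
  w <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start + 1L,
                                               windows$end))
  p <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$start + 1L, peaks$end))
  hits <- GenomicRanges::findOverlaps(w, p)
  wi <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  tibble::tibble(
    win = wi, peak = pi,
    ov_bp = pmin(windows$end[wi], peaks$end[pi]) -
      pmax(windows$start[wi], peaks$start[pi])
  )
}

#' Aggregate peak signal into promoter windows
#'
#' Per gene, sums `signal * (overlap bp / peak length)` over all peaks
#' overlapping its promoter window: the portion of each peak's signal mass
#' that falls inside the window. Genes with no overlapping peak get 0. Peaks
#' without a signal value are counted with signal 1 (with a warning).
#' Alternative aggregation modes: `"occupancy"` (count of overlapping
#' peaks) and `"signal_bp"` (signal times overlap bp).
#'
#' @param peaks peak-set tibble.
#' @param windows promoter-window tibble from [promoter_windows()].
#' @param mode aggregation rule; default `"signal_fraction"`.
#' @return Named numeric vector, one entry per window gene.
#' @export
aggregate_promoter_signal <- function(peaks, windows,
                                      mode = c("signal_fraction", "occupancy",
                                               "signal_bp")) {
  mode <- match.arg(mode)
  stopifnot(all(windows$kind == "promoter"))
  sig <- peaks$signal
  if (nrow(peaks) > 0 && anyNA(sig)) {
    warn(sprintf("%d peak(s) lack a signal value; using 1.0",
                 sum(is.na(sig))))
    sig[is.na(sig)] <- 1
  }
  ov <- window_overlap(peaks, windows)
  contrib <- switch(mode,
    signal_fraction = sig[ov$peak] * ov$ov_bp /
      (peaks$end[ov$peak] - peaks$start[ov$peak]),
    occupancy = rep(1, nrow(ov)),
    signal_bp = sig[ov$peak] * ov$ov_bp
  )
  out <- setNames(numeric(nrow(windows)), windows$gene_id)
  if (nrow(ov) > 0) {
    agg <- rowsum(contrib, ov$win)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Aggregate peak signal over gene bodies, adjusted for gene length
#'
#' Per gene, computes the sum of `signal * overlap bp` over peaks in the gene
#' body, divided by the gene length in kb: a length-adjusted signal density.
#' Genes shorter than the minimum length must already have been excluded by
#' [genebody_windows()].
#'
#' @param peaks peak-set tibble.
#' @param windows gene-body windows from [genebody_windows()].
#' @param min_len guard: windows shorter than this are an upstream invariant
#'   breach and raise an error.
#' @return Named numeric vector of per-kb signal densities.
#' @export
aggregate_genebody_signal <- function(peaks, windows, min_len = 750L) {
  stopifnot(all(windows$kind == "genebody"))
  len <- windows$end - windows$start
  if (any(len < min_len)) {
    abort(sprintf("gene-body window for '%s' is %d bp < %d; filter upstream",
                  windows$gene_id[which(len < min_len)[1]],
                  len[which(len < min_len)[1]], min_len))
  }
  sig <- peaks$signal
  if (nrow(peaks) > 0 && anyNA(sig)) {
    warn(sprintf("%d peak(s) lack a signal value; using 1.0", sum(is.na(sig))))
    sig[is.na(sig)] <- 1
  }
  ov <- window_overlap(peaks, windows)
  out <- setNames(numeric(nrow(windows)), windows$gene_id)
  if (nrow(ov) > 0) {
    agg <- rowsum(sig[ov$peak] * ov$ov_bp, ov$win)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out / (len / 1000)
}

#' Build a features x samples signal matrix
#'
#' Aggregates each sample's peaks over a shared set of windows. All samples
#' must carry the same histone mark; promoter windows are the convention for
#' promoter marks (H3K4me3, H3K27ac), gene-body windows for H3K36me3.
#' Tissue labels are taken from the sample metadata; the exclusion class of
#' each sample (the broader tissue grouping removed from the comparison
#' group during specificity testing) comes from `class_map`, a two-column
#' tibble `tissue`, `class`. Tissues absent from the map are an error.
#'
#' @param samples list of peak-set tibbles, one per sample.
#' @param windows window tibble.
#' @param kind `"promoter"` or `"genebody"`; must match the windows.
#' @param class_map tibble mapping `tissue` to exclusion `class`; by default
#'   every tissue is its own class.
#' @param mode promoter aggregation mode, see [aggregate_promoter_signal()].
#' @return A `signal_matrix` object: list with `values` (features x samples),
#'   `samples` (tibble: `sample_id`, `tissue`, `class`), and `kind`.
#' @export
build_signal_matrix <- function(samples, windows,
                                kind = c("promoter", "genebody"),
                                class_map = NULL,
                                mode = "signal_fraction") {
  kind <- match.arg(kind)
  stopifnot(all(windows$kind == kind))
  marks <- unique(vapply(samples, peak_meta, character(1), what = "mark"))
  if (length(unique(marks[!is.na(marks)])) > 1) {
    abort(paste0("samples mix histone marks: ",
                 paste(unique(marks), collapse = ", ")))
  }
  meta <- tibble::tibble(
    sample_id = vapply(samples, peak_meta, character(1), what = "sample_id"),
    tissue = vapply(samples, peak_meta, character(1), what = "tissue")
  )
  if (is.null(class_map)) {
    meta$class <- meta$tissue
  } else {
    meta$class <- class_map$class[match(meta$tissue, class_map$tissue)]
    if (anyNA(meta$class)) {
      abort(paste0("tissue not in class map for sample(s): ",
                   paste(meta$sample_id[is.na(meta$class)], collapse = ", ")))
    }
  }
  cols <- lapply(samples, function(s) {
    if (kind == "promoter") aggregate_promoter_signal(s, windows, mode = mode)
    else aggregate_genebody_signal(s, windows)
  })
  values <- do.call(cbind, cols)
  colnames(values) <- meta$sample_id
  rownames(values) <- windows$gene_id
  signal_matrix(values, meta, kind = kind, mark = marks[1])
}

#' Construct a signal matrix from a values matrix and sample metadata
#'
#' @param values features x samples numeric matrix (no missing values for
#'   histone/expression matrices; methylation matrices may carry `NA` for
#'   windows without CpG coverage).
#' @param samples tibble with `sample_id`, `tissue`, and optionally `class`
#'   (exclusion class; defaults to the tissue itself), aligned to columns.
#' @param kind feature kind label.
#' @param mark assay label.
#' @return A `signal_matrix` object.
#' @export
signal_matrix <- function(values, samples, kind = "promoter",
                          mark = NA_character_) {
  samples <- tibble::as_tibble(samples)
  if (!"class" %in% names(samples)) samples$class <- samples$tissue
  stopifnot(ncol(values) == nrow(samples))
  structure(list(values = values, samples = samples, kind = kind,
                 mark = mark),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d features x %d samples (%s%s)\n",
              nrow(x$values), ncol(x$values), x$kind,
              if (is.na(x$mark)) "" else paste0(", ", x$mark)))
  cat("tissues:", paste(unique(x$samples$tissue), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.signal_matrix <- function(x, ...) {
  as.data.frame(as_tibble_signal(x))
}

#' Long-format view of a signal matrix
#' @param x a `signal_matrix`.
#' @return Tibble with `feature_id`, `sample_id`, `tissue`, `class`, `value`.
#' @export
as_tibble_signal <- function(x) {
  tibble::tibble(
    feature_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(x$samples$sample_id, each = nrow(x$values)),
    tissue = rep(x$samples$tissue, each = nrow(x$values)),
    class = rep(x$samples$class, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Write a signal matrix as TSV (values + sample metadata)
#' @param x a `signal_matrix`.
#' @param values_path,samples_path output paths.
#' @return `values_path`, invisibly.
#' @export
write_signal_matrix <- function(x, values_path, samples_path) {
  df <- tibble::as_tibble(x$values, rownames = "feature_id")
  readr::write_tsv(df, values_path, progress = FALSE)
  readr::write_tsv(x$samples, samples_path, progress = FALSE)
  invisible(values_path)
}

#' Read a signal matrix written by [write_signal_matrix()]
#' @param values_path,samples_path paths written by [write_signal_matrix()].
#' @param kind,mark labels, see [signal_matrix()].
#' @return A `signal_matrix`.
#' @export
read_signal_matrix <- function(values_path, samples_path, kind = "promoter",
                               mark = NA_character_) {
  df <- readr::read_tsv(values_path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_tsv(samples_path, show_col_types = FALSE,
                          progress = FALSE)
  values <- as.matrix(df[, -1])
  rownames(values) <- df$feature_id
  signal_matrix(values, meta, kind = kind, mark = mark)
}
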