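#' Read GWAS (or selection-scan) summary statistics
#'
#' Reads a header-ed TSV with columns `marker_id`, `chrom`, `pos` (1-based bp)
#' and either a signed statistic column `stat` or the pair `effect`, `se`
#' (then `stat = effect / se`). Markers are sorted by the explicit chromosome
#' order followed by position (a stable sort), and the resulting rank is
#' recorded in an `index` column (0-based): this is the marker's position in
#' the circular genome order used by the rotation null. A selection-signature
#' scan is ingested identically, with the scan statistic in `stat`.
#'
#' @param path file path.
#' @param chrom_order character vector giving the chromosome order. Markers
#'   on chromosomes absent from this list are an error.
#' @param trait optional trait label attached to all rows.
#' @return A tibble with columns `marker_id`, `chrom`, `pos`, `stat`,
#'   optionally `pvalue`, plus `trait` and `index`.
#' @export
read_gwas_summary <- function(path, chrom_order, trait = NA_character_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("marker_id", "chrom", "pos")
  missing <- setdiff(need, names(g))
  if (length(missing) > 0) {
    abort(paste0("GWAS TSV missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!"stat" %in% names(g)) {
    if (!all(c("effect", "se") %in% names(g))) {
      abort("GWAS TSV needs either a `stat` column or both `effect` and `se`")
    }
    zero_se <- which(g$se == 0)
    if (length(zero_se) > 0) {
      abort(sprintf("marker '%s' has se = 0; cannot form stat = effect/se",
                    g$marker_id[zero_se[1]]))
    }
    g$stat <- g$effect / g$se
  }
  if (any(!is.finite(g$stat))) {
    bad <- which(!is.finite(g$stat))
    abort(sprintf("marker '%s' has non-finite stat", g$marker_id[bad[1]]))
  }
  as_gwas_table(g, chrom_order, trait = trait)
}

#' Coerce a marker data frame into circular genome order
#'
#' @param g data frame with `marker_id`, `chrom`, `pos`, `stat`.
#' @param chrom_order chromosome name order defining the circle.
#' @param trait optional trait label.
#' @return Sorted tibble with an `index` column of circular ranks 0..m-1.
#' @export
as_gwas_table <- function(g, chrom_order, trait = NA_character_) {
  g <- tibble::as_tibble(g)
  unknown <- setdiff(unique(g$chrom), chrom_order)
  if (length(unknown) > 0) {
    abort(paste0("chromosomes not in chrom_order: ",
                 paste(unknown, collapse = ", ")))
  }
  ord <- order(match(g$chrom, chrom_order), g$pos)
  g <- g[ord, ]
  dup <- duplicated(g[, c("chrom", "pos")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("duplicate marker position %s:%d", g$chrom[i], g$pos[i]))
  }
  if (!"trait" %in% names(g) || all(is.na(g$trait))) g$trait <- trait
  g$index <- seq_len(nrow(g)) - 1L
  attr(g, "chrom_order") <- chrom_order
  g
}

#' Read per-CpG methylation counts
#'
#' TSV with columns `chrom`, `pos` (1-based), `meth`, `total` and optionally
#' `sample_id`, `tissue`. Rows with zero total coverage are dropped with a
#' logged count; `meth > total` is an error.
#'
#' @param path file path.
#' @param sample_id,tissue metadata attached when absent from the file.
#' @return Tibble with columns `chrom`, `pos`, `meth_reads`, `total_reads`,
#'   `sample_id`, `tissue`.
#' @export
read_methylation_counts <- function(path, sample_id = NA_character_,
                                    tissue = NA_character_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "meth", "total")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("methylation TSV missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(x$meth > x$total)
  if (length(bad) > 0) {
    abort(sprintf("CpG %s:%d has meth %d > total %d", x$chrom[bad[1]],
                  x$pos[bad[1]], x$meth[bad[1]], x$total[bad[1]]))
  }
  if (any(x$meth < 0)) abort("negative methylated-read count")
  zero <- x$total == 0
  if (any(zero)) {
    tm_log(sprintf("dropped %d CpG(s) with zero coverage", sum(zero)))
    x <- x[!zero, ]
  }
  tibble::tibble(
    chrom = as.character(x$chrom),
    pos = as.integer(x$pos),
    meth_reads = as.integer(x$meth),
    total_reads = as.integer(x$total),
    sample_id = if ("sample_id" %in% names(x)) x$sample_id else sample_id,
    tissue = if ("tissue" %in% names(x)) x$tissue else tissue
  )
}
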