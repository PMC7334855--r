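#' Read a gene annotation, keeping protein-coding genes
#'
#' Accepts either GTF (gene feature lines; 1-based inclusive coordinates,
#' converted to 0-based half-open on read) or a pre-tabulated TSV with columns
#' `gene_id`, `chrom`, `start`, `end`, `strand`, `biotype` already in 0-based
#' half-open coordinates. Records whose biotype is not `protein_coding` are
#' dropped. The TSS of a `+` strand gene is its `start`; of a `-` strand gene,
#' its `end`.
#'
#' @param path file path.
#' @param format `"gtf"` or `"tsv"`.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`.
#' @export
read_gene_annotation <- function(path, format = c("gtf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "gtf") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- stringr::str_split(lines, "\t")
    nf <- lengths(fields)
    bad <- which(nf < 9)
    if (length(bad) > 0) {
      abort(sprintf("line %d of %s: GTF needs 9 tab-separated fields, got %d",
                    bad[1], path, nf[bad[1]]))
    }
    mat <- t(vapply(fields, function(x) x[1:9], character(9)))
    keep <- mat[, 3] == "gene"
    mat <- mat[keep, , drop = FALSE]
    attr_field <- mat[, 9]
    pull_attr <- function(key) {
      m <- stringr::str_match(attr_field, paste0(key, ' "([^"]*)"'))[, 2]
      m
    }
    genes <- tibble::tibble(
      gene_id = pull_attr("gene_id"),
      chrom = mat[, 1],
      start = as.integer(mat[, 4]) - 1L,
      end = as.integer(mat[, 5]),
      strand = mat[, 7],
      biotype = pull_attr("gene_biotype")
    )
  } else {
    genes <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
    missing <- setdiff(need, names(genes))
    if (length(missing) > 0) {
      abort(paste0("gene TSV missing columns: ", paste(missing, collapse = ", ")))
    }
    genes <- genes[, need]
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
  }
  bad_strand <- which(is.na(genes$strand) | !genes$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(sprintf("gene '%s' has missing or invalid strand",
                  genes$gene_id[bad_strand[1]]))
  }
  bad <- which(!(genes$start < genes$end))
  if (length(bad) > 0) {
    abort(sprintf("gene '%s': start %d >= end %d", genes$gene_id[bad[1]],
                  genes$start[bad[1]], genes$end[bad[1]]))
  }
  n_before <- nrow(genes)
  genes <- dplyr::filter(genes, .data$biotype == "protein_coding")
  if (n_before > nrow(genes)) {
    tm_log(sprintf("dropped %d non-protein-coding gene(s)", n_before - nrow(genes)))
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated gene_id: ", paste(unique(dup), collapse = ", ")))
  }
  genes
}

#' Transcription start sites of an annotation
#'
#' @param genes tibble as returned by [read_gene_annotation()].
#' @return Integer vector of TSS positions (0-based): `start` for `+` strand
#'   genes and `end` for `-` strand genes.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}
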