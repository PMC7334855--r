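#' Peak-set tibbles
#'
#' A peak set is a tibble of half-open genomic intervals (`chrom`, `start`,
#' `end`, `name`, `score`, `strand`, `signal`) plus constant sample metadata
#' columns (`sample_id`, `tissue`, `mark`). Coordinates follow the BED
#' convention: 0-based start, exclusive end. `signal` carries the narrowPeak
#' signalValue and is `NA` for plain BED input.
#'
#' @param intervals tibble with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`, `signal`.
#' @param sample_id,tissue,mark sample metadata recycled across rows.
#' @return A tibble with one row per interval.
#' @export
peak_set <- function(intervals, sample_id = NA_character_,
                     tissue = NA_character_, mark = NA_character_) {
  iv <- tibble::as_tibble(intervals)
  for (col in c("name", "strand", "score", "signal")) {
    if (!col %in% names(iv)) {
      iv[[col]] <- if (col == "strand") "." else if (col == "score") 0L else NA
    }
  }
  iv <- iv[, c("chrom", "start", "end", "name", "score", "strand", "signal")]
  iv$chrom <- as.character(iv$chrom)
  iv$start <- as.integer(iv$start)
  iv$end <- as.integer(iv$end)
  iv$signal <- as.numeric(iv$signal)
  validate_intervals(iv)
  iv$sample_id <- sample_id
  iv$tissue <- tissue
  iv$mark <- mark
  # metadata survives empty peak sets (zero rows carry no column values)
  attr(iv, "sample_id") <- sample_id
  attr(iv, "tissue") <- tissue
  attr(iv, "mark") <- mark
  iv
}

peak_meta <- function(s, what) {
  v <- attr(s, what, exact = TRUE)
  if (!is.null(v) && !is.na(v)) return(v)
  if (nrow(s) > 0 && what %in% names(s)) s[[what]][1] else NA_character_
}

validate_intervals <- function(iv, what = "interval") {
  bad <- which(!(iv$start >= 0 & iv$start < iv$end))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s %d violates 0 <= start < end (chrom=%s start=%d end=%d)",
      what, bad[1], iv$chrom[bad[1]], iv$start[bad[1]], iv$end[bad[1]]
    ))
  }
  bad_strand <- which(!iv$strand %in% c("+", "-", "."))
  if (length(bad_strand) > 0) {
    abort(sprintf("%s %d has invalid strand '%s'", what, bad_strand[1],
                  iv$strand[bad_strand[1]]))
  }
  bad_sig <- which(!is.na(iv$signal) & iv$signal < 0)
  if (length(bad_sig) > 0) {
    abort(sprintf("%s %d has negative signal %g", what, bad_sig[1],
                  iv$signal[bad_sig[1]]))
  }
  invisible(iv)
}

#' Read peak intervals from BED-family files
#'
#' Supports plain BED3, BED6, and the ENCODE 10-column narrowPeak dialect.
#' Coordinates are kept 0-based half-open as on disk; for narrowPeak the
#' per-peak signalValue (column 7) populates `signal`. Input row order is
#' preserved. Extra trailing columns beyond the dialect are ignored with a
#' warning; malformed rows and invalid coordinates are errors that name the
#' offending line.
#'
#' @param path file path.
#' @param dialect one of `"narrowPeak"`, `"bed6"`, `"bed3"`.
#' @param sample_id,tissue,mark metadata attached to every row.
#' @return A peak-set tibble (see [peak_set()]).
#' @export
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t200\tp1\t0\t+\t10.0\t-1\t-1\t50", f)
#' read_peaks(f, "narrowPeak")
read_peaks <- function(path, dialect = c("narrowPeak", "bed6", "bed3"),
                       sample_id = NA_character_, tissue = NA_character_,
                       mark = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ncol_needed <- c(narrowPeak = 10L, bed6 = 6L, bed3 = 3L)[[dialect]]
  if (length(lines) == 0) {
    return(peak_set(
      tibble::tibble(chrom = character(), start = integer(), end = integer()),
      sample_id, tissue, mark
    ))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  short <- which(nf < ncol_needed)
  if (length(short) > 0) {
    abort(sprintf("line %d of %s has %d fields; %s needs %d",
                  short[1], path, nf[short[1]], dialect, ncol_needed))
  }
  if (any(nf > ncol_needed)) {
    warn(sprintf("%s: ignoring extra columns beyond the %s dialect on %d line(s)",
                 path, dialect, sum(nf > ncol_needed)))
  }
  mat <- t(vapply(fields, function(x) x[seq_len(ncol_needed)],
                  character(ncol_needed)))
  parse_int <- function(x, col) {
    out <- suppressWarnings(as.integer(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad) > 0) {
      abort(sprintf("line %d of %s: cannot parse '%s' as integer %s",
                    bad[1], path, x[bad[1]], col))
    }
    out
  }
  iv <- tibble::tibble(
    chrom = mat[, 1],
    start = parse_int(mat[, 2], "start"),
    end = parse_int(mat[, 3], "end")
  )
  if (dialect %in% c("bed6", "narrowPeak")) {
    iv$name <- mat[, 4]
    iv$score <- parse_int(mat[, 5], "score")
    iv$strand <- mat[, 6]
  }
  if (dialect == "narrowPeak") {
    sig <- suppressWarnings(as.numeric(mat[, 7]))
    bad <- which(is.na(sig))
    if (length(bad) > 0) {
      abort(sprintf("line %d of %s: cannot parse signalValue '%s'",
                    bad[1], path, mat[bad[1], 7]))
    }
    iv$signal <- sig
  }
  bad <- which(!(iv$start >= 0 & iv$start < iv$end))
  if (length(bad) > 0) {
    abort(sprintf("line %d of %s: start %d >= end %d",
                  bad[1], path, iv$start[bad[1]], iv$end[bad[1]]))
  }
  peak_set(iv, sample_id, tissue, mark)
}

#' Write intervals as BED6
#'
#' Writes `chrom`, `start`, `end`, `name`, `score`, `strand`. Reading a valid
#' BED6 file with [read_peaks()] and writing it back reproduces the
#' coordinate and name fields byte-identically.
#'
#' @param x peak-set tibble.
#' @param path output path.
#' @param score_from column used for the BED score field; `"score"` (default)
#'   or `"signal"`.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(x, path, score_from = c("score", "signal")) {
  score_from <- match.arg(score_from)
  sc <- x[[score_from]]
  sc[is.na(sc)] <- 0
  nm <- x$name
  nm[is.na(nm)] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   x$chrom, x$start, x$end, nm,
                   format(sc, trim = TRUE, scientific = FALSE), x$strand)
  writeLines(lines, path)
  invisible(path)
}
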