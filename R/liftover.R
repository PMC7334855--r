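#' Parse a UCSC chain file into explicit alignment blocks
#'
#' A chain file describes a pairwise genome alignment as colinear ungapped
#' blocks. Each chain header carries the source (`t`) and target (`q`)
#' sequence, size, strand and span; data lines are `size dt dq` triples
#' (gap in source / gap in target after the block) with a final bare `size`.
#' Blocks on a negative target strand are converted so that target
#' coordinates are on the forward strand, with the strand recorded.
#'
#' @param path chain file path.
#' @return A tibble of blocks with columns `chain_id`, `score`, `src_chrom`,
#'   `src_start`, `src_end`, `tgt_chrom`, `tgt_start`, `tgt_end`,
#'   `tgt_strand` (all coordinates 0-based half-open, forward strand).
#' @export
parse_chain <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- stringr::str_trim(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    # an empty file is a valid chain set covering nothing
    return(tibble::tibble(chain_id = character(), score = numeric(),
                          src_chrom = character(), src_start = numeric(),
                          src_end = numeric(), tgt_chrom = character(),
                          tgt_start = numeric(), tgt_end = numeric(),
                          tgt_strand = character()))
  }
  headers <- which(startsWith(lines, "chain"))
  if (length(headers) == 0) abort(paste0("no chain headers in ", path))
  out <- vector("list", length(headers))
  ends <- c(headers[-1] - 1L, length(lines))
  for (ci in seq_along(headers)) {
    h <- stringr::str_split_1(lines[headers[ci]], "\\s+")
    if (length(h) < 12) {
      abort(sprintf("chain header %d of %s has %d fields; expected >= 12",
                    ci, path, length(h)))
    }
    score <- as.numeric(h[2])
    src_chrom <- h[3]; src_size <- as.numeric(h[4]); src_strand <- h[5]
    src_from <- as.numeric(h[6]); src_to <- as.numeric(h[7])
    tgt_chrom <- h[8]; tgt_size <- as.numeric(h[9]); tgt_strand <- h[10]
    tgt_from <- as.numeric(h[11]); tgt_to <- as.numeric(h[12])
    chain_id <- if (length(h) >= 13) h[13] else as.character(ci)
    if (src_strand != "+") {
      abort(sprintf("chain %s: source strand must be '+'", chain_id))
    }
    body <- lines[seq.int(headers[ci] + 1L, ends[ci])]
    body <- body[nzchar(body)]
    if (length(body) == 0) abort(sprintf("chain %s has no data lines", chain_id))
    parts <- stringr::str_split(body, "\\s+")
    np <- lengths(parts)
    if (any(np[-length(np)] != 3) || np[length(np)] != 1) {
      abort(sprintf(
        "chain %s: data lines must be 'size dt dq' with a final bare size",
        chain_id))
    }
    size <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    dt <- c(vapply(parts[-length(parts)], function(p) as.numeric(p[2]),
                   numeric(1)), 0)
    dq <- c(vapply(parts[-length(parts)], function(p) as.numeric(p[3]),
                   numeric(1)), 0)
    if (anyNA(size) || anyNA(dt) || anyNA(dq)) {
      abort(sprintf("chain %s: non-numeric data line", chain_id))
    }
    if (sum(size) + sum(dt) != src_to - src_from ||
        sum(size) + sum(dq) != tgt_to - tgt_from) {
      abort(sprintf(
        "chain %s: block sums inconsistent with header span", chain_id))
    }
    src_start <- src_from + cumsum(c(0, head(size + dt, -1)))
    tgt_start_strand <- tgt_from + cumsum(c(0, head(size + dq, -1)))
    if (tgt_strand == "-") {
      tgt_start_fwd <- tgt_size - (tgt_start_strand + size)
      tgt_end_fwd <- tgt_size - tgt_start_strand
    } else {
      tgt_start_fwd <- tgt_start_strand
      tgt_end_fwd <- tgt_start_strand + size
    }
    out[[ci]] <- tibble::tibble(
      chain_id = chain_id,
      score = score,
      src_chrom = src_chrom,
      src_start = src_start,
      src_end = src_start + size,
      tgt_chrom = tgt_chrom,
      tgt_start = tgt_start_fwd,
      tgt_end = tgt_end_fwd,
      tgt_strand = tgt_strand
    )
  }
  dplyr::bind_rows(out)
}

# vectorized core: per-peak lift decisions against a block table.
# Returns one row per input interval with status, target and mapped_fraction.
lift_intervals <- function(iv, chains, min_map_ratio = 0.5,
                           max_span_factor = 2) {
  stopifnot(min_map_ratio > 0, min_map_ratio <= 1)
  n <- nrow(iv)
  res <- tibble::tibble(
    chrom = iv$chrom, start = iv$start, end = iv$end,
    status = rep("unmapped", n),
    tgt_chrom = NA_character_, tgt_start = NA_real_, tgt_end = NA_real_,
    tgt_strand = NA_character_, mapped_fraction = 0
  )
  if (n == 0 || nrow(chains) == 0) return(res)
  q <- GenomicRanges::GRanges(iv$chrom,
                              IRanges::IRanges(iv$start + 1L, iv$end))
  s <- GenomicRanges::GRanges(chains$src_chrom,
                              IRanges::IRanges(chains$src_start + 1,
                                               chains$src_end))
  hits <- GenomicRanges::findOverlaps(q, s)
  if (length(hits) == 0) return(res)
  pi <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  ov <- tibble::tibble(
    peak = pi,
    chain_id = chains$chain_id[bi],
    score = chains$score[bi],
    ov_start = pmax(iv$start[pi], chains$src_start[bi]),
    ov_end = pmin(iv$end[pi], chains$src_end[bi]),
    src_start = chains$src_start[bi],
    tgt_chrom = chains$tgt_chrom[bi],
    tgt_b_start = chains$tgt_start[bi],
    tgt_b_end = chains$tgt_end[bi],
    tgt_strand = chains$tgt_strand[bi]
  )
  # map each overlapped source piece into target coordinates
  ov <- dplyr::mutate(
    ov,
    piece_tgt_start = ifelse(.data$tgt_strand == "+",
                             .data$tgt_b_start + (.data$ov_start - .data$src_start),
                             .data$tgt_b_end - (.data$ov_end - .data$src_start)),
    piece_tgt_end = ifelse(.data$tgt_strand == "+",
                           .data$tgt_b_start + (.data$ov_end - .data$src_start),
                           .data$tgt_b_end - (.data$ov_start - .data$src_start)),
    ov_bp = .data$ov_end - .data$ov_start
  )
  per_chain <- ov |>
    dplyr::group_by(.data$peak, .data$chain_id) |>
    dplyr::summarise(
      ov_bp = sum(.data$ov_bp),
      score = .data$score[1],
      n_tgt = dplyr::n_distinct(paste(.data$tgt_chrom, .data$tgt_strand)),
      tgt_chrom = .data$tgt_chrom[1],
      tgt_strand = .data$tgt_strand[1],
      tgt_start = min(.data$piece_tgt_start),
      tgt_end = max(.data$piece_tgt_end),
      .groups = "drop"
    )
  best <- per_chain |>
    dplyr::group_by(.data$peak) |>
    dplyr::arrange(dplyr::desc(.data$ov_bp), dplyr::desc(.data$score),
                   .data$chain_id, .by_group = TRUE) |>
    dplyr::summarise(
      total_bp = sum(.data$ov_bp),
      ov_bp = .data$ov_bp[1],
      n_tgt = .data$n_tgt[1],
      tgt_chrom = .data$tgt_chrom[1],
      tgt_strand = .data$tgt_strand[1],
      tgt_start = .data$tgt_start[1],
      tgt_end = .data$tgt_end[1],
      .groups = "drop"
    )
  len <- (iv$end - iv$start)[best$peak]
  frac <- best$ov_bp / len
  span_ok <- (best$tgt_end - best$tgt_start) <= max_span_factor * len
  mapped <- frac >= min_map_ratio & best$n_tgt == 1 & span_ok
  split <- !mapped & ((best$total_bp / len >= min_map_ratio) |
                        (frac >= min_map_ratio))
  res$mapped_fraction[best$peak] <- frac
  res$status[best$peak] <- ifelse(mapped, "mapped",
                                  ifelse(split, "split_rejected", "unmapped"))
  ok <- best$peak[mapped]
  res$tgt_chrom[ok] <- best$tgt_chrom[mapped]
  res$tgt_start[ok] <- best$tgt_start[mapped]
  res$tgt_end[ok] <- best$tgt_end[mapped]
  res$tgt_strand[ok] <- best$tgt_strand[mapped]
  res
}

#' Map one interval through an alignment chain set
#'
#' Intersects the interval with the blocks of every chain, keeps the chain
#' with the most overlapped bases, and accepts the lift when that chain
#' covers at least `min_map_ratio` of the interval on a single target
#' chromosome and strand. The target is the minimal interval spanning the
#' mapped pieces; a spanning interval longer than `max_span_factor` times the
#' source is rejected as a split. Pieces scattered over chains with no
#' dominant one are reported `split_rejected`; insufficient coverage is
#' `unmapped`. An empty chain set gives `unmapped`, not an error.
#'
#' @param chrom,start,end the source interval (0-based half-open).
#' @param chains block tibble from [parse_chain()].
#' @param min_map_ratio minimal mapped fraction of the source (default 0.5).
#' @param max_span_factor maximal target-span inflation (default 2).
#' @return One-row tibble: source coordinates, `status` (`mapped`,
#'   `unmapped`, `split_rejected`), target coordinates (`NA` unless mapped)
#'   and `mapped_fraction`.
#' @export
map_interval <- function(chrom, start, end, chains, min_map_ratio = 0.5,
                         max_span_factor = 2) {
  iv <- tibble::tibble(chrom = chrom, start = as.integer(start),
                       end = as.integer(end))
  validate_intervals(dplyr::mutate(iv, strand = ".", signal = NA_real_))
  lift_intervals(iv, chains, min_map_ratio, max_span_factor)
}

#' Transfer a peak set between genomes
#'
#' Applies [map_interval()] to every peak; mapped peaks keep their signal,
#' name and sample metadata with target coordinates substituted. Every input
#' peak appears in exactly one row of the lift report.
#'
#' @param peaks peak-set tibble.
#' @param chains block tibble from [parse_chain()].
#' @param min_map_ratio,max_span_factor see [map_interval()].
#' @return A list with `mapped` (peak-set tibble on the target genome) and
#'   `results` (per-peak lift report).
#' @export
transfer_peaks <- function(peaks, chains, min_map_ratio = 0.5,
                           max_span_factor = 2) {
  res <- lift_intervals(peaks, chains, min_map_ratio, max_span_factor)
  ok <- res$status == "mapped"
  mapped <- peaks[ok, ]
  mapped$chrom <- res$tgt_chrom[ok]
  mapped$start <- as.integer(res$tgt_start[ok])
  mapped$end <- as.integer(res$tgt_end[ok])
  list(mapped = mapped, results = res)
}

#' Transfer efficiency of a lift
#'
#' Fraction of input peaks whose status is `mapped`. With `bp_weighted = TRUE`
#' the fraction is of source base pairs in mapped peaks instead of peak
#' counts.
#'
#' @param results lift report from [transfer_peaks()] or [map_interval()].
#' @param bp_weighted weight peaks by their length.
#' @return A number in \[0, 1\].
#' @export
transfer_efficiency <- function(results, bp_weighted = FALSE) {
  if (nrow(results) == 0) abort("empty lift report")
  if (bp_weighted) {
    len <- results$end - results$start
    sum(len[results$status == "mapped"]) / sum(len)
  } else {
    mean(results$status == "mapped")
  }
}
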