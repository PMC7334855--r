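# fixtures are built in code; tests silence the package logger
options(tissuemark.quiet = TRUE)

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# identity chain: one block covering [0, len) of chromosome `s` onto `t`
identity_chain <- function(len = 1000, src = "s", tgt = "t") {
  parse_chain(write_tmp(c(
    sprintf("chain 100 %s %d + 0 %d %s %d + 0 %d 1", src, len, len, tgt,
            len, len),
    sprintf("%d", len), ""
  ), ".chain"))
}

tiny_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    start = c(5000L, 20000L, 40000L),
    end = c(9000L, 28000L, 41500L),
    strand = c("+", "-", "+"),
    biotype = "protein_coding"
  )
}

tiny_gwas <- function(stats, chrom = "chr1", spacing = 10L) {
  m <- length(stats)
  as_gwas_table(tibble::tibble(
    marker_id = sprintf("m%03d", seq_len(m)), chrom = chrom,
    pos = spacing * seq_len(m), stat = stats
  ), unique(chrom))
}

# independent oracle: pooled equal-variance two-sample t on a partition
pooled_t_oracle <- function(y, tested) {
  y1 <- y[tested]; y0 <- y[!tested]
  n1 <- length(y1); n0 <- length(y0)
  sp2 <- (sum((y1 - mean(y1))^2) + sum((y0 - mean(y0))^2)) / (n1 + n0 - 2)
  (mean(y1) - mean(y0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

# independent oracle: brute-force circular rotation null by explicit loop
brute_rotation_p <- function(stats, indices, m, summand = function(x) x^2) {
  v <- summand(stats)
  T_obs <- sum(v[indices + 1])
  null_T <- numeric(m - 1)
  for (k in seq_len(m - 1)) {
    s <- 0
    for (i in indices) s <- s + v[((i + k) %% m) + 1]
    null_T[k] <- s
  }
  (sum(null_T >= T_obs) + 1) / (m - 1 + 1)
}
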