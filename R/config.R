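#' Run configuration
#'
#' Bundles the constants used across the pipeline. The defaults are the
#' values used throughout the analyses this package supports: promoter
#' windows from 1000 bp upstream to 500 bp downstream of the TSS, gene
#' bodies only for genes of at least 750 bp, top 5% of features called
#' tissue-specific, 10,000 circular permutations for the enrichment null,
#' and an FDR threshold of 0.05.
#'
#' @param promoter_up bp upstream of the TSS included in the promoter window.
#' @param promoter_down bp downstream of the TSS included in the promoter window.
#' @param min_gene_len minimum gene length (bp) for gene-body features.
#' @param top_fraction fraction of features (by descending t) called specific.
#' @param n_perm number of circular permutations for the enrichment null.
#' @param seed integer seed governing all stochastic steps.
#' @param fdr_alpha FDR threshold used to star significant cells.
#'
#' @return A list with class `run_config`.
#' @export
#' @examples
#' cfg <- run_config(seed = 1)
#' cfg$top_fraction
run_config <- function(promoter_up = 1000L,
                       promoter_down = 500L,
                       min_gene_len = 750L,
                       top_fraction = 0.05,
                       n_perm = 10000L,
                       seed = 1L,
                       fdr_alpha = 0.05) {
  stopifnot(promoter_up >= 0, promoter_down >= 0, min_gene_len >= 0)
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    abort("`top_fraction` must lie in (0, 1].")
  }
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  if (!(fdr_alpha > 0 && fdr_alpha < 1)) abort("`fdr_alpha` must lie in (0, 1).")
  structure(
    list(
      promoter_up = as.integer(promoter_up),
      promoter_down = as.integer(promoter_down),
      min_gene_len = as.integer(min_gene_len),
      top_fraction = top_fraction,
      n_perm = as.integer(n_perm),
      seed = as.integer(seed),
      fdr_alpha = fdr_alpha
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Unknown keys raise an error so that typos in configuration files do not
#' silently fall back to defaults.
#'
#' @param path path to a YAML file whose top-level keys are arguments of
#'   [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("configuration file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("unknown configuration keys: ", paste(extra, collapse = ", ")))
  }
  do.call(run_config, raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
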