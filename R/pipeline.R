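#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate -> liftover -> aggregate -> specificity ->
#' enrichment -> correlate from a single configuration and writes every
#' stage's outputs plus a provenance manifest. In demo mode (the default
#' when the configuration carries a `simulation` block and no input paths)
#' all inputs are generated first with the synthetic module. Stages whose
#' inputs are not configured are skipped with a log line. All stochastic
#' stages are seeded from the configuration, so re-running an identical
#' configuration reproduces identical outputs and an identical manifest.
#'
#' The configuration is a YAML file (or list) with blocks:
#' \describe{
#'   \item{run}{arguments of [run_config()] (seed, n_perm, ...).}
#'   \item{simulation}{arguments of [simulation_spec()] minus `seed`
#'     (demo mode), or absent when real inputs are given.}
#'   \item{inputs}{paths: `peaks` (list of narrowPeak files + metadata),
#'     `genes`, `chain`, `gwas` (named TSVs), `chrom_order`.}
#'   \item{stages}{logical switches: `liftover`, `methylation`,
#'     `expression`, `enrichment`, `correlate` (all default `TRUE` in demo
#'     mode when their inputs exist).}
#' }
#'
#' @param config path to a YAML configuration or an equivalent list.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly: a list with the configuration snapshot,
#'   per-stage output paths and md5 digests, seeds and package version.
#' @export
run_pipeline <- function(config, out_dir = "tissuemark_run") {
  cfg_list <- if (is.character(config)) yaml::read_yaml(config) else config
  run <- do.call(run_config, cfg_list$run %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  stage <- function(name, expr) {
    tm_log("stage: ", name)
    tryCatch(expr, error = function(e) {
      marker <- file.path(out_dir, paste0(name, ".failed"))
      writeLines(conditionMessage(e), marker)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  demo <- !is.null(cfg_list$simulation)
  if (demo) {
    sim_args <- cfg_list$simulation
    sim_args$seed <- sim_args$seed %||% run$seed
    spec <- do.call(simulation_spec, sim_args)
    genes <- stage("simulate_genes", generate_genome_annotation(spec))
    pk <- stage("simulate_peaks", generate_peak_samples(spec, genes))
    chain_path <- file.path(out_dir, "alignment.chain")
    ch <- stage("simulate_chain", generate_chain_file(spec, chain_path))
    paths["chain"] <- chain_path
    genes_path <- file.path(out_dir, "genes.tsv")
    readr::write_tsv(genes, genes_path, progress = FALSE)
    paths["genes"] <- genes_path
  } else {
    inputs <- cfg_list$inputs
    if (is.null(inputs)) abort("configuration has neither simulation nor inputs")
    genes <- stage("read_genes",
                   read_gene_annotation(inputs$genes,
                                        inputs$genes_format %||% "tsv"))
    pk <- list(
      samples = purrr::map(inputs$peaks, function(p) {
        read_peaks(p$path, p$dialect %||% "narrowPeak",
                   sample_id = p$sample_id, tissue = p$tissue, mark = p$mark)
      }),
      truth = NULL
    )
    spec <- NULL
  }

  # liftover: map peaks through the chain onto the target genome, then pull
  # them back for aggregation against the (source-coordinate) annotation in
  # demo mode. The transfer report is the stage output of record.
  chains <- NULL
  if (demo || !is.null(cfg_list$inputs$chain)) {
    chain_file <- if (demo) paths[["chain"]] else cfg_list$inputs$chain
    chains <- stage("parse_chain", parse_chain(chain_file))
    lift <- stage("liftover", {
      all_peaks <- dplyr::bind_rows(pk$samples)
      transfer_peaks(all_peaks, chains)
    })
    lift_path <- file.path(out_dir, "lift_report.tsv")
    readr::write_tsv(lift$results, lift_path, progress = FALSE)
    paths["lift_report"] <- lift_path
    eff <- transfer_efficiency(lift$results)
    tm_log(sprintf("transfer efficiency: %.3f", eff))
  } else {
    tm_log("no chain configured; liftover skipped")
    eff <- NA_real_
  }

  # aggregation + histone specificity on the source-coordinate peaks
  windows <- promoter_windows(genes, run$promoter_up, run$promoter_down)
  cmap <- if (demo) pk$truth$class_map else NULL
  sm <- stage("aggregate",
              build_signal_matrix(pk$samples, windows, "promoter",
                                  class_map = cmap))
  write_signal_matrix(sm, file.path(out_dir, "signal_matrix.tsv"),
                      file.path(out_dir, "signal_samples.tsv"))
  paths["signal_matrix"] <- file.path(out_dir, "signal_matrix.tsv")
  spec_res <- stage("specificity", specificity_matrix(sm))
  readr::write_tsv(spec_res, file.path(out_dir, "specificity_histone.tsv"),
                   progress = FALSE)
  paths["specificity_histone"] <- file.path(out_dir, "specificity_histone.tsv")
  tissues <- unique(sm$samples$tissue)
  top_sets <- purrr::map(setNames(tissues, tissues), function(tt) {
    select_top_fraction(spec_res, tt, run$top_fraction, windows)
  })
  for (tt in tissues) {
    write_top_features_bed(top_sets[[tt]],
                           file.path(out_dir, paste0("top_", tt, ".bed")))
  }

  # expression stage (demo mode generates the matrix)
  spec_expr <- NULL
  if (demo) {
    ex <- stage("expression", generate_expression_matrix(spec, genes, pk$truth))
    std <- standardize_expression(ex$expression)
    spec_expr <- specificity_matrix(std, covariates = ex$covariates)
    readr::write_tsv(spec_expr,
                     file.path(out_dir, "specificity_expression.tsv"),
                     progress = FALSE)
    paths["specificity_expression"] <-
      file.path(out_dir, "specificity_expression.tsv")
  }

  # enrichment stage: demo plants each trait in one tissue's top regions;
  # otherwise GWAS summary TSVs are read from the configuration
  profile <- NULL
  gwas_tables <- NULL
  if (demo) {
    traits <- setNames(tissues, paste0("trait_", tissues))
    regions <- purrr::map(traits, function(tt) {
      top_sets[[tt]][, c("chrom", "start", "end")]
    })
    gw <- stage("simulate_gwas", generate_gwas_summary(spec, regions))
    gwas_tables <- gw$gwas
  } else if (!is.null(cfg_list$inputs$gwas)) {
    gwas_tables <- stage("read_gwas_summary", {
      purrr::imap(cfg_list$inputs$gwas, function(p, trait) {
        read_gwas_summary(p, cfg_list$inputs$chrom_order, trait = trait)
      })
    })
  }
  if (!is.null(gwas_tables)) {
    profile <- stage("enrichment",
                     enrichment_profile(gwas_tables, purrr::map(top_sets, ~.x),
                                        cfg = run))
    readr::write_tsv(tibble::as_tibble(profile),
                     file.path(out_dir, "enrichment_profile.tsv"),
                     progress = FALSE)
    paths["enrichment_profile"] <- file.path(out_dir, "enrichment_profile.tsv")
  } else {
    tm_log("no GWAS configured; enrichment skipped")
  }

  # concordance stage
  if (!is.null(spec_expr)) {
    conc <- stage("correlate", modality_correlation(spec_res, spec_expr))
    readr::write_tsv(conc, file.path(out_dir, "modality_correlation.tsv"),
                     progress = FALSE)
    paths["modality_correlation"] <- file.path(out_dir,
                                               "modality_correlation.tsv")
  }

  manifest <- list(
    tool = "tissuemark",
    version = as.character(utils::packageVersion("tissuemark")),
    config = cfg_list,
    seed = run$seed,
    transfer_efficiency = eff,
    outputs = purrr::imap(paths, function(p, nm) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  tm_log("pipeline complete: ", out_dir)
  invisible(manifest)
}
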