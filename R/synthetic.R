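#' Simulation specification
#'
#' Collects every constant the synthetic-data generators use, so that no
#' distributional choice is hard-coded in a generator. Defaults describe a
#' small multi-tissue design: 10 tissues with 5 peak samples each over 1000
#' genes on 2 chromosomes, tissue-specific features planted at an effect of
#' 3 within-group standard deviations, 2000 evenly spaced GWAS markers with
#' planted regional enrichment shifting the marker statistic mean by 2, and
#' alignment chains covering 80% of the source genome. Two tissues share an
#' exclusion class to exercise same-class exclusion.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length, bp.
#' @param n_genes number of protein-coding genes.
#' @param n_tissues number of tissues.
#' @param samples_per_tissue peak samples per tissue.
#' @param n_specific_per_tissue planted specific features per tissue;
#'   default 4% of `n_genes`.
#' @param effect_delta planted specificity effect, in within-group sd units.
#' @param noise_sd sdlog of the lognormal background peak signal.
#' @param rho_modality target cross-modality t correlation in \[0, 1).
#' @param n_markers number of GWAS markers.
#' @param enrich_delta mean shift of marker statistics inside planted regions.
#' @param chain_coverage fraction of the source genome covered by chains.
#' @param n_shared_class_tissues leading tissues sharing one exclusion class.
#' @param ar1_phi AR(1) coefficient for local correlation of marker
#'   statistics (0 = independent).
#' @param seed integer seed (mandatory); every generator derives its
#'   randomness from it.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_chrom = 2L, chrom_len = 5e6, n_genes = 1000L,
                            n_tissues = 10L, samples_per_tissue = 5L,
                            n_specific_per_tissue = NULL, effect_delta = 3,
                            noise_sd = 0.5, rho_modality = 0.6,
                            n_markers = 2000L, enrich_delta = 2,
                            chain_coverage = 0.8,
                            n_shared_class_tissues = 2L, ar1_phi = 0,
                            seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  n_specific_per_tissue <- n_specific_per_tissue %||%
    max(1L, round(0.04 * n_genes))
  stopifnot(n_chrom >= 1, chrom_len > 0, n_genes >= 0, n_tissues >= 1,
            samples_per_tissue >= 1, effect_delta >= 0, noise_sd > 0,
            n_markers >= 2, chain_coverage >= 0, chain_coverage <= 1,
            abs(ar1_phi) < 1)
  if (!(rho_modality >= 0 && rho_modality < 1)) {
    abort("`rho_modality` must lie in [0, 1)")
  }
  structure(
    list(n_chrom = as.integer(n_chrom), chrom_len = as.integer(chrom_len),
         n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
         samples_per_tissue = as.integer(samples_per_tissue),
         n_specific_per_tissue = as.integer(n_specific_per_tissue),
         effect_delta = effect_delta, noise_sd = noise_sd,
         rho_modality = rho_modality, n_markers = as.integer(n_markers),
         enrich_delta = enrich_delta, chain_coverage = chain_coverage,
         n_shared_class_tissues = as.integer(n_shared_class_tissues),
         ar1_phi = ar1_phi, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

sim_chroms <- function(spec) sprintf("chr%d", seq_len(spec$n_chrom))

#' Tissue labels and exclusion-class map of a simulation
#' @param spec a [simulation_spec()].
#' @return Tibble with `tissue` and `class`; the first
#'   `n_shared_class_tissues` tissues share class `"shared"`.
#' @export
sim_class_map <- function(spec) {
  tissue <- sprintf("T%02d", seq_len(spec$n_tissues))
  class <- tissue
  k <- min(spec$n_shared_class_tissues, spec$n_tissues)
  if (k >= 2) class[seq_len(k)] <- "shared"
  tibble::tibble(tissue = tissue, class = class)
}

# slot geometry: genes live in 8 kb slots, started >= 1.5 kb into the slot,
# so neighbouring promoter windows (1 kb up / 0.5 kb down) never overlap.
SIM_SLOT <- 8000L

#' Generate a non-overlapping gene annotation
#'
#' Genes of length uniform in \[1000, 5000\] bp with random strand, packed
#' into fixed slots so genes and their promoter windows never overlap.
#' Deterministic under the spec seed.
#'
#' @param spec a [simulation_spec()].
#' @return Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype`).
#' @export
generate_genome_annotation <- function(spec) {
  slots_per_chrom <- spec$chrom_len %/% SIM_SLOT
  if (spec$n_genes > slots_per_chrom * spec$n_chrom) {
    abort(sprintf("cannot pack %d genes into %d slots; increase chrom_len",
                  spec$n_genes, slots_per_chrom * spec$n_chrom))
  }
  if (spec$n_genes == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), biotype = character()))
  }
  withr::with_seed(spec$seed + 1L, {
    slot <- sort(sample.int(slots_per_chrom * spec$n_chrom, spec$n_genes))
    chrom_i <- (slot - 1L) %/% slots_per_chrom + 1L
    slot_start <- ((slot - 1L) %% slots_per_chrom) * SIM_SLOT
    len <- sample(1000:5000, spec$n_genes, replace = TRUE)
    offset <- 1500L + vapply(5000L - len, function(room) {
      if (room == 0) 0L else sample.int(room + 1L, 1L) - 1L
    }, integer(1))
    strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
    tibble::tibble(
      gene_id = sprintf("g%05d", seq_len(spec$n_genes)),
      chrom = sim_chroms(spec)[chrom_i],
      start = slot_start + offset,
      end = slot_start + offset + len,
      strand = strand,
      biotype = "protein_coding"
    )
  })
}

# planted-feature assignment: disjoint gene sets per tissue
sim_planted_features <- function(spec, genes) {
  need <- spec$n_specific_per_tissue * spec$n_tissues
  if (need > nrow(genes)) {
    abort("n_specific_per_tissue x n_tissues exceeds n_genes")
  }
  withr::with_seed(spec$seed + 11L, {
    picked <- sample(genes$gene_id, need)
    split(picked, rep(sim_class_map(spec)$tissue,
                      each = spec$n_specific_per_tissue))
  })
}

# lognormal moments used to convert effect_delta (in within-group sd units)
# into the multiplicative planting factor applied to planted peak signals
lognormal_planting_factor <- function(effect_delta, noise_sd) {
  mu <- exp(noise_sd^2 / 2)
  s <- sqrt((exp(noise_sd^2) - 1) * exp(noise_sd^2))
  1 + effect_delta * s / mu
}

#' Generate per-sample peak sets with planted tissue-specific signal
#'
#' Every sample carries a background peak at every gene promoter with
#' signal drawn from Lognormal(0, `noise_sd`) and boundaries jittered by
#' up to 200 bp. In a tissue's planted features the signal is multiplied by
#' a factor chosen from the lognormal moments so that the expected shift
#' equals `effect_delta` within-group standard deviations.
#'
#' @param spec a [simulation_spec()].
#' @param genes gene tibble from [generate_genome_annotation()].
#' @return List with `samples` (list of peak-set tibbles) and `truth`
#'   (list: `specific_features` per tissue, `class_map`, `planting_factor`).
#' @export
generate_peak_samples <- function(spec, genes) {
  cmap <- sim_class_map(spec)
  planted <- if (spec$effect_delta > 0) sim_planted_features(spec, genes)
    else setNames(rep(list(character(0)), spec$n_tissues), cmap$tissue)
  win <- promoter_windows(genes)
  factor_planted <- lognormal_planting_factor(spec$effect_delta, spec$noise_sd)
  samples <- withr::with_seed(spec$seed + 2L, {
    purrr::flatten(purrr::map(seq_len(spec$n_tissues), function(ti) {
      tt <- cmap$tissue[ti]
      purrr::map(seq_len(spec$samples_per_tissue), function(si) {
        jit1 <- sample(-200:200, nrow(win), replace = TRUE)
        jit2 <- sample(-200:200, nrow(win), replace = TRUE)
        sig <- stats::rlnorm(nrow(win), 0, spec$noise_sd)
        sig[win$gene_id %in% planted[[tt]]] <-
          sig[win$gene_id %in% planted[[tt]]] * factor_planted
        peak_set(
          tibble::tibble(
            chrom = win$chrom,
            start = pmax(win$start + jit1, 0L),
            end = win$end + jit2,
            name = paste0(tt, "_s", si, "_", win$gene_id),
            score = 0L, strand = ".", signal = sig
          ),
          sample_id = sprintf("%s_s%d", tt, si), tissue = tt,
          mark = "H3K4me3"
        )
      })
    }))
  })
  list(samples = samples,
       truth = list(specific_features = planted, class_map = cmap,
                    planting_factor = factor_planted))
}

#' Write a synthetic alignment chain file
#'
#' Tiles every chromosome with 10 kb units whose leading
#' `chain_coverage` fraction is an aligned block and the remainder a gap;
#' target coordinates are the source shifted by a constant per chromosome
#' onto a renamed target chromosome. `chain_coverage = 1` yields an
#' identity-up-to-shift chain; `chain_coverage = 0` writes a file with no
#' chains (nothing maps).
#'
#' @param spec a [simulation_spec()].
#' @param path output chain file path.
#' @return List with `path` and `truth` (tibble of gap intervals on the
#'   source genome — deliberately unmappable regions).
#' @export
generate_chain_file <- function(spec, path) {
  tile <- 10000L
  block <- as.integer(round(spec$chain_coverage * tile))
  chroms <- sim_chroms(spec)
  lines <- character(0)
  gaps <- list()
  if (block > 0) {
    for (ci in seq_along(chroms)) {
      n_tiles <- spec$chrom_len %/% tile
      shift <- ci * 100000L
      src_span <- (n_tiles - 1L) * tile + block
      header <- sprintf("chain %d %s %d + 0 %d %s %d + %d %d %d",
                        1000L, chroms[ci], spec$chrom_len, src_span,
                        paste0("tgt_", chroms[ci]),
                        spec$chrom_len + 200000L * spec$n_chrom, shift,
                        shift + src_span, ci)
      gap <- tile - block
      body <- c(rep(sprintf("%d %d %d", block, gap, gap), n_tiles - 1L),
                sprintf("%d", block))
      lines <- c(lines, header, body, "")
      if (gap > 0) {
        tile_starts <- (seq_len(n_tiles) - 1L) * tile
        gaps[[ci]] <- tibble::tibble(chrom = chroms[ci],
                                     start = tile_starts + block,
                                     end = tile_starts + tile)
      }
    }
  } else {
    gaps[[1]] <- tibble::tibble(chrom = chroms, start = 0L,
                                end = spec$chrom_len)
  }
  writeLines(lines, path)
  list(path = path, truth = dplyr::bind_rows(gaps))
}

#' Generate a log2FPKM expression matrix with planted specificity
#'
#' Gene baselines are Normal(5, 2); a tissue's planted expression-specific
#' genes get `effect_delta` added (within-group residual sd is 1). The
#' expression-planted set of a tissue overlaps the histone-planted set
#' (`truth$specific_features`): each histone-planted gene is co-planted with
#' probability `w` derived from the closed form below, and fresh genes top
#' the set up to the same size, so the realized correlation of
#' tissue-specificity t-statistics between the two modalities targets
#' `rho_modality`.
#'
#' Closed form: with planted fraction `f`, planted t around
#' `tau = delta * sqrt(n1 n0 / n)` and unit-variance null t, the
#' between-modality correlation of t-vectors under co-planting fraction `w`
#' is approximately `w * sqrt(c_h c_e)` with `c = f tau^2 / (1 + f tau^2)`
#' (the planted component's share of the t variance); hence
#' `w = rho / sqrt(c_h c_e)`, clipped to 1.
#'
#' @param spec a [simulation_spec()].
#' @param genes gene tibble.
#' @param truth truth list from [generate_peak_samples()].
#' @return List with `expression` (a `signal_matrix` of log2FPKM),
#'   `covariates` (tibble: `sex`, `study` per sample) and `truth`
#'   (expression-planted features per tissue, co-planting fraction).
#' @export
generate_expression_matrix <- function(spec, genes, truth) {
  cmap <- truth$class_map
  f <- spec$n_specific_per_tissue / spec$n_genes
  n1 <- spec$samples_per_tissue
  shared <- cmap$class == "shared"
  w_by_tissue <- vapply(seq_len(spec$n_tissues), function(ti) {
    excl <- if (shared[ti]) sum(shared) else 1L
    n0 <- (spec$n_tissues - excl) * spec$samples_per_tissue
    tau2 <- spec$effect_delta^2 * n1 * n0 / (n1 + n0)
    cc <- f * tau2 / (1 + f * tau2)
    if (spec$rho_modality == 0 || cc == 0) 0 else
      min(1, spec$rho_modality / cc)
  }, numeric(1))
  n_samples <- spec$n_tissues * spec$samples_per_tissue
  sample_meta <- tibble::tibble(
    sample_id = sprintf("rna_%s_s%d",
                        rep(cmap$tissue, each = spec$samples_per_tissue),
                        rep(seq_len(spec$samples_per_tissue), spec$n_tissues)),
    tissue = rep(cmap$tissue, each = spec$samples_per_tissue),
    class = rep(cmap$class, each = spec$samples_per_tissue)
  )
  withr::with_seed(spec$seed + 4L, {
    planted_e <- purrr::map(seq_len(spec$n_tissues), function(ti) {
      tt <- cmap$tissue[ti]
      hist_set <- truth$specific_features[[tt]]
      keep <- hist_set[runif(length(hist_set)) < w_by_tissue[ti]]
      n_fresh <- length(hist_set) - length(keep)
      pool <- setdiff(genes$gene_id, unlist(truth$specific_features))
      c(keep, if (n_fresh > 0) sample(pool, n_fresh))
    })
    names(planted_e) <- cmap$tissue
    base <- rnorm(spec$n_genes, 5, 2)
    study <- sample(c("A", "B"), n_samples, replace = TRUE)
    sex <- sample(c("F", "M"), n_samples, replace = TRUE)
    study_effect <- matrix(rnorm(spec$n_genes * 2, 0, 0.3), ncol = 2,
                           dimnames = list(NULL, c("A", "B")))
    E <- matrix(base, spec$n_genes, n_samples) +
      matrix(rnorm(spec$n_genes * n_samples), spec$n_genes) +
      study_effect[, study]
    for (ti in seq_len(spec$n_tissues)) {
      cols <- sample_meta$tissue == cmap$tissue[ti]
      rows <- genes$gene_id %in% planted_e[[ti]]
      E[rows, cols] <- E[rows, cols] + spec$effect_delta
    }
    rownames(E) <- genes$gene_id
    colnames(E) <- sample_meta$sample_id
    list(
      expression = signal_matrix(E, sample_meta, kind = "expression",
                                 mark = "RNA"),
      covariates = tibble::tibble(sex = sex, study = study),
      truth = list(expression_features = planted_e,
                   co_plant_fraction = w_by_tissue)
    )
  })
}

#' Generate per-CpG methylation counts with planted hypomethylation
#'
#' Two WGBS samples per tissue; each gene promoter carries 10 evenly spaced
#' CpGs with coverage Poisson(10) (floored at 1). Promoters of a tissue's
#' planted features are hypomethylated in that tissue (levels Beta(2, 8))
#' and methylated elsewhere (Beta(8, 2)); non-planted promoters are
#' methylated everywhere.
#'
#' @param spec a [simulation_spec()].
#' @param genes gene tibble.
#' @param truth truth list from [generate_peak_samples()].
#' @param samples_per_tissue WGBS samples per tissue (default 2).
#' @return CpG tibble across all samples (see [read_methylation_counts()]).
#' @export
generate_methylation_data <- function(spec, genes, truth,
                                      samples_per_tissue = 2L) {
  cmap <- truth$class_map
  win <- promoter_windows(genes)
  n_cpg <- 10L
  cpg_pos <- function(w) {
    # 1-based positions of n_cpg evenly spaced CpGs inside the window
    round(seq(w["start"] + 1, w["end"], length.out = n_cpg))
  }
  pos_mat <- t(apply(cbind(start = win$start, end = win$end), 1, cpg_pos))
  withr::with_seed(spec$seed + 5L, {
    out <- purrr::map(seq_len(spec$n_tissues), function(ti) {
      tt <- cmap$tissue[ti]
      hypo <- win$gene_id %in% truth$specific_features[[tt]]
      purrr::map(seq_len(samples_per_tissue), function(si) {
        level <- ifelse(hypo, rbeta(nrow(win), 2, 8), rbeta(nrow(win), 8, 2))
        total <- pmax(1L, rpois(nrow(win) * n_cpg, 10))
        lv <- rep(level, times = n_cpg)
        meth <- rbinom(length(total), total, lv)
        tibble::tibble(
          chrom = rep(win$chrom, times = n_cpg),
          pos = as.integer(pos_mat),
          meth_reads = meth, total_reads = total,
          sample_id = sprintf("wgbs_%s_s%d", tt, si), tissue = tt
        )
      })
    })
    dplyr::bind_rows(purrr::flatten(out))
  })
}

#' Generate GWAS summary statistics with planted regional enrichment
#'
#' Markers are evenly spaced over the simulated genome with baseline
#' statistics Normal(0, 1) (or an AR(1) process when `ar1_phi` is nonzero);
#' markers inside a trait's planted regions get mean `enrich_delta`. A
#' planted region containing no marker is an error.
#'
#' @param spec a [simulation_spec()].
#' @param regions_by_trait named list of region tibbles
#'   (`chrom`, `start`, `end`); an empty-region trait is a pure null.
#' @return List with `gwas` (named list of GWAS tibbles) and `truth`
#'   (planted marker indices per trait).
#' @export
generate_gwas_summary <- function(spec, regions_by_trait) {
  chroms <- sim_chroms(spec)
  per_chrom <- spec$n_markers %/% spec$n_chrom
  extra <- spec$n_markers %% spec$n_chrom
  marker_df <- purrr::map_dfr(seq_along(chroms), function(ci) {
    k <- per_chrom + (ci <= extra)
    tibble::tibble(
      chrom = chroms[ci],
      pos = as.integer(round(seq(1, spec$chrom_len, length.out = k)))
    )
  })
  marker_df$marker_id <- sprintf("m%06d", seq_len(nrow(marker_df)))
  base <- as_gwas_table(dplyr::mutate(marker_df, stat = 0), chroms)
  planted_idx <- purrr::imap(regions_by_trait, function(regions, trait) {
    if (is.null(regions) || nrow(regions) == 0) return(integer(0))
    set <- build_marker_set(base, regions)
    if (set$n_set == 0) {
      abort(paste0("planted regions for trait '", trait,
                   "' contain no marker"))
    }
    # also require every individual region to hit a marker
    r <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start + 1L,
                                                 regions$end))
    p <- GenomicRanges::GRanges(base$chrom,
                                IRanges::IRanges(base$pos, base$pos))
    cov <- GenomicRanges::countOverlaps(r, p)
    if (any(cov == 0)) {
      abort(sprintf("%d planted region(s) for trait '%s' contain no marker",
                    sum(cov == 0), trait))
    }
    set$indices
  })
  gwas <- withr::with_seed(spec$seed + 6L, {
    purrr::imap(regions_by_trait, function(regions, trait) {
      m <- nrow(base)
      if (spec$ar1_phi != 0) {
        stat <- as.numeric(stats::arima.sim(
          list(ar = spec$ar1_phi), m,
          sd = sqrt(1 - spec$ar1_phi^2)))
      } else {
        stat <- rnorm(m)
      }
      stat[planted_idx[[trait]] + 1L] <-
        stat[planted_idx[[trait]] + 1L] + spec$enrich_delta
      g <- base
      g$stat <- stat
      g$trait <- trait
      g
    })
  })
  list(gwas = gwas, truth = list(planted_indices = planted_idx))
}
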