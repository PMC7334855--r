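Package: tissuemark
Title: Tissue-Specific Histone Marks, Cross-Genome Peak Transfer, and
    GWAS Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative epigenomics at the level of summary data:
    transfer histone-mark peak sets between genomes through pairwise alignment
    chain files; aggregate peak signal into strand-aware promoter windows or
    length-adjusted gene bodies; score tissue specificity of histone signal,
    expression, or promoter methylation with a +/-1-coded linear-model
    t-statistic with same-class sample exclusion; test enrichment of GWAS or
    selection-scan statistics in tissue-specific regions with a sum-based
    marker-set statistic against a circular-rotation null; and compare
    tissue-enrichment profiles across data modalities and traits. A synthetic
    data module generates all inputs with planted ground truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
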