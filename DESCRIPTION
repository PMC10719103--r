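Package: merfishkit
Title: Analysis Toolkit for Whole-Brain MERFISH Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control, normalization, reference integration and spatial
    statistics for multiplexed error-robust fluorescence in situ hybridization
    (MERFISH) cell-by-gene data. Implements error-robust barcode codebook
    construction (constant-weight-4, Hamming-distance-4 Steiner quadruple
    systems), marker gene panel selection by differential expression screening
    and greedy completion, five-step cell quality filtering and volume
    normalization, anchor-based label transfer and transcriptome imputation
    against a clustered single-cell reference via canonical correlation
    co-embedding, neurotransmitter and regional-enrichment annotation,
    weighted-neighborhood spatial module detection, spatial gradient
    statistics, proximity-based cell-cell interaction testing against
    local-randomization nulls, and ligand-receptor upregulation screens.
    A synthetic-data generator with known ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    readr,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
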