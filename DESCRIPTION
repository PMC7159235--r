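Package: enhtol
Title: Loss-of-Function Tolerance Scoring for Human Enhancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates loss-of-function (LoF) tolerant and low-LoF-tolerance
    enhancer training sets from whole-genome deletion calls and ultraconserved
    elements, builds an integrated heterogeneous enhancer-gene regulatory
    network ("MegaNet"), derives network feature vectors per enhancer
    (out-degree, tissue ubiquity, edge tissue ubiquity, target-gene in-degree,
    centralities and indispensability aggregates, per-tissue blocks,
    conservation), trains a balanced-resampling random-forest classifier with
    stratified cross-validation and a null-model overfitting check, and emits
    genome-wide LoF-tolerance probabilities together with downstream validation
    statistics (tissue enrichment, score-distribution comparisons, discovery
    curves, disease-enhancer matching, motif enrichment). Includes a seeded
    synthetic-data generator that emulates all required inputs with
    controllable class signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    igraph,
    jsonlite,
    pROC,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
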