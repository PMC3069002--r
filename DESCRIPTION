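Package: mlsaCore
Title: Core Housekeeping-Gene Selection for Multilocus Sequence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects a core housekeeping-gene set for multilocus sequence
    analysis (MLSA) of bacterial clades such as the Actinobacteridae.
    Screens candidate genes for length, ubiquity, single-copy status and
    genomic linkage; profiles alignment variability in sliding windows to
    locate conserved primer-binding flanks around hypervariable
    identification targets; designs degenerate IUPAC consensus primers and
    evaluates them by in-silico PCR; computes whole-genome conserved-region
    similarity from maximal unique match (MUM) anchors with length-weighted
    identity; fits quadratic regressions predicting genome conserved
    relatedness from gene-fragment similarity and ranks genes by R-squared;
    and builds neighbor-joining trees under the Kimura two-parameter model
    with bootstrap node support. A fully specified synthetic-genome
    simulator (known tree, per-gene rates, accessory DNA, planted primer
    flanks, engineered decoys) makes every stage testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
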