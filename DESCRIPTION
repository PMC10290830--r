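Package: gapmotif
Title: Gapped N-mer Motif Models for Core Promoter Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Combinatorial gapped n-mer motif models for short core promoter
    elements (TATA box, initiator): model catalogs with anchored (32) and full
    binary (64) numbering, count/probability/log-odds matrices and joint
    tuple tables built from aligned binding sites, real-versus-scrambled (RZ)
    discrimination scoring at percentile thresholds, a position weight matrix
    scanner with exact enumeration p-values, positive-predictive-value
    threshold selection, true-hit-ratio evaluation and leave-parts-out
    cross-validation trials, and a Monte Carlo test for pairwise nucleotide
    interdependency within aligned sites. Includes synthetic-data generators
    (sites with optional planted pairwise coupling, promoters with planted
    sites on a biased background) so every stage is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
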