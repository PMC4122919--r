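Package: mitopopcons
Title: Detecting Purifying Selection from Ultradense Mitochondrial Polymorphism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting purifying selection and calling functional
    elements in a small circular genome from ultradense within-species
    polymorphism. Implements a two-state hidden Markov model over per-site
    distinct-allele counts with fixed transitions and emission-only Baum-Welch
    training ('mitoPopCons'-style element calling), correction of
    replication-driven mutational bias (single-stranded duration D_ssH) via a
    Poisson generalized linear model, rank-correlation analyses of polymorphism
    against between-species divergence at site, window, gene and codon-class
    resolution, a permutation test for genomic interval overlap, allele-count
    downsampling for sample-size power analysis, and a synthetic-data generator
    emulating a mitochondrial-like genome so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    methods,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
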