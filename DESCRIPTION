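Package: cdr3tools
Title: T Cell Receptor CDR3 Profiling from Bulk RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, extraction, benchmarking and repertoire analytics for
    T cell receptor (TCR) CDR3 clonotypes recovered from bulk RNA-seq reads.
    Provides an in silico V(D)J recombination simulator with configurable
    junction models, generators for positive-control, decoy and
    expression-weighted read sets, a read-level CDR3 caller with tunable
    minimum V/J alignment stringency, an unbiased (minV, minJ) parameter-grid
    optimizer scored against positive and negative controls, a logistic model
    of CDR3 detection probability as a function of transcript abundance,
    sequencing depth, read length and CDR3 length, and repertoire-sharing
    statistics (tumor/normal overlap, alpha-beta pair co-occurrence
    randomization, greedy CDR3 clustering and peptide-MHC sharing resampling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
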