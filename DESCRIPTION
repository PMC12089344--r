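Package: RepliFit
Title: Kinetic Modelling of Genome-Wide DNA Replication Timing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers per-site DNA replication origin firing rates from
    Repli-seq-style replication timing profiles at 1-kb resolution using a
    closed-form expectation for replication time under exponential origin
    firing and constant-speed bidirectional forks. Provides an iterative
    multiplicative fitting scheme, an event-driven stochastic simulator of
    replication (fork directionality, inter-origin distances, replicon
    lengths), conversion of ENCODE-style wavelet signals and cumulative
    S-phase fraction matrices to timing, and detection of misfit regions
    where observed timing deviates from the constant-fork-speed model,
    with annotation-overlap and track-correlation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    minpack.lm,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Software, Epigenetics, Coverage, Sequencing, MathematicalBiology
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'grid.R'
    'core-model.R'
    'synthetic.R'
    'repliseq-io.R'
    'misfit.R'
    'simulator.R'
    'fitting.R'
    'cli.R'
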