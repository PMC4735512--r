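Package: polyclust
Title: Chromatin Polymer Simulation and Nanoscale Cluster Analysis for
    Polycomb Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how self-association of Polycomb group
    proteins shapes nuclear protein clusters and chromatin topology. Provides
    a lattice Monte-Carlo simulator of the strings-and-binders chromatin
    polymer model with diffusing binders that spread on chromatin nodes and
    bridge distant nodes, including weak-binding and oligomer-capping mutant
    mechanisms and limited/unlimited spreading; connected-component cluster
    calling, size statistics and two-channel colocalization for
    single-molecule localization (STORM) tables; 4C-seq viewpoint-track
    normalization with near/far contact quantification, changed-window
    flagging and nearest-peak distances; and seeded synthetic-data
    generators with planted ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    nortest,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
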