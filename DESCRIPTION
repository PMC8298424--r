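Package: RLoopCycle
Title: Cell-Cycle-Resolved R-Loop and DNA-Damage Landscape Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide comparison of strand-specific DNA-RNA hybrid
    (DRIPc-seq) and DNA-damage (gamma-H2A ChIP-seq) landscapes between
    conditions and cell-cycle phases in small genomes. Provides a two-state
    negative-binomial hidden Markov model peak caller with replicate
    consensus, TMM-normalised differential R-loop-gain classification,
    RPKM coverage and oriented metaprofiles with a damage asymmetry index,
    head-on versus codirectional transcription-replication conflict
    analysis around replication origins, and a synthetic-data generator
    that plants labelled ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    edgeR,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Epigenetics, PeakDetection, DifferentialPeakCalling, Coverage,
    HiddenMarkovModel, Sequencing
RoxygenNote: 7.3.3
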