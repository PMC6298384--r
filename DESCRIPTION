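Package: nanoamplikit
Title: Consensus Correction and Partition-Based OTU Clustering for Nanopore Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-basecalling workflow for full-length 16S rRNA gene amplicon
    sequencing from rolling-circle concatemer consensus reads on the nanopore
    platform. Implements chopSeq-style read correction (degenerate-primer
    localisation in both orientations, circular-permutation re-orientation,
    sliding-window tandem-repeat detection and removal, size selection) and
    nanoClust-style read-partitioning de novo OTU clustering (per-partition
    dereplication, chimera screening and greedy 97% clustering, best-partition
    selection, full-length read recruitment, multiple alignment and majority
    consensus calling). Includes a calibrated simulator of concatemer-consensus
    reads with circular permutation, tandem-repeat insertions and
    deletion-dominated, homopolymer-biased errors, plus reference-based accuracy
    and OTU-recovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
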