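Package: ampliswarm
Title: Generalised Fastidious Swarm Clustering of Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Exact, alignment-based de novo clustering of dereplicated
    amplicons into operational taxonomic units (OTUs). OTUs are grown
    iteratively from abundance-ranked seeds with a small local threshold and
    an optional abundance-monotone breaking rule, then optionally refined by
    a generalised fastidious step that grafts light OTUs onto heavy ones
    through virtual linking amplicons at an independent threshold. Candidate
    pairs are generated with a pigeonhole segment filter over inverted
    indices (even partitions, multimatch-aware substring selection, a
    bidirectional second stage) and confirmed by bounded, length-aware
    verification, either as plain edit distance or as the difference count
    of an optimal affine-gap alignment. Includes a mock-community simulator
    with ground truth, pair-counting precision/recall and the adjusted Rand
    index, Swarm-compatible output formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
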