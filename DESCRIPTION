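Package: pirnaphase
Title: Signatures of Phased piRNA Biogenesis from Small RNA and Degradome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify the sequence signatures of
    trigger-piRNA-initiated, phased piRNA biogenesis from small RNA
    sequencing and 5'-monophosphorylated long RNA (degradome) sequencing.
    Implements split-UMI adapter parsing and PCR-duplicate removal,
    spike-in calibrated absolute quantification, a desk-scale ungapped
    aligner with non-templated 3'-tail detection, 5'-5' overlap spectra
    with the Z10 standard score, pre-pre-piRNA identification at
    transposon-insertion junctions, phasing metaplots with
    autocorrelation-based period estimation, positional nucleotide
    composition (1U/10A biases), Mann-Whitney abundance comparisons and
    delta-delta-Ct calculations with error propagation. Includes a
    truth-tagged generative simulator of the biogenesis model so that
    every pipeline stage can be verified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    Rcpp,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
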