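Package: armiso
Title: Arm-Resolved Evolutionary and IsomiR Expression Analysis of MicroRNAs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing mature microRNAs by their arm of origin on the
    pre-miRNA hairpin (miR-#-5p versus miR-#-3p): parsing miRBase-dialect
    FASTA, locating matures on hairpins and classifying 5p/3p arms; length,
    nucleotide, homopolymer-run and positional composition statistics with the
    corresponding two-group tests; cross-species shared-family discovery,
    reference-anchored alignment, per-position transition/transversion/indel
    divergence profiles, and nucleotide diversity statistics (pi, Hd, k) with
    Nei (1987) sampling variances; within-locus isomiR extraction and
    quantification from collapsed small-RNA reads (RPM, relative expression,
    cross-sample dispersion); seed extraction, seed-shift detection and
    seed-match target-overlap statistics; plus a fully seeded synthetic-data
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
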