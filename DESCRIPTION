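Package: h2avariants
Title: Signature-Based Classification and Characterization of Histone H2A Variants
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to annotate the histone-fold anatomy of H2A candidate proteins,
    extract the diagnostic sequence features used to distinguish H2A variant
    classes (replication-coupled H2A, H2A.X, H2A.Z, H2A.E, H2A.O, H2A.N, H2A.W,
    H2A.M and macroH2A), and assign variant labels through an explicit,
    auditable decision procedure. Supporting evidence layers cover Jalview-style
    consensus and conservation profiles, gene-context analysis (intron counts,
    histone gene-cluster detection, anchored micro-synteny comparison with
    break annotation), TPM-level expression filtering with tissue-specificity
    calls, modified-peptide assignment, and a neighbor-joining monophyly sanity
    check. A synthetic-data module generates labelled protein sets with planted
    signatures, gene neighborhoods with planted synteny breaks, and expression
    matrices with planted patterns, so every stage is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
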