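Package: ChargeSeq
Title: Sequencing-Based Quantification of tRNA Aminoacylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying tRNA aminoacylation ("charging") per
    isodecoder from periodate-protection sequencing libraries. Builds a
    deduplicated, CCA-appended tRNA reference from GtRNAdb-style FASTA,
    simulates oxidized and control read libraries and qPCR Ct tables from a
    ground-truth charging profile, assigns reads to isodecoders with a
    deterministic 3'-anchored one-mismatch matcher and an explicit
    multimapping policy, computes spike-in-normalized charge ratios and
    delta-delta-Ct charged fractions, and provides polyglutamine tract
    scanning together with -1 ribosomal frameshift reporter construction
    and reading-frame analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
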