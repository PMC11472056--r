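Package: seedscreen
Title: Duplex Melting Thermodynamics and Seed-Mediated siRNA Off-Target
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how chemical modification of siRNA
    duplexes affects hybridization thermodynamics and seed-mediated
    off-target gene repression. Implements the two-state duplex melting
    model with van't Hoff estimation of enthalpy and entropy from the
    concentration dependence of melting temperature, melting-curve Tm
    extraction, ribose sugar-pucker estimation from proton J-couplings,
    7-mer/8-mer seed-complement scanning of 3'UTR sequence sets,
    quantile normalization and QC filtering of expression tables, and
    rank-sum comparison of seed-matched versus non-seed-matched
    log2 fold-change distributions (MA and cumulative-distribution
    summaries). A fully seeded synthetic-data generator produces melting
    curves, UTR sets with planted seed matches, expression matrices with
    seed-dependent knockdown, and reporter/qPCR assay tables with truth
    labels for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    limma,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
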