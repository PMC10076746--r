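Package: triodx
Title: Trio Genomic Diagnosis with Expression-Based Dosage Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-variant-calling diagnostic triage for autism spectrum
    disorder (ASD) trio cohorts. Classifies de novo protein-truncating
    single-nucleotide variants, matches copy-number variants (CNVs) against a
    catalog of known syndromic regions by reciprocal overlap, validates
    candidate CNVs and truncating variants against peripheral-blood RNA-seq
    dosage signatures (in-CNV versus resampled out-CNV gene sets, per-gene
    cohort z-scores and log2 fold changes), confirms copy number by qBase-style
    efficiency-corrected qPCR relative quantification, and reports cohort-level
    diagnostic yields. Includes a fully synthetic trio-cohort generator so
    every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
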