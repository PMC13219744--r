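Package: sqamp
Title: Functional-Gene Amplicon Analysis for the Sulfoquinovosidase Marker yihQ
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for functional-gene amplicon assays targeting the
    sulfoquinovosidase gene yihQ (glycoside hydrolase family 31). Evaluates
    degenerate primer pairs against reference nucleotide databases by
    in-silico PCR, verifies amplicon sequence variants (ASVs) by six-frame
    translation and protein homology filtering, places candidate peptides on
    a fixed reference tree by maximum-likelihood evolutionary placement with
    jplace export, clusters verified ASVs into OTUs at a fixed identity
    threshold, computes subsampled alpha diversity, assigns best-hit
    taxonomy with a hard identity floor, and tests differential abundance
    between conditions with a simplified negative-binomial Wald test. A
    synthetic-data generator emulates reference bundles, primer sites,
    error-bearing amplicons and multi-sample count tables so that the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    withr,
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
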