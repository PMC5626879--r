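Package: srnaedit
Title: Chloroplast RNA Editing Detection and Quantification from Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies chloroplast RNA editing (C-to-U in coding
    sequences, A-to-I in tRNAs) from small-RNA sequencing reads. Implements a
    hierarchical, strand-specific, mismatch-bounded read partition against
    chloroplast, nuclear and mitochondrial references, feature-space pileups
    with a terminal-mismatch filter, binomial variant calling of editing
    sites, confirmation of externally predicted sites, editing-rate
    quantification from allele-specific qPCR Ct values, and a deterministic
    tri-genome read simulator with planted editing sites and truth tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb,
    jsonlite,
    optparse
Config/testthat/edition: 3
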