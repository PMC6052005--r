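Package: gapfillr
Title: Pseudo-De Novo Assembly of Unmapped Reads and Reference Gap Closure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines the read pairs that fail to map to a reference genome for
    novel sequence. Unaligned pairs are quality-trimmed and triaged, assembled
    per sample and then pooled per group (pseudo-de novo assembly with singlet
    exclusion), screened for contigs already present verbatim in the reference,
    placed on the genome from one-end-anchored read pairs, verified by local
    realignment, and intersected with assembly gaps and gene models to count
    closed gaps, filled bases, and genic-gap classes. A synthetic-data module
    generates a reference with N-run gaps, a donor genome carrying planted
    insertions, and simulated paired-end reads, so every stage is testable
    against a machine-readable ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
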