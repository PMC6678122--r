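Package: seedmir
Title: Small RNA Profiling of Developing Seeds: miRNA Discovery,
    Expression Trends and Target Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for bulk small-RNA
    sequencing of developing seeds sampled over successive developmental
    phases. Raw reads are filtered and adapter-trimmed, collapsed to
    unique tags, screened against a contaminant ncRNA reference, and
    matched exactly against a mature plant miRNA reference to call
    conserved miRNAs. Hairpin precursors are recovered from a unigene
    transcriptome and evaluated with a bundled deterministic single-stem
    nearest-neighbour folding engine (MFE, AMFE, MFEI); unannotated tags
    are screened for novel miRNAs under explicit hairpin criteria.
    Expression is normalised as transcripts per million with a 0.01
    floor, differential miRNAs are called by fold-change and Welch
    P-value thresholds and classified into phase trends (bell, V,
    monotone), targets are predicted under positional complementarity
    rules with G:U wobble half-penalties and a duplex MFE-ratio filter,
    and target sets are tested for GO/KEGG over-representation with
    hypergeometric tests under Benjamini-Hochberg FDR control. A
    synthetic-data generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    stringi,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
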