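Package: circorf
Title: Coding Potential, Terminus Novelty and Differential Expression of
    Circular RNAs
Version: 0.1.0
Authors@R:
    person("circorf", "maintainers", email = "circorf@example.org",
           role = c("aut", "cre"))
Description: Identifies circular RNAs (circRNAs) that potentially encode
    proteins with a novel primary structure or a novel domain composition,
    and flags those differentially expressed in cancer. Provides a
    backsplice-record selection and circular splicing stage, a circular
    open-reading-frame caller that handles junction-crossing and
    rolling-circle frames, Smith-Waterman based classification of N- and
    C-terminus novelty against cognate linear proteins, domain-architecture
    comparison, a quantile-normalisation plus Wilcoxon/Benjamini-Hochberg
    differential-expression stage, Fisher-exact over-representation and
    interval-overlap utilities, and a synthetic-data generator that plants
    machine-readable ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
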