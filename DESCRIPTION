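Package: rrbsim
Title: In-Silico RRBS Design and Reduced-Representation Methylome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing reduced representation bisulfite
    sequencing (RRBS) experiments. Simulates MspI (C|CGG) digestion of a genome,
    builds the size-selected reduced-representation (RR) genome with enrichment
    and feature-capture statistics, calls per-CpG methylation levels from
    bisulfite count data with conversion-rate QC, computes TSS-anchored and
    metagene methylation profiles, detects CpG islands, classifies promoters
    into high- and low-CpG classes via a two-component Gaussian mixture, and
    calls differentially methylated cytosines and regions between two samples
    with a beta-binomial Wald test. A synthetic-data module generates genomes,
    gene models and bisulfite counts with planted structure so every stage is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors,
    methods,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
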