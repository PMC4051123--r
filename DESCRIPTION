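Package: cnvpop
Title: Population-Level Analysis of Deleted Copy Number Variants in Two Breeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for downstream population analysis of deletion-type copy
    number variant (CNV) genotype tables, as produced by population-scale
    callers such as Genome STRiP. Given per-sample deletion genotypes (0/0,
    0/1, 1/1) for two breeds, the package computes call-set summaries, gene
    deletion scores with normal-fit tail probabilities, QTL deletion density
    ("average distance between deletions"), Nei heterozygosity-based F_ST
    selection scans with Benjamini-Hochberg FDR control, and breed-specific
    CNV calls. A synthetic-data generator with Hardy-Weinberg genotype
    sampling and planted ground truth supports testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
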