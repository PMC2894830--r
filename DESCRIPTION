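Package: dupliPIN
Title: Duplicability of Self-Interacting Genes in Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for the relationship between gene duplicability
    and protein self-interaction in a protein interaction network with
    self-loops. Classifies genes as singleton, duplicate or ambiguous from
    all-against-all similarity hits or from human-mouse ortholog cardinality,
    partitions duplicates into whole-genome (WGD) versus small-scale (SSD)
    duplicates via an ohnolog list, tests self-interaction against any binary
    gene partition with Yates-corrected chi-square statistics and odds ratios,
    performs degree-stratified analyses (equal-frequency degree bins, logistic
    regression of WGD membership on degree, Ks-binned mean connectivity), and
    runs simulation-based GO-slim term enrichment with hypergeometric p-values
    and Bonferroni correction. Includes a synthetic-data generator that plants
    configurable effect sizes so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
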