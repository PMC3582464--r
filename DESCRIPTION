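Package: mitophylo
Title: Phylogeographic Analysis of Human mtDNA Haplogroups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for phylogeographic analysis of human mitochondrial DNA
    haplogroups, built around the workflow used to study the North African
    clades M1 and U6. Provides a packaged mtDNA reference model with
    site-class annotation (control region, RNA genes, synonymous and
    non-synonymous coding positions), a parser for the RSRS-relative variant
    nomenclature used in haplogroup trees, median-joining network and rooted
    clade-tree construction, rho-statistic coalescent dating with Saillard
    standard errors under synonymous and purifying-selection-corrected
    clocks, regional haplogroup frequency tables, Slatkin-linearised FST,
    great-circle and binary language distance matrices with Mantel
    permutation tests, classical skyline estimation of effective population
    size through time, and a seeded Kingman-coalescent simulator with
    class-partitioned Poisson mutations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    igraph,
    geosphere,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
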