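Package: coumnet
Title: Attribute-Enhanced Network Analysis of Yeast p-Coumaric-Acid Stress
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-omics network analysis of the Saccharomyces cerevisiae
    response to p-coumaric acid stress in anaerobic chemostat culture.
    Builds an attribute-enhanced protein-protein interaction graph whose
    edge weights combine interaction confidence with log2 fold-change
    similarity, detects co-expressed gene clusters with a Markov clustering
    (MCL) implementation tuned by weighted modularity, identifies hub genes
    from four centrality metrics, labels clusters by hypergeometric term
    enrichment, associates genes with physiological phenotypes through a
    discretized Bayesian evidence score, classifies short variants by
    zygosity and predicted impact, and assembles a signed, directed
    multi-omics integration network (variant -> gene -> pathway/phenotype).
    Includes chemostat physiology arithmetic (specific rates, yields,
    percent and log2 changes) and a synthetic-data generator that emulates
    every pipeline input for fully reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
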