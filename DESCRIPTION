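Package: essMiner
Title: Literature Mining and Pangenome Partitioning for Essential-Gene
    Discovery in Sulfate-Reducing Bacteria
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A semi-automated workflow for nominating essential genes in a
    bacterial genome, modelled on the analysis of the sulfate reducer
    Oleidesulfovibrio alaskensis G20. The pipeline combines dictionary-based
    gene named-entity recognition over a literature corpus, mapping and
    deduplication of mined gene symbols onto the target genome,
    protein-protein-interaction subnetwork expansion with a degree-model
    enrichment test, and persistent/shell/cloud partitioning of gene-family
    presence/absence profiles by a multivariate Bernoulli mixture model
    fitted with EM and smoothed by a Markov-random-field prior over the
    family contiguity graph. A synthetic-data module generates corpora,
    scored interaction networks and planted-mixture pangenomes so every
    stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pheatmap,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Annotation, Network, Pangenomics, TextMining
RoxygenNote: 7.3.3
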