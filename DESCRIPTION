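Package: deggnet
Title: Differential Gene-Gene Interaction Networks from Bulk RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts subgroup-specific gene-gene interaction networks from
    log-scale bulk RNA-Seq expression and a curated interaction scaffold.
    Network nodes are weighted by mean subgroup expression, thresholded with
    a percolation scan, and edges unique to one subgroup are tested for
    differential interaction by robust (Huber M-estimator) linear regression
    with a group-by-gene interaction term. Significant pairs feed per-pair
    logistic models of binary treatment response with a gene-ratio
    (interaction) term, evaluated by ROC/AUC with and without the term.
    Includes greedy-modularity cluster detection with hypergeometric
    gene-set enrichment, readers and writers for TSV expression, SIF-like
    interaction tables, GMT gene sets and GraphML/JSON networks, and a
    synthetic-study generator with planted differential edges and a planted
    predictive pair for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    pROC,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
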