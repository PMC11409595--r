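Package: pldaCells
Title: Penalized Latent Dirichlet Allocation for Single-Cell RNA-Seq with
    Cell-Type and Age Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Topic modeling of single-cell RNA-seq count matrices by
    penalized latent Dirichlet allocation (pLDA), fitted by variational EM
    with a tuning parameter that shrinks per-gene topic frequencies toward
    homogeneity so that uninformative "stop-word" genes can be filtered.
    Includes fold-in inference of topic profiles for new cells with the
    topic-gene frequency matrix held fixed, a hierarchical support vector
    machine pipeline that predicts cell type and then, per type, age group
    from square-root transformed topic profiles, conditional hypergeometric
    gene-set enrichment per topic, evaluation utilities (confusion matrices,
    recall by age, learning curves), and a Dirichlet-multinomial simulator
    that plants cell types, marker genes, stop-word genes and age effects
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    e1071,
    fgsea,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
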