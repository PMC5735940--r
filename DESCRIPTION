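Package: grrann
Title: Gene-Regulatory-Network-Constrained Regularized Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Binary phenotype prediction from gene-expression profiles using a
    sparse single-hidden-layer neural network whose input-to-hidden
    connectivity is dictated by a gene regulatory network: input nodes are
    genes, hidden nodes are their upstream regulators, and a connection exists
    only where a regulatory interaction does. Training combines a ridge
    penalty on the gene-to-regulator weights with a group-lasso penalty on the
    regulator-to-output weights, scaled by the square root of each regulator's
    in-degree, so that inactive regulators and their whole gene sets are
    dropped from the model. Includes edge-list parsing and alignment with
    expression data, sign-filtered and randomized (ablation) architectures,
    proximal-gradient training with exact zeros, a lambda grid search,
    stratified cross-validation with balanced accuracy, bootstrap stability
    ranking of regulators, and a synthetic-data generator with planted active
    regulators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
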