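Package: mdvae
Title: miRNA-Disease Association Prediction with Variational Autoencoders
Version: 0.1.0
Authors@R:
    person("mdvae", "developers", email = "mdvae@example.org", role = c("aut", "cre"))
Description: Unsupervised prediction of miRNA-disease associations by matrix
    completion with variational autoencoders. Builds integrated miRNA and
    disease similarity matrices (MeSH-style DAG semantic similarity, Gaussian
    interaction profile kernels, functional-similarity fusion), splices them
    with the known-association adjacency matrix into two feature matrices,
    trains one variational autoencoder per side, and averages the two
    reconstructions into association scores. Includes leave-one-out,
    repeated k-fold and leave-one-disease-out cross-validation harnesses
    with rank-based ROC/AUC, a synthetic-data generator with planted
    low-rank structure for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
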