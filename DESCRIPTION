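Package: gimda
Title: Graphlet Interaction Based Prediction of miRNA-Disease Associations
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts candidate miRNA-disease associations from a known
    binary association matrix by scoring graphlet interactions between
    nodes of a miRNA similarity graph and a disease similarity graph
    (GIMDA). Implements DAG-based disease semantic similarity (two
    models), Gaussian interaction-profile kernel similarity, similarity
    integration, an exhaustively enumerated catalog of 2-4 node graphlets
    with their automorphism orbits and 28 ordered orbit-pair interaction
    isomers, a weighted isomer census with an independent brute-force
    oracle, closed-form ridge/least-squares fitting of isomer weights,
    global and local leave-one-out as well as k-fold cross-validation
    with ROC/AUC, and a block-structured synthetic benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
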