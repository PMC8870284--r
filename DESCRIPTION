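Package: eegnetage
Title: Graph-Theoretic Analysis and Classification of Aging EEG Functional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for studying age-related differences in EEG functional
    connectivity networks. Builds Pearson-correlation connectivity matrices from
    multichannel EEG epochs, thresholds them to fixed-density weighted or binary
    networks, and computes seven graph-theory measures (local and global
    efficiency, clustering coefficient, characteristic path length, node
    strength, node betweenness centrality, and degree assortativity). Group
    differences are assessed with Wilcoxon rank-sum tests, and cohorts are
    classified (middle-aged-like versus elderly-like) with K-nearest-neighbour,
    support-vector-machine and random-forest models under stratified 10-fold
    cross-validation scored by accuracy, sensitivity, specificity, Cohen's
    kappa, precision, F-score and AUC. Includes a synthetic multichannel EEG
    cohort generator with controllable group-dependent inter-channel coupling so
    the whole pipeline is testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    kernlab,
    randomForest,
    pROC,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
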