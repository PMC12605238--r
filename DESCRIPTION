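Package: mdgcn
Title: Multi-Domain Brain-Network Graph Convolutional Networks for
    Personalized Motor-Imagery Prediction from Cognitive EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts a subject's personalized motor-imagery (MI) action
    from cognitive-task EEG. Per-trial time-, frequency- and
    spatial-domain brain networks (absolute Pearson correlation,
    phase-locking value, and normalized Manhattan distance of common
    spatial pattern features) are built from 19-channel cognitive epochs
    and classified by a three-branch spectral graph convolutional
    network with majority voting over trials. Ground-truth strong/weak
    action labels come from a CSP + deep-neural-network left-vs-right MI
    decoding pipeline with ten-fold cross-validation. Includes a
    synthetic multi-channel EEG cohort generator, a
    leave-one-subject-out cross-validation harness, confusion-based
    metrics with Cohen's kappa, binarized clustering-coefficient network
    contrasts, and EDF import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
RoxygenNote: 7.3.3
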