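Package: crisprEssentials
Title: Context-Specific Essential Gene Labelling and Prediction from CRISPR Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised labelling of human genes as essential or not essential
    from CRISPR knockout gene-effect screens in user-defined contexts (tissues,
    diseases), and supervised prediction of those labels. Labels are derived per
    cell line by Otsu thresholding of the gene-effect score distribution and
    aggregated by mode, with a two-level mode yielding common essential genes and
    a set-difference yielding uncommonly context-specific ones; a second
    thresholding pass refines the not-essential class into almost-essential and
    strongly-not-essential genes. Prediction uses a splitting voting ensemble
    that partitions majority-class training samples across base learners and
    soft-votes by averaging probabilities, with node embeddings of a
    protein-protein interaction network (biased second-order random walks plus a
    skip-gram objective) among the features. Includes a repeated stratified
    cross-validation harness and synthetic data generators with planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ranger,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
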