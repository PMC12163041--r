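Package: topobrain
Title: Topological Signatures of Brain Dynamics from ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts topological signatures of brain dynamics from
    region-of-interest (ROI) time series: Takens delay embedding with
    mutual-information delay and false-nearest-neighbour dimension
    selection, Vietoris-Rips persistent homology in dimensions 0 and 1
    implemented from scratch, and persistence-landscape vectorisation on a
    shared grid. Downstream individual-difference analyses include
    cross-session connectome-style fingerprinting (globally and per
    network), penalised logistic group classification with cross-validated
    ROC/AUC, repeated cross-validated behavioural regression with paired
    comparison, and a permutation-tested canonical correlation analysis
    (CCA) linking topological features to behaviour, with per-ROI and
    per-network contribution summaries. A seeded synthetic multi-subject
    cohort generator with planted individual-specific loop geometry, group
    labels and brain-behaviour covariation makes the whole pipeline
    testable without access-restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    glmnet,
    pROC,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
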