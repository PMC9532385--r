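Package: metaHub
Title: Harmonized Meta-Analytic Mapping of Functional Connectome Hubs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Voxelwise identification of functional connectome hubs from
    multi-cohort connectivity-strength maps using DerSimonian-Laird
    random-effects meta-analysis with max-statistic permutation control of
    the family-wise error rate. Includes per-subject functional connectivity
    strength (FCS) computation, per-cohort general linear models adjusting
    for age and sex, cluster-extent thresholding and peak extraction,
    leave-one-cohort-out and hub-occurrence reproducibility analyses,
    seed-based connectivity profiling with hierarchical clustering,
    spatial-autocorrelation-preserving surrogate maps for valid spatial
    inference, and a balanced gradient-boosting / support-vector protocol
    relating hub topography to gene expression. A synthetic-data module
    generates multi-cohort inputs with known ground truth for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    RNifti,
    igraph,
    xgboost,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
biocViews: FunctionalConnectomics, StatisticalMethod, GeneExpression
RoxygenNote: 7.3.3
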