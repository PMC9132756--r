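Package: rbconn
Title: Voxel-Level Regularized Brain Connectivity for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates voxel-level functional connectivity from resting-state
    fMRI by ridge regression of each gray-matter voxel's time series on all
    remaining in-mask voxels, solved in the dual (Gram) form so that the
    p >> N regime is tractable (regularized brain connectivity, RBC).  Also
    implements the weighted global brain connectivity average (GBC) and a
    supervised principal-component ("non-redundant") connectivity estimator
    (NRC) for comparison, the Fisher variance-stabilising transform, and
    permutation-based group inference with threshold-free cluster enhancement
    (TFCE) and Freedman-Lane handling of nuisance covariates.  A synthetic
    4D cohort generator with known latent-network structure and planted group
    effects makes every estimator and the inference stack testable without
    external data.  A command-line interface covers the full pipeline from
    simulation to group maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
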