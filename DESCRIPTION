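Package: netlesion
Title: Lesion Network Topography and Outcome Modelling for Stroke Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating stroke lesion topography to functional
    outcome. Maps binary lesion masks onto vascular, resting-state-network
    and white-matter parcellations; estimates indirect functional
    disconnection by seeding the lesion into a normative voxel-wise
    connectome (with PCA-based lesion reshaping) and indirect structural
    disconnection from normative tract visitation maps; compares
    atlas-based Lasso predictions of 3-month disability (modified Rankin
    Scale) under leave-one-out cross-validation; and locates voxel-wise
    correlates of outcome with threshold-free cluster enhancement (TFCE)
    and max-statistic permutation family-wise error correction. Includes a
    synthetic-cohort generator with planted effect structure so the whole
    pipeline can be exercised end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
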