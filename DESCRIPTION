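Package: boldmvpa
Title: Multivoxel Pattern Decoding of Event-Related BOLD fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multivoxel pattern analysis (MVPA) of event-related
    functional MRI. Implements leave-one-run-out cross-validated linear
    support-vector-machine decoding of stimulus conditions from normalized
    BOLD response patterns within regions of interest, four-way
    classification by pairwise voting with confusion matrices, group-level
    permutation inference on classification accuracy, classifier-weight
    sensitivity maps with group F-statistics and 1-r map dissimilarity,
    univariate GLM characterization of contributing voxels, and region
    utilities (mask erosion, parcellation extraction, out-of-brain control
    regions). A companion simulator generates synthetic event-related BOLD
    datasets with condition-specific multivoxel patterns, double-gamma
    hemodynamic responses, linear drift and white noise, so that every
    stage of the pipeline can be validated without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
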