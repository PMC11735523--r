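Package: VesselVote
Title: Patch-Wise Detection of Intracranial Stenosis and Aneurysms in
    TOF-MRA-Like Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, patch-wise detection pipeline for intracranial
    atherosclerotic stenosis and saccular aneurysms on time-of-flight
    MR-angiography-like volumes. Provides synthetic vascular phantom
    generation on a circle-of-Willis region of interest, histogram-based
    fast fuzzy c-means vessel segmentation with small-cluster pruning,
    labelled 32x32x32-voxel patch sampling with flip/offset augmentation and
    hard-negative oversampling, a seeded 3-D residual patch classifier,
    stride-4 sliding-window inference with a probability-voting rule that
    converts adjacent positive windows into findings, and participant-level
    diagnostic metrics including prevalence-adjusted predictive values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    withr,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
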