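Package: glossMVPA
Title: Stereoscopic Gloss Stimuli and Multivoxel Pattern Analysis of
    Block-Design BOLD Responses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the visual cortex represents surface
    gloss from binocular and monocular cues.  Renders stereoscopic
    specular stimuli (mirror, painted, anti-mirror and flat disparity
    manipulations of a procedurally generated object under a spherical
    environment map) and monocular glossy/matte pairs via highlight
    rotation; simulates multi-subject block-design BOLD voxel time
    series with controllable representational structure; and implements
    the full multivoxel pattern-analysis chain: run-level quality
    control, t-contrast voxel selection, block-pattern extraction,
    leave-one-run-out linear support-vector decoding with balanced
    class weights, cross-decoding transfer, signal-detection d-prime
    indices, permutation-null thresholds, group statistics, and
    searchlight mapping with cluster-size thresholding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    jsonlite,
    RNifti,
    optparse
Config/testthat/edition: 3
biocViews: Software, Visualization, Classification, StatisticalMethod
RoxygenNote: 7.3.3
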