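Package: motionscrub
Title: Censoring, Concatenation and ICA Denoising for High-Motion Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Preprocessing and quality-control toolkit for resting-state fMRI
    sessions dominated by head motion, as encountered in young pediatric
    cohorts. Implements framewise-displacement (FD) volume censoring with run
    concatenation, field-of-view outlier rejection by per-volume brain-voxel
    counts, rigid-body realignment, per-volume intensity normalization,
    spatial independent component analysis with rule-based signal/noise
    component labeling and aggressive noise regression, and the QC-FD
    evaluation battery (temporal SNR, parcel-wise functional connectivity,
    edge-wise FD correlations with distance profiles, DVARS-FD regression,
    subject retention by threshold). Ships a synthetic multi-run BOLD phantom
    generator with known motion, artifacts, networks and field-of-view
    dropout so every stage can be validated against exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
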