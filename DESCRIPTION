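Package: navdecode
Title: Walking-Direction Decoding and Tuning-Precision Analysis for
    Virtual-Navigation fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for direction-selective
    multi-voxel fMRI signals recorded during free navigation in a circular
    virtual arena. Simulates the spatial-memory task (trajectories, object
    placement feedback trials, behavioural chance distributions), generates
    direction-tuned voxel time series with controllable tuning width, gain
    and noise, extracts consistent-walking direction events, performs
    within-session cross-validated multinomial logistic-regression decoding
    with class upsampling, balanced accuracy and permutation nulls, fits a
    discrete Gaussian precision model to classifier confusion functions,
    and provides group-level tests against chance with Bonferroni-Holm
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
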