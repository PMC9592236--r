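Package: wmalff
Title: White-Matter Low-Frequency Fluctuation Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxel-wise analysis of low-frequency BOLD fluctuations in cerebral
    white matter. Provides a synthetic two-group 4D BOLD phantom generator with
    planted band-limited amplitude deficits, resting-state preprocessing
    (volume trimming, detrending, Friston-24 plus CSF nuisance regression with
    motion-spike regressors, tissue-restricted smoothing), maximum-probability
    tissue labelling and group white-matter masks, ALFF and fALFF spectral
    amplitude maps with mALFF and z normalisation, two-sample voxel-wise
    inference with Gaussian random-field cluster-level correction and a
    permutation oracle, atlas-labelled cluster tables, clinical group
    comparisons, and a Q-learning classifier with linear value approximation
    evaluated by leave-one-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
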