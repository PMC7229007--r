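Package: pseudoCT
Title: Pseudo-CT Synthesis from Dual-Contrast MRI by Region-Wise Polynomial Regression
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxel-based synthesis of pseudo-CT volumes from two co-registered
    MRI contrasts. Training voxels are pooled per anatomical region (bony,
    soft, mixed), accumulated on an Nbin x Nbin grid over the joint
    (MR1, MR2) intensity plane, empty bins are imputed from their nearest
    filled neighbour, and a count-weighted bivariate polynomial (or a
    bilinear lookup alternative) maps intensities to Hounsfield units.
    Includes cohort intensity normalization, millimetre-margin region
    construction, a full error-decomposition framework (MAE, rms error,
    fit vs intra-bin spread components), point-to-point dose comparison,
    a leave-one-out cross-validation driver, and a synthetic multi-patient
    phantom generator so the whole pipeline can be tested without patient
    data. Volumes are read and written as NIfTI-1 files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
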