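Package: retinoconn
Title: Retinotopically Resolved V1-V2 Short-Association-Fiber Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for short association (U-) fiber
    connectivity between retinotopically defined primary (V1) and secondary
    (V2) visual cortex. Recovers eccentricity and polar-angle phase maps from
    phase-encoded fMRI runs, derives visual field sign maps and a six-segment
    parcellation of each area, filters streamline tractograms into 6x6
    connectivity and proximity (mean reciprocal length) matrices, and tests
    the retinotopic-connectivity hypothesis with a restricted sign-flip
    permutation t-test, intraclass-correlation and coefficient-of-variation
    reliability matrices, and a two-way repeated-measures ANOVA. A synthetic
    data generator produces retinotopic patches, phase-encoded BOLD runs,
    segment label volumes, U-shaped streamline sets and b=0 image series with
    known ground truth, so every stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
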