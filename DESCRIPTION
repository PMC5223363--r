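Package: connlife
Title: Adult-Lifespan Functional Connectivity of Resting-State fMRI Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reproducible pipeline for studying how within- and
    between-network resting-state functional connectivity changes across the
    adult lifespan. Starting from 4-D BOLD volumes in MNI space (real or
    simulated), the package performs spatial smoothing, temporal detrending
    and low-pass filtering, nuisance regression with optional global-signal
    regression, framewise-displacement and standardized-DVARS motion quality
    control, seed-sphere time-series extraction for 42 regions in seven
    intrinsic connectivity networks, per-subject Fisher r-to-z connectivity
    matrices, age-group difference matrices with false-discovery-rate
    correction, permutation-based voxelwise group tests, and a mixed-model
    ANCOVA with pre-planned multiplicity-corrected contrasts comparing
    young-to-middle versus middle-to-old connectivity transitions. A
    multi-center synthetic cohort generator with planted, age-group-dependent
    network covariance provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
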