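Package: oxymetr
Title: Multimodal NIRS-MRI Quantification of Cortical Oxidative Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cortical oxidative metabolism from combined broadband
    near-infrared spectroscopy (NIRS) and arterial spin labeling (ASL) MRI in
    mouse cohorts. Implements second-derivative chromophore quantification
    (deoxyhemoglobin, oxidized and reduced cytochrome c oxidase) with
    water-feature optical pathlength estimation, anoxia-pulse total
    hemoglobin calibration, tissue oximetry and CMRO2 via the modified Fick
    principle, single-compartment CASL perfusion quantification with
    variable-TR T1 mapping, and the cohort-level nonparametric statistics.
    Ships a synthetic cohort generator that emulates the raw data of a
    three-group (naive, adjuvant control, EAE) mouse study so that every
    pipeline stage can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    signal,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
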