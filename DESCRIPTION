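Package: cortiquant
Title: Quantification of Light-Induced Cortical Recruitment Kinetics in Fission Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify plasma-membrane recruitment and polarity-factor
    relocalization kinetics from multi-channel fluorescence time-lapse
    recordings of mixed fission-yeast cell populations. Implements
    background subtraction and photobleaching correction from co-imaged
    control cells, membrane-profile and peak extraction, saturating-exponential
    half-time fitting, tip-signal normalization and dual-channel ratios,
    kymographs and sum projections, together with a synthetic trace and
    time-lapse generator with known ground truth for validating the
    estimators by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
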