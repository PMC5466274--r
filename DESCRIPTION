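Package: solestrike
Title: Footstrike Pattern Detection from Insole Sensor Onset Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating a runner's footstrike pattern from the
    onset-time difference (OTD) between heel and toe force-sensing-resistor
    insole channels. Implements the laboratory reference measure (strike
    index, the centre-of-pressure position at initial contact as a
    percentage of foot length), a force-platform processing chain
    (zero-phase Butterworth low-pass filtering, stance segmentation,
    split-belt exclusion), foot-length normalisation of OTD, univariate
    agreement regression of strike index on OTD with surface-stratified
    models, inversion of fitted lines into classification time windows at
    the 33% and 66% strike-index boundaries, rearfoot/midfoot/forefoot
    classification with confusion-matrix agreement summaries, and a seeded
    synthetic-gait generator that emulates a 109-runner split-belt
    treadmill study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
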