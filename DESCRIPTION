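Package: flashear
Title: Dosimetry, Blood-Volume and Inflammation Analysis for Proton-FLASH Mouse-Ear Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for preclinical proton-FLASH skin studies on
    the mouse-ear model. Converts beam current, linear energy transfer and
    chopper pulse structure into peak and mean dose rates and irradiation
    durations; estimates the irradiated blood volume from traced vessel
    morphometry (static cylinder volumes plus entry-vein flow exchange) and
    derives blood fractions and mean blood dose; analyses longitudinal
    ear-swelling and ordinal inflammation scores with percent-reduction
    statistics and two-sample t-tests; performs delta-delta-Ct qPCR
    fold-change analysis of blood cytokines; and simulates synthetic cohorts,
    vessel traces and qPCR plates with known ground truth for validation.
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
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
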