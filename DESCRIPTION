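Package: ruckmet
Title: Metabolic Cost Prediction for Heavy Backpack Load Carriage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts steady-state metabolic rate (W per kg body mass) during
    standing and walking with heavy backpack loads using the LCDA backpacking
    equation, with extensions for grade and terrain. Includes indirect
    calorimetry from respiratory gas exchange with steady-state quality
    control, nonlinear model fitting with participant random intercepts,
    grouped k-fold cross-validation, equivalence (TOST) and agreement
    (concordance correlation) statistics with cluster bootstrap confidence
    intervals, comparator models (Pandolf, minimum-mechanics), and a
    synthetic study generator that emulates a heavy load-carriage protocol
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
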