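Package: winterbudget
Title: Energetics-Based Activity Budgets and Deviation Analysis for Winter Endotherms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the minimum daily activity time a winter-acclimatized
    endotherm needs to meet its energy-balance target from a
    Scholander-Irving energy budget (intake rate, activity multiplier,
    resting metabolism, thermal conductance, lower critical temperature,
    thermal-refuge quality, optional fat subsidy), quantifies deviations of
    observed accelerometry-derived activity from that prediction, attributes
    deviations to risk and energetic covariates with individual random
    intercepts fitted via 'lme4', summarizes diel patterns and
    inter-individual activity synchrony, and translates covariate effects
    back into daily energy (kJ). Includes a synthetic-data module that
    simulates winter weather series and two-species cohorts with known
    generative structure for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
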