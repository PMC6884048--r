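Package: oxydose
Title: Time-Weighted Hyperoxemia Dose and ICU Mortality Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying exposure to supraphysiologic arterial
    oxygen tension (hyperoxemia) from irregularly sampled arterial blood-gas
    series and relating it to ICU mortality. Computes a time-weighted
    hyperoxemia dose as the area of the PaO2 curve above a 13.3 kPa
    threshold via gap-aware linear interpolation, builds nested
    censoring-free cohorts over fixed exposure windows, fits spike-at-zero
    logistic models with restricted cubic splines and AIC-tuned ridge
    penalties on interaction terms, validates them with bootstrap optimism
    correction, and estimates counterfactual (zero-exposure) mortality risk
    by plug-in g-computation. Includes a fully specified synthetic ICU
    cohort generator so every stage is testable without patient data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
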