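Package: ipacuity
Title: Inverse-Problem Least-Squares Prediction of Best-Corrected Visual Acuity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predictive modelling of best-corrected visual acuity (BCVA) for
    cataract patients from seven clinical risk factors (age, BMI, mean arterial
    pressure, intraocular pressure, HbA1c, LDL-C and gender). Risk factors are
    min-max normalized to the dimensionless range [-1, +1], expanded into a
    design matrix of single factors, all pairwise interactions and a constant
    term, and fitted by closed-form least squares (the inverse problem
    algorithm). Includes coefficient-magnitude factor ranking, truncation and
    subsample ablations, percent-agreement statistics, a packaged reference
    model, and a synthetic cohort generator with planted-coefficient outcomes
    for parameter-recovery validation.
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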