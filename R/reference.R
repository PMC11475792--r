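#' Reference coefficient vector of the cataract BCVA model
#'
#' The published best-fitting coefficients of the 29-term formula for the
#' cataract reference cohort, aligned to the canonical term schema
#' (`a1`...`a29`: seven singles, twenty-one pairwise interactions, constant).
#' The coefficients act on normalized inputs and produce the outcome on the
#' normalized acuity scale.
#'
#' @return Named numeric vector of length 29.
#' @export
#' @examples
#' reference_coefficients()[c("a1", "a12", "a29")]
reference_coefficients <- function() {
  co <- c(
    # singles: age, bmi, map, iop, hba1c, ldl_c, gender
    a1 = -0.6798, a2 = -0.3452, a3 = 0.0780, a4 = -0.2852,
    a5 = 0.1000, a6 = 0.1231, a7 = -0.0419,
    # pairs (i < j) in lexicographic index order
    a8 = -0.1161,  # age x bmi
    a9 = 0.4858,   # age x map
    a10 = -0.0813, # age x iop
    a11 = -0.2330, # age x hba1c
    a12 = -0.8183, # age x ldl_c
    a13 = -0.0327, # age x gender
    a14 = 0.1538,  # bmi x map
    a15 = -0.1281, # bmi x iop
    a16 = 0.1287,  # bmi x hba1c
    a17 = -0.5843, # bmi x ldl_c
    a18 = -0.0281, # bmi x gender
    a19 = -0.1087, # map x iop
    a20 = 0.1808,  # map x hba1c
    a21 = 0.2932,  # map x ldl_c
    a22 = 0.0086,  # map x gender
    a23 = -0.1223, # iop x hba1c
    a24 = -0.1734, # iop x ldl_c
    a25 = 0.1274,  # iop x gender
    a26 = -0.1217, # hba1c x ldl_c
    a27 = -0.0982, # hba1c x gender
    a28 = -0.0972, # ldl_c x gender
    a29 = -0.1345  # constant
  )
  co
}

#' Reference normalization bounds of the cataract cohort
#'
#' Raw-unit minima and maxima of the reference training cohort, per factor,
#' plus the decimal-acuity range of the outcome. These bounds define the
#' `\[-1, +1\]` scale the reference coefficients act on.
#'
#' @return Bounds tibble (`factor`, `min`, `max`, `source`).
#' @export
reference_bounds <- function() {
  factor_bounds(
    factor = c("age", "bmi", "map", "iop", "hba1c", "ldl_c", "gender", "bcva"),
    min = c(50, 13.06, 57, 6, 1.5, 19, -1, 0.1),
    max = c(103, 43.55, 161, 35, 15.7, 234, 1, 1.1),
    source = "reference"
  )
}

#' Packaged reference model
#'
#' The fitted cataract BCVA model assembled from the published reference
#' coefficients and cohort bounds: a ready-to-use `ipa_model` for predicting
#' the acuity of new patients from their seven biological indices, and the
#' fixture against which ranking and reduced-formula behaviour are validated.
#' Its outcome scale is `"normalized"`; [predict.ipa_model()] maps
#' predictions back to decimal acuity by default.
#'
#' @return An `ipa_model`.
#' @export
#' @examples
#' m <- reference_model()
#' rank_terms(m)\[1:3, \]
reference_model <- function() {
  new_ipa_model(
    schema = build_term_schema(),
    coefficients = reference_coefficients(),
    bounds = reference_bounds(),
    outcome = "bcva",
    outcome_scale = "normalized",
    diagnostics = NULL,
    provenance = list(n = 632, source = "reference-coefficients", seed = NULL)
  )
}
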