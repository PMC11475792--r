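#' Default synthetic cohort specification
#'
#' Marginal targets for the synthetic cataract cohort: per-factor mean, SD and
#' truncation bounds matching the reference cohort's summary statistics
#' (age 78 +/- 10.83 yr on \[50, 103\], BMI 24.39 +/- 3.98 kg/m^2 on
#' \[13.06, 43.55\], MAP 97.24 +/- 15.43 mmHg on \[57, 161\], IOP 16.13 +/- 3.66
#' mmHg on \[6, 35\], HbA1c 6.80 +/- 1.88 % on \[1.5, 15.7\], LDL-C
#' 98.69 +/- 34.96 mg/dL on \[19, 234\]), a balanced sex ratio, and decimal
#' acuity clamped to \[0.1, 1.1\].
#'
#' @return A `cohort_spec`: list with `factors` (tibble of `factor`, `mean`,
#'   `sd`, `min`, `max`), `p_male`, `bcva_range`, `integer_age`.
#' @export
#' @examples
#' default_cohort_spec()$factors
default_cohort_spec <- function() {
  spec <- list(
    factors = tibble(
      factor = c("age", "bmi", "map", "iop", "hba1c", "ldl_c"),
      mean = c(78, 24.39, 97.24, 16.13, 6.80, 98.69),
      sd = c(10.83, 3.98, 15.43, 3.66, 1.88, 34.96),
      min = c(50, 13.06, 57, 6, 1.5, 19),
      max = c(103, 43.55, 161, 35, 15.7, 234)
    ),
    p_male = 0.5,
    bcva_range = c(0.1, 1.1),
    integer_age = TRUE
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  f <- spec$factors
  if (any(f$max <= f$min) || any(f$sd <= 0)) {
    abort("Cohort spec needs max > min and sd > 0 for every factor.",
      class = "ipa_error_domain"
    )
  }
  if (spec$p_male < 0 || spec$p_male > 1) {
    abort("`p_male` must lie in [0, 1].", class = "ipa_error_domain")
  }
  # truncation keeps mass: the interval must retain a workable probability
  p_lo <- pnorm(f$min, f$mean, f$sd)
  p_hi <- pnorm(f$max, f$mean, f$sd)
  if (any(p_hi - p_lo < 1e-6)) {
    abort(
      paste0(
        "Infeasible truncation for factor `", f$factor[which(p_hi - p_lo < 1e-6)[1]],
        "`: mean/sd place almost no mass inside [min, max]."
      ),
      class = "ipa_error_generator"
    )
  }
  invisible(spec)
}

# inverse-CDF truncated-normal draw: sequence-exact determinism under one seed
rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

#' Sample a synthetic raw cohort
#'
#' Draws each continuous factor independently from a truncated normal with
#' the spec's mean/SD on its min..max interval (inverse-CDF sampling, so
#' the draw is sequence-exact under a fixed seed), samples gender as a
#' Bernoulli +/-1, and integer-rounds age. Factors are independent: the
#' reference summary statistics give marginals only, and no dependence
#' structure is invented.
#'
#' @param n Number of patients, `n >= 1`.
#' @param seed Integer seed (required; the table is a pure function of
#'   `(spec, n, seed)`).
#' @param spec A `cohort_spec`; default [default_cohort_spec()].
#' @return Tibble with `patient_id` and the seven factor columns (no outcome).
#' @export
#' @examples
#' sample_cohort(5, seed = 42)
sample_cohort <- function(n, seed, spec = default_cohort_spec()) {
  if (n < 1) abort("`n` must be at least 1.", class = "ipa_error_domain")
  if (missing(seed) || is.null(seed)) {
    abort("A `seed` is required for reproducible sampling.", class = "ipa_error_domain")
  }
  validate_cohort_spec(spec)
  f <- spec$factors
  withr::with_seed(seed, {
    cols <- purrr::pmap(
      f, function(factor, mean, sd, min, max) {
        x <- rtruncnorm_inv(n, mean, sd, min, max)
        if (identical(factor, "age") && isTRUE(spec$integer_age)) {
          x <- pmin(max, pmax(min, round(x)))
        }
        x
      }
    )
    names(cols) <- f$factor
    gender <- ifelse(runif(n) < spec$p_male, 1, -1)
    dplyr::bind_cols(
      tibble(patient_id = sprintf("S%05d", seq_len(n))),
      as_tibble(cols),
      tibble(gender = gender)
    )
  })
}

#' Plant a linear outcome on a normalized cohort
#'
#' Generates `y = V M + eps`, where `V` is the design expansion of the
#' normalized cohort, `M` the planted coefficient vector and
#' `eps ~ N(0, noise_sd)`. This defines a known ground truth against which
#' the estimator's parameter recovery can be measured. With `noise_sd = 0`
#' the outcome is exactly linear in the design.
#'
#' @param data Normalized cohort (see [normalize_cohort()]).
#' @param coefficients Numeric vector aligned to `schema` (length must match).
#' @param noise_sd Gaussian noise SD in outcome units, `>= 0`.
#' @param seed Integer seed for the noise (required when `noise_sd > 0`).
#' @param clamp Optional length-2 range to clamp outcomes to (e.g.
#'   `c(0.1, 1.1)` for decimal acuity); `NULL` (default) leaves them free.
#' @param schema Term schema; default the canonical schema over the factors
#'   present in `data`.
#' @return Numeric outcome vector of length `nrow(data)`.
#' @export
plant_outcome <- function(data, coefficients, noise_sd = 0, seed = NULL,
                          clamp = NULL, schema = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "ipa_error_domain")
  V <- build_design_matrix(data, schema)
  schema <- attr(V, "schema")
  if (length(coefficients) != ncol(V)) {
    abort(
      paste0(
        "Coefficient vector (length ", length(coefficients),
        ") does not align with the ", ncol(V), "-term schema."
      ),
      class = "ipa_error_schema"
    )
  }
  y <- drop(V %*% as.numeric(coefficients))
  if (noise_sd > 0) {
    if (is.null(seed)) {
      abort("A `seed` is required when noise_sd > 0.", class = "ipa_error_domain")
    }
    y <- y + withr::with_seed(seed, rnorm(length(y), 0, noise_sd))
  }
  if (!is.null(clamp)) {
    y <- pmin(clamp[2], pmax(clamp[1], y))
  }
  y
}

#' Simulate a complete raw cohort with a BCVA outcome
#'
#' Convenience wrapper binding the generator to the reference model: samples
#' a raw cohort, normalizes it against its own bounds, plants the reference
#' coefficient vector (a normalized-acuity outcome), maps the outcome back to
#' decimal acuity and clamps it to the spec's BCVA range. The result looks
#' like a clinical table: raw factor readings plus a `bcva` column.
#'
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param noise_sd Noise SD on the normalized outcome scale (default 0.05).
#' @param coefficients Planted coefficients; default [reference_coefficients()].
#' @param spec A `cohort_spec`.
#' @return Raw cohort tibble with `patient_id`, the seven factors and `bcva`.
#' @export
#' @examples
#' simulate_cohort(10, seed = 1)
simulate_cohort <- function(n, seed, noise_sd = 0.05,
                            coefficients = reference_coefficients(),
                            spec = default_cohort_spec()) {
  raw <- sample_cohort(n, seed = seed, spec = spec)
  norm <- normalize_cohort(raw)
  y_star <- plant_outcome(norm, coefficients,
    noise_sd = noise_sd, seed = seed + 1L
  )
  bcva <- denormalize_value(y_star, spec$bcva_range[1], spec$bcva_range[2])
  raw$bcva <- pmin(spec$bcva_range[2], pmax(spec$bcva_range[1], bcva))
  raw
}

#' End-to-end parameter-recovery experiment
#'
#' Samples a cohort, normalizes it, plants a known coefficient vector with
#' Gaussian noise, refits by the closed-form estimator and reports how well
#' the planted coefficients were recovered. The noiseless case must recover
#' them to numerical precision; under noise the error shrinks with cohort
#' size.
#'
#' @param n Cohort size (must exceed the term count).
#' @param noise_sd Outcome noise SD.
#' @param seed Integer seed.
#' @param coefficients Planted vector; default [reference_coefficients()].
#' @param spec A `cohort_spec`.
#' @return A `recovery_report`: list with `planted`, `recovered`,
#'   `max_abs_error`, `rmse`, `n`, `noise_sd`, `seed`.
#' @export
#' @examples
#' recovery_experiment(100, noise_sd = 0, seed = 3)$max_abs_error
recovery_experiment <- function(n, noise_sd, seed,
                                coefficients = reference_coefficients(),
                                spec = default_cohort_spec()) {
  schema <- build_term_schema()
  if (n <= nrow(schema)) {
    abort("`n` must exceed the term count for a well-posed fit.",
      class = "ipa_error_domain"
    )
  }
  raw <- sample_cohort(n, seed = seed, spec = spec)
  norm <- normalize_cohort(raw)
  y <- plant_outcome(norm, coefficients,
    noise_sd = noise_sd, seed = seed + 1L, schema = schema
  )
  norm$y <- y
  fit <- fit_ipa(norm,
    outcome = "y", normalized = TRUE,
    bounds = attr(norm, "ipa_bounds"), seed = seed
  )
  err <- unname(fit$coefficients) - as.numeric(coefficients)
  structure(
    list(
      planted = as.numeric(coefficients),
      recovered = unname(fit$coefficients),
      max_abs_error = max(abs(err)),
      rmse = sqrt(mean(err^2)),
      n = n,
      noise_sd = noise_sd,
      seed = seed
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> n = %d, noise_sd = %g, seed = %d\n  max |error| = %.3g, RMSE = %.3g\n",
    x$n, x$noise_sd, x$seed, x$max_abs_error, x$rmse
  ))
  invisible(x)
}
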