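#' Mean arterial pressure from systolic and diastolic readings
#'
#' MAP summarises the perfusion pressure over one cardiac cycle as
#' `(SBP + 2 * DBP) / 3`, weighting diastole twice because the heart spends
#' roughly two thirds of the cycle in it.
#'
#' @param sbp Systolic blood pressure, mmHg. Vectorised.
#' @param dbp Diastolic blood pressure, mmHg. Vectorised.
#' @return Mean arterial pressure, mmHg.
#' @export
#' @examples
#' compute_map(120, 80)
compute_map <- function(sbp, dbp) {
  if (!is.numeric(sbp) || !is.numeric(dbp)) {
    abort("`sbp` and `dbp` must be numeric.", class = "ipa_error_domain")
  }
  bad <- !is.na(sbp) & !is.na(dbp) & (dbp <= 0 | sbp < dbp)
  if (any(bad)) {
    k <- which(bad)[1]
    abort(
      paste0(
        "Invalid blood pressure: need sbp >= dbp > 0 (position ", k,
        ": sbp = ", sbp[k], ", dbp = ", dbp[k], ")."
      ),
      class = "ipa_error_blood_pressure"
    )
  }
  (sbp + 2 * dbp) / 3
}

#' Body mass index from weight and height
#'
#' @param weight_kg Body weight in kilograms. Vectorised.
#' @param height_m Standing height in metres. Vectorised.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' compute_bmi(65, 1.7)
compute_bmi <- function(weight_kg, height_m) {
  if (!is.numeric(weight_kg) || !is.numeric(height_m)) {
    abort("`weight_kg` and `height_m` must be numeric.", class = "ipa_error_domain")
  }
  bad <- !is.na(weight_kg) & !is.na(height_m) & (weight_kg <= 0 | height_m <= 0)
  if (any(bad)) {
    abort("BMI requires strictly positive weight and height.",
      class = "ipa_error_domain"
    )
  }
  weight_kg / height_m^2
}

#' Encode gender labels as +1 / -1
#'
#' Male-coded records map to `+1`, female-coded records to `-1`, matching the
#' model's dimensionless factor scale. Accepted (case-insensitive) synonyms:
#' `m`, `male`, `1`, `+1` and `f`, `female`, `-1`. Numeric `+1`/`-1` pass
#' through unchanged.
#'
#' @param x Character, factor or numeric vector of gender codes.
#' @return Numeric vector with values in `{-1, +1}`.
#' @export
#' @examples
#' encode_gender(c("male", "F", "+1"))
encode_gender <- function(x) {
  if (is.numeric(x)) {
    if (any(!is.na(x) & !(x %in% c(-1, 1)))) {
      abort("Numeric gender codes must be +1 or -1.", class = "ipa_error_encoding")
    }
    return(as.numeric(x))
  }
  key <- tolower(trimws(as.character(x)))
  male <- c("m", "male", "1", "+1")
  female <- c("f", "female", "-1")
  out <- ifelse(key %in% male, 1, ifelse(key %in% female, -1, NA_real_))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    abort(
      paste0(
        "Unrecognised gender label(s): ",
        paste(unique(x[bad]), collapse = ", "),
        ". Accepted forms: m/male/1/+1 (male), f/female/-1 (female)."
      ),
      class = "ipa_error_encoding"
    )
  }
  out
}

#' Construct per-factor normalization bounds
#'
#' Bounds define the affine map of each raw risk factor onto `\[-1, +1\]`; a
#' fitted model is only meaningful together with the bounds it was trained
#' under, so bounds carry a `source` provenance tag.
#'
#' @param factor Character vector of factor names.
#' @param min,max Numeric vectors of raw-unit lower/upper bounds.
#' @param source `"fitted"` (derived from a cohort) or `"supplied"`.
#' @return A tibble with columns `factor`, `min`, `max`, `source`.
#' @export
#' @examples
#' factor_bounds("bmi", 13.06, 43.55)
factor_bounds <- function(factor, min, max, source = "supplied") {
  if (any(!is.finite(min)) || any(!is.finite(max))) {
    abort("Bounds must be finite.", class = "ipa_error_bounds")
  }
  if (any(max <= min)) {
    bad <- factor[max <= min][1]
    abort(
      paste0("Degenerate bounds for factor `", bad, "`: max must exceed min."),
      class = "ipa_error_degenerate"
    )
  }
  tibble(
    factor = as.character(factor),
    min = as.numeric(min),
    max = as.numeric(max),
    source = rep_len(source, length(factor))
  )
}

#' Fit normalization bounds from a cohort
#'
#' Computes the observed minimum and maximum of each factor column; these are
#' the `X_min`, `X_max` of the `\[-1, +1\]` normalization. Gender is bounded at
#' `(-1, +1)` by its encoding rather than by the data, so a single-sex cohort
#' is not degenerate.
#'
#' @param data A cohort data frame with the factor columns.
#' @param factors Factor names to fit; defaults to [ipa_factors()].
#' @return Bounds tibble (see [factor_bounds()]), `source = "fitted"`.
#' @export
#' @examples
#' fit_factor_bounds(tibble::tibble(bmi = c(13.06, 20, 43.55)), "bmi")
fit_factor_bounds <- function(data, factors = intersect(ipa_factors(), names(data))) {
  missing_cols <- setdiff(factors, names(data))
  if (length(missing_cols)) {
    abort(
      paste0("Cohort lacks factor column(s): ", paste(missing_cols, collapse = ", ")),
      class = "ipa_error_schema"
    )
  }
  rows <- purrr::map(factors, function(f) {
    if (identical(f, "gender")) {
      return(tibble(factor = f, min = -1, max = 1, source = "fixed"))
    }
    v <- data[[f]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      abort(paste0("Factor `", f, "` must be finite numeric."),
        class = "ipa_error_domain"
      )
    }
    if (length(v) < 2 || diff(range(v)) == 0) {
      abort(
        paste0("Degenerate factor `", f, "`: needs at least two distinct values."),
        class = "ipa_error_degenerate"
      )
    }
    tibble(factor = f, min = min(v), max = max(v), source = "fitted")
  })
  dplyr::bind_rows(rows)
}

#' Min-max normalization onto \[-1, +1\]
#'
#' Maps a raw reading `x` to `(x - (max + min)/2) / ((max - min)/2)`, so the
#' cohort minimum lands at -1, the maximum at +1 and the midpoint at 0.
#' Values outside the bounds extrapolate linearly (magnitude > 1); range
#' policy is the caller's concern (see [normalize_cohort()]).
#'
#' @param x Raw reading(s), in the factor's native units.
#' @param min,max Normalization bounds, `max > min`.
#' @return Dimensionless value(s).
#' @seealso [denormalize_value()] for the exact inverse.
#' @export
#' @examples
#' normalize_value(15.00, 13.06, 43.55)
normalize_value <- function(x, min, max) {
  if (any(max <= min)) {
    abort("Bounds must satisfy max > min.", class = "ipa_error_degenerate")
  }
  (x - (max + min) / 2) / ((max - min) / 2)
}

#' Invert the \[-1, +1\] normalization
#'
#' @param x_star Dimensionless value(s).
#' @param min,max The bounds used to normalize, `max > min`.
#' @return Raw-unit value(s); `denormalize_value(normalize_value(x)) == x`.
#' @export
#' @examples
#' denormalize_value(-1, 13.06, 43.55)
denormalize_value <- function(x_star, min, max) {
  if (any(max <= min)) {
    abort("Bounds must satisfy max > min.", class = "ipa_error_degenerate")
  }
  x_star * (max - min) / 2 + (max + min) / 2
}

#' Normalize a cohort table
#'
#' Applies the `\[-1, +1\]` normalization to every factor column using the given
#' (or freshly fitted) bounds, encodes gender as +/-1, and flags values that
#' fall outside their bounds. Out-of-range values arise naturally when a
#' verification cohort is normalized against training bounds.
#'
#' @param data Raw cohort data frame (factor columns plus any others, which
#'   pass through untouched).
#' @param bounds Bounds tibble from [fit_factor_bounds()] / [factor_bounds()],
#'   or `NULL` to fit from `data` itself.
#' @param policy What to do with values outside `\[-1, +1\]` after normalization:
#'   `"allow"` keeps them (linear extrapolation), `"clip"` clamps to the range,
#'   `"error"` aborts naming the first offending patient and factor. The
#'   `oor_<factor>` flag columns are set regardless of policy.
#' @return A tibble with normalized factor columns, logical `oor_*` columns,
#'   and the bounds attached as attribute `"ipa_bounds"`.
#' @export
#' @examples
#' coh <- sample_cohort(20, seed = 1)
#' normalize_cohort(coh)
normalize_cohort <- function(data, bounds = NULL,
                             policy = c("allow", "clip", "error")) {
  policy <- match.arg(policy)
  data <- as_tibble(data)
  if ("gender" %in% names(data)) {
    data$gender <- encode_gender(data$gender)
  }
  if (is.null(bounds)) {
    bounds <- fit_factor_bounds(data)
  }
  missing_cols <- setdiff(bounds$factor, names(data))
  if (length(missing_cols)) {
    abort(
      paste0("Cohort lacks factor column(s): ", paste(missing_cols, collapse = ", ")),
      class = "ipa_error_schema"
    )
  }
  out <- data
  ids <- data[["patient_id"]] %||% as.character(seq_len(nrow(data)))
  for (i in seq_len(nrow(bounds))) {
    f <- bounds$factor[i]
    z <- normalize_value(data[[f]], bounds$min[i], bounds$max[i])
    oor <- abs(z) > 1 + 1e-12
    if (policy == "error" && any(oor)) {
      k <- which(oor)[1]
      abort(
        paste0(
          "Out-of-range value for factor `", f, "` (patient ", ids[k],
          "): raw ", data[[f]][k], " outside bounds [", bounds$min[i],
          ", ", bounds$max[i], "]."
        ),
        class = "ipa_error_range"
      )
    }
    if (policy == "clip") z <- pmin(1, pmax(-1, z))
    out[[f]] <- z
    out[[paste0("oor_", f)]] <- oor
  }
  attr(out, "ipa_bounds") <- bounds
  out
}
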