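cohort_required_cols <- function() {
  c("patient_id", ipa_factors())
}

#' Read a cohort CSV
#'
#' Expects the header `patient_id,age,bmi,map,iop,hba1c,ldl_c,gender,bcva`
#' (`bcva` optional for prediction-only tables). In `derive` mode, `map` may
#' be absent if `sbp`/`dbp` columns are present (derived via [compute_map()]),
#' and `bmi` absent if `weight_kg`/`height_m` are present (via
#' [compute_bmi()]). Gender synonyms are encoded to +/-1 on read.
#'
#' @param path CSV file path (UTF-8, `.` decimal separator).
#' @param mode `"strict"` requires every factor column verbatim; `"derive"`
#'   computes the derived indices from their raw components when absent.
#' @return Raw cohort tibble.
#' @export
read_cohort_csv <- function(path, mode = c("strict", "derive")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "ipa_error_io")
  }
  data <- readr::read_csv(path,
    col_types = readr::cols(gender = readr::col_character(), .default = readr::col_guess()),
    show_col_types = FALSE, progress = FALSE
  )
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(
      paste0(
        "Malformed cell(s) in ", path, ": first at row ", probs$row[1],
        ", column ", probs$col[1], " (expected ", probs$expected[1], ")."
      ),
      class = "ipa_error_parse"
    )
  }
  if (mode == "derive") {
    if (!"map" %in% names(data) && all(c("sbp", "dbp") %in% names(data))) {
      data$map <- compute_map(data$sbp, data$dbp)
    }
    if (!"bmi" %in% names(data) && all(c("weight_kg", "height_m") %in% names(data))) {
      data$bmi <- compute_bmi(data$weight_kg, data$height_m)
    }
  }
  missing_cols <- setdiff(cohort_required_cols(), names(data))
  if (length(missing_cols)) {
    abort(
      paste0("Cohort CSV lacks required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "ipa_error_schema"
    )
  }
  data$gender <- encode_gender(data$gender)
  for (f in setdiff(ipa_factors(), "gender")) {
    if (!is.numeric(data[[f]]) || any(!is.finite(data[[f]]))) {
      abort(paste0("Column `", f, "` must be finite numeric."),
        class = "ipa_error_parse"
      )
    }
  }
  if ("bcva" %in% names(data) && any(data$bcva <= 0, na.rm = TRUE)) {
    abort("`bcva` must be positive where present.", class = "ipa_error_domain")
  }
  as_tibble(data)
}

#' Write a cohort CSV
#'
#' @param data Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  out <- as_tibble(data)
  if ("gender" %in% names(out)) out$gender <- encode_gender(out$gender)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

model_json_version <- "1"

#' Serialize a fitted model to JSON
#'
#' Writes the schema, coefficients, bounds, outcome scale, training
#' diagnostics and provenance with full (round-trip) numeric precision, so
#' `read_model_json(write_model_json(m))` reproduces the model bit-exactly.
#'
#' @param model An `ipa_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "ipa_model"))
  payload <- list(
    format = "ipacuity-model",
    version = model_json_version,
    schema = model$schema,
    coefficients = as.list(model$coefficients),
    bounds = model$bounds,
    outcome = model$outcome,
    outcome_scale = model$outcome_scale,
    diagnostics = if (is.null(model$diagnostics)) NULL else as.list(model$diagnostics),
    provenance = model$provenance
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = I(17), null = "null", na = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read a model back from JSON
#'
#' @param path JSON path written by [write_model_json()].
#' @return An `ipa_model`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "ipa_error_io")
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "ipacuity-model")) {
    abort("Not an ipacuity model file.", class = "ipa_error_io")
  }
  if (!identical(as.character(payload$version), model_json_version)) {
    abort(
      paste0("Unsupported model file version: ", payload$version),
      class = "ipa_error_version"
    )
  }
  schema <- as_tibble(payload$schema)
  schema$f1 <- as.character(schema$f1)
  schema$f2 <- as.character(schema$f2)
  co <- unlist(payload$coefficients)
  bounds <- as_tibble(payload$bounds)
  diagnostics <- if (is.null(payload$diagnostics)) NULL else as_tibble(payload$diagnostics)
  new_ipa_model(
    schema = schema,
    coefficients = setNames(as.numeric(co), names(co)),
    bounds = bounds,
    outcome = payload$outcome,
    outcome_scale = payload$outcome_scale,
    diagnostics = diagnostics,
    provenance = payload$provenance
  )
}

#' Write / read a plain named-list report as JSON
#'
#' Full-precision JSON round trip for flat report objects such as a
#' `recovery_report`.
#'
#' @param x Named list (numeric/character scalars and vectors).
#' @param path JSON path.
#' @return `write_report_json()` returns `path` invisibly;
#'   `read_report_json()` returns the list (class restored if present).
#' @export
write_report_json <- function(x, path) {
  cls <- class(x)
  payload <- c(unclass(x), list(.class = cls))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$.class
  payload$.class <- NULL
  if (!is.null(cls) && !identical(cls, "list")) class(payload) <- cls
  payload
}
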