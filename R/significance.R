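#' Rank model terms by coefficient magnitude
#'
#' Because every factor lives on the same dimensionless `\[-1, +1\]` scale, the
#' absolute size of a coefficient measures how strongly its term moves the
#' predicted outcome; rank 1 is the largest magnitude. Ties are broken by
#' schema order, so ranking is deterministic.
#'
#' @param model A fitted `ipa_model`.
#' @return Tibble with `term`, `symbol`, `coefficient`, `rank`.
#' @export
#' @examples
#' rank_terms(reference_model())
rank_terms <- function(model) {
  stopifnot(inherits(model, "ipa_model"))
  co <- unname(model$coefficients)
  ord <- order(-abs(co), seq_along(co))
  rank <- integer(length(co))
  rank[ord] <- seq_along(co)
  tibble(
    term = model$schema$label,
    symbol = model$schema$symbol,
    coefficient = co,
    rank = rank
  )
}

#' Split single factors into significant and minor
#'
#' Orders the single-factor terms by their whole-model rank and labels the
#' top `n_significant` as significant, the rest as minor. Interaction and
#' constant terms do not participate.
#'
#' @param model A fitted `ipa_model` whose schema contains single terms.
#' @param n_significant How many leading factors count as significant
#'   (default 3, the convention used for the cataract reference model).
#' @return Tibble with `factor`, `term`, `coefficient`, `rank`,
#'   `significance` (`"significant"`/`"minor"`), ordered by rank.
#' @export
#' @examples
#' classify_factors(reference_model())
classify_factors <- function(model, n_significant = 3) {
  rt <- rank_terms(model)
  singles <- model$schema$kind == "single"
  if (!any(singles)) {
    abort("Model schema has no single-factor terms.", class = "ipa_error_schema")
  }
  if (n_significant > sum(singles)) {
    abort(
      paste0("`n_significant` (", n_significant, ") exceeds the factor count (",
             sum(singles), ")."),
      class = "ipa_error_domain"
    )
  }
  out <- tibble(
    factor = model$schema$f1[singles],
    term = rt$term[singles],
    coefficient = rt$coefficient[singles],
    rank = rt$rank[singles]
  )
  out <- dplyr::arrange(out, .data$rank)
  out$significance <- ifelse(seq_len(nrow(out)) <= n_significant,
    "significant", "minor"
  )
  out
}

#' Factor removal order of the reference cataract analysis
#'
#' The order in which the reference analysis discarded factors when studying
#' truncated models: gender, MAP, LDL-C, HbA1c, IOP, BMI (age is never
#' dropped). Note this deviates slightly from strict ascending significance —
#' LDL-C is dropped before HbA1c although its single-term coefficient ranks
#' higher — so it is provided as an explicit preset rather than silently
#' recomputed.
#'
#' @return Character vector of six factor names.
#' @export
reference_drop_order <- function() {
  c("gender", "map", "ldl_c", "hba1c", "iop", "bmi")
}

#' Truncation ladder: refit with progressively fewer factors
#'
#' Emulates missing clinical indices: starting from the full model, factors
#' are removed one at a time — each removal discards the factor's single term
#' and every interaction involving it — the schema is rebuilt and the model
#' REFIT on the remaining terms. For seven factors the term count steps
#' through 29, 22, 16, 11, 7, 4, 2. Training loss can only grow as terms are
#' removed, and the fit variance can only shrink.
#'
#' @param data Cohort data frame (raw units unless `normalized = TRUE`).
#' @param outcome Outcome column name.
#' @param drop_order Character vector of factors to drop, in order (at most
#'   `k - 1`), or `NULL` to drop in ascending significance as ranked by the
#'   full-model fit (worst-ranked single factor first). See
#'   [reference_drop_order()] for the preset used by the reference analysis.
#' @param factors Ordered factor names of the full model.
#' @param ... Passed to [fit_ipa()] (e.g. `outcome_scale`, `normalized`).
#' @return Tibble with one row per ladder level: `n_factors`, `n_terms`,
#'   `dropped` (factor removed at this level, `NA` for the full model),
#'   `loss`, `variance`, `slope`, `intercept`, `r2`.
#' @export
#' @examples
#' coh <- simulate_cohort(200, seed = 7)
#' truncation_ladder(coh, drop_order = reference_drop_order())
truncation_ladder <- function(data, outcome = "bcva", drop_order = NULL,
                              factors = intersect(ipa_factors(), names(data)),
                              ...) {
  full <- fit_ipa(data, outcome = outcome, factors = factors, ...)
  if (is.null(drop_order)) {
    cls <- classify_factors(full, n_significant = 1)
    drop_order <- rev(cls$factor)[seq_len(length(factors) - 1)]
  }
  drop_order <- as.character(drop_order)
  bad <- setdiff(drop_order, factors)
  if (length(bad)) {
    abort(
      paste0("Cannot drop factor(s) absent from the model: ",
             paste(bad, collapse = ", ")),
      class = "ipa_error_schema"
    )
  }
  if (anyDuplicated(drop_order) || length(drop_order) > length(factors) - 1) {
    abort("`drop_order` must be distinct factors, at most k - 1 of them.",
      class = "ipa_error_domain"
    )
  }
  level_row <- function(fit, dropped) {
    g <- glance(fit)
    tibble(
      n_factors = g$n_factors, n_terms = g$n_terms, dropped = dropped,
      loss = g$loss, variance = g$variance, slope = g$slope,
      intercept = g$intercept, r2 = g$variance
    )
  }
  rows <- list(level_row(full, NA_character_))
  remaining <- factors
  for (f in drop_order) {
    remaining <- setdiff(remaining, f)
    fit <- fit_ipa(data, outcome = outcome, factors = remaining, ...)
    rows[[length(rows) + 1]] <- level_row(fit, f)
  }
  dplyr::bind_rows(rows)
}

#' Evaluate the model over a raw-unit factor grid
#'
#' Builds a full lattice over up to three axis factors (raw units), pins every
#' other factor at normalized zero (its bounds midpoint; for gender, absence
#' of a sex effect), and predicts each lattice point. Pinning factors at zero
#' annihilates their single and interaction terms, so this equals evaluating
#' the reduced formula containing only the axis factors' terms and the
#' constant. Predictions below `risk_threshold` (decimal acuity) are flagged
#' as at risk.
#'
#' @param model A fitted `ipa_model` with bounds for the axis factors.
#' @param axes Tibble/data frame with columns `factor`, `min`, `max`, `n`
#'   (raw-unit range and number of lattice points per axis, `n >= 2`).
#' @param risk_threshold Decimal-acuity threshold for the risk flag
#'   (default 0.80).
#' @return Tibble of class `ipa_grid`: one row per lattice point with the raw
#'   axis values, `predicted` (model scale), `predicted_bcva` (decimal
#'   acuity) and `risk_flag`.
#' @export
#' @examples
#' grid <- evaluate_reduced_grid(
#'   reference_model(),
#'   axes = tibble::tibble(
#'     factor = c("age", "bmi", "iop"),
#'     min = c(30, 13.97, 7), max = c(80, 28.01, 19), n = c(6, 6, 6)
#'   )
#' )
evaluate_reduced_grid <- function(model, axes, risk_threshold = 0.8) {
  stopifnot(inherits(model, "ipa_model"))
  axes <- as_tibble(axes)
  need <- c("factor", "min", "max", "n")
  if (!all(need %in% names(axes))) {
    abort("`axes` needs columns factor, min, max, n.", class = "ipa_error_domain")
  }
  if (any(axes$n < 2) || any(axes$max <= axes$min)) {
    abort("Each axis needs max > min and n >= 2.", class = "ipa_error_domain")
  }
  model_factors <- model$schema$f1[model$schema$kind == "single"]
  if (length(setdiff(axes$factor, model_factors))) {
    abort("Axis factors must belong to the model.", class = "ipa_error_schema")
  }
  for (f in axes$factor) {
    if (!f %in% model$bounds$factor) {
      abort(paste0("Model carries no bounds for axis factor `", f, "`."),
        class = "ipa_error_bounds"
      )
    }
  }
  axis_values <- purrr::pmap(
    axes, function(factor, min, max, n) seq(min, max, length.out = n)
  )
  names(axis_values) <- axes$factor
  lattice <- tidyr::expand_grid(!!!axis_values)
  norm <- lattice
  for (i in seq_len(nrow(axes))) {
    f <- axes$factor[i]
    b <- model$bounds[model$bounds$factor == f, ]
    norm[[f]] <- normalize_value(lattice[[f]], b$min, b$max)
  }
  for (f in setdiff(model_factors, axes$factor)) {
    norm[[f]] <- 0
  }
  pred_model <- predict(model, norm, normalized = TRUE, scale = "model")
  pred_raw <- if (identical(model$outcome_scale, "normalized")) {
    ob <- model$bounds[model$bounds$factor == model$outcome, ]
    denormalize_value(pred_model, ob$min, ob$max)
  } else {
    pred_model
  }
  out <- lattice
  out$predicted <- pred_model
  out$predicted_bcva <- pred_raw
  out$risk_flag <- pred_raw < risk_threshold
  class(out) <- c("ipa_grid", class(out))
  attr(out, "axes") <- axes
  out
}
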