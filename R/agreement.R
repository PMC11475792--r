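#' Percent agreement between actual and predicted acuity
#'
#' The per-patient agreement statistic
#' `AT = (actual - predicted) / actual * 100` (percent). Zero means a perfect
#' prediction; over-prediction gives a negative AT. Undefined when the actual
#' value is zero (decimal acuity is bounded away from zero on faithful data).
#'
#' @param actual,predicted Numeric vectors of equal length, decimal acuity.
#' @return Numeric vector of AT values, percent.
#' @export
#' @examples
#' at_value(0.5, 0.4) # 20
at_value <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have equal length.", class = "ipa_error_domain")
  }
  if (any(actual == 0)) {
    abort("AT undefined: `actual` contains zero(s).", class = "ipa_error_at_zero")
  }
  (actual - predicted) / actual * 100
}

#' Cohort agreement summary
#'
#' Computes the AT vector, its mean and sample standard deviation, and how
#' many records fall below each threshold (by default on `|AT|`, since AT is
#' signed; `signed = TRUE` compares the signed value instead).
#'
#' @param actual,predicted Numeric vectors of equal length, decimal acuity.
#' @param thresholds Percent thresholds to count below (default 6).
#' @param signed Compare signed AT against the thresholds instead of `|AT|`.
#' @param on_zero `"error"` aborts when an actual value is zero;
#'   `"skip"` drops such records with a warning.
#' @return An `agreement_report`: list with `at`, `at_mean`, `at_sd`, `n`,
#'   `below` (named integer counts), `thresholds`, `signed`.
#' @export
#' @examples
#' at_summary(c(0.5, 0.5), c(0.45, 0.55))
at_summary <- function(actual, predicted, thresholds = 6, signed = FALSE,
                       on_zero = c("error", "skip")) {
  on_zero <- match.arg(on_zero)
  if (length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have equal length.", class = "ipa_error_domain")
  }
  if (length(actual) == 0) {
    abort("Empty input: no records to summarise.", class = "ipa_error_domain")
  }
  zero <- actual == 0
  if (any(zero)) {
    if (on_zero == "error") {
      abort("AT undefined: `actual` contains zero(s).", class = "ipa_error_at_zero")
    }
    warn(paste0("Skipping ", sum(zero), " record(s) with actual = 0."))
    actual <- actual[!zero]
    predicted <- predicted[!zero]
  }
  at <- at_value(actual, predicted)
  cmp <- if (signed) at else abs(at)
  below <- vapply(thresholds, function(t) sum(cmp < t), integer(1))
  names(below) <- paste0(format(thresholds, trim = TRUE), "%")
  structure(
    list(
      at = at,
      at_mean = mean(at),
      at_sd = if (length(at) > 1) sd(at) else 0,
      n = length(at),
      below = below,
      thresholds = thresholds,
      signed = signed
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> n = %d, AT = %.2f%% +/- %.2f%%\n", x$n, x$at_mean, x$at_sd
  ))
  for (i in seq_along(x$below)) {
    cat(sprintf(
      "  %s%s below %s: %d/%d\n",
      if (x$signed) "AT" else "|AT|", "", names(x$below)[i], x$below[i], x$n
    ))
  }
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  tibble(at_percent = x$at)
}

#' @export
glance.agreement_report <- function(x, ...) {
  out <- tibble(n = x$n, at_mean = x$at_mean, at_sd = x$at_sd)
  for (i in seq_along(x$below)) {
    out[[paste0("below_", names(x$below)[i])]] <- x$below[[i]]
  }
  out
}

#' Histogram of AT values with explicit under/overflow bins
#'
#' Bins are half-open `[e_i, e_{i+1})`; everything below the first edge falls
#' in the underflow bin and everything at or above the last edge in the
#' overflow bin, so the counts always sum to the number of values.
#'
#' @param at Numeric vector of AT percentages.
#' @param edges Strictly increasing numeric vector of bin edges (percent).
#' @return Tibble with `lower`, `upper`, `count` (first row `-Inf`, last `Inf`).
#' @export
#' @examples
#' at_histogram(c(1, 5, 7), edges = c(0, 6, 12))
at_histogram <- function(at, edges) {
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    abort("`edges` must be strictly increasing with at least two values.",
      class = "ipa_error_domain"
    )
  }
  lower <- c(-Inf, edges)
  upper <- c(edges, Inf)
  count <- vapply(
    seq_along(lower),
    function(i) sum(at >= lower[i] & at < upper[i]),
    integer(1)
  )
  tibble(lower = lower, upper = upper, count = count)
}

#' Subsample-refit experiment
#'
#' Measures how prediction agreement degrades when the model is trained on
#' fewer patients: draws `n_sub` records without replacement (seeded), refits
#' the full interaction model, predicts an independent verification cohort
#' and summarises its AT. With `replicates > 1` the experiment is repeated
#' with seeds `seed, seed + 1, ...` and one summary row returned per
#' replicate.
#'
#' @param data Training cohort (raw units) with the outcome column.
#' @param verification Verification cohort (raw units) with the outcome
#'   column; predicted with the subsample model under the training bounds.
#' @param n_sub Subsample size (must be at least the model's term count).
#' @param seed Integer seed; the report is a pure function of
#'   `(data, n_sub, seed)`.
#' @param outcome Outcome column name.
#' @param replicates Number of repeats (default 1).
#' @param thresholds Percent thresholds for the agreement summary.
#' @param ... Passed to [fit_ipa()].
#' @return For `replicates = 1`, an `agreement_report`; otherwise a tibble
#'   with one glance row per replicate plus a `seed` column.
#' @export
subsample_refit <- function(data, verification, n_sub, seed,
                            outcome = "bcva", replicates = 1,
                            thresholds = 6, ...) {
  data <- as_tibble(data)
  if (n_sub > nrow(data)) {
    abort("`n_sub` exceeds the cohort size.", class = "ipa_error_domain")
  }
  one <- function(s) {
    idx <- withr::with_seed(s, sample.int(nrow(data), n_sub))
    fit <- fit_ipa(data[idx, , drop = FALSE], outcome = outcome, seed = s, ...)
    pred <- predict(fit, verification, scale = "raw")
    at_summary(as.numeric(verification[[outcome]]), pred, thresholds = thresholds)
  }
  if (replicates == 1) {
    return(one(seed))
  }
  purrr::map_dfr(seq_len(replicates), function(r) {
    rep_seed <- seed + r - 1
    g <- glance(one(rep_seed))
    dplyr::bind_cols(tibble(seed = rep_seed), g)
  })
}
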