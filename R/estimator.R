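#' Closed-form least-squares solve of the inverse problem
#'
#' Returns the coefficient vector `M` minimising the loss `||V M - y||^2`,
#' i.e. the normal-equations solution `(V'V)^{-1} V'y` computed through a QR
#' decomposition rather than an explicit inverse. When `V` is rank deficient
#' (collinear columns or `n < p`) the behaviour is configurable: abort, or
#' return the minimum-norm solution via the SVD pseudoinverse with a warning.
#'
#' @param V Numeric design matrix, `n x p`.
#' @param y Numeric outcome vector of length `n`.
#' @param singular `"error"` (default) or `"pseudoinverse"`.
#' @return Numeric coefficient vector of length `p` (named after `colnames(V)`).
#' @export
ipa_solve <- function(V, y, singular = c("error", "pseudoinverse")) {
  singular <- match.arg(singular)
  V <- as.matrix(V)
  y <- as.numeric(y)
  if (nrow(V) != length(y)) {
    abort("`V` and `y` have incompatible sizes.", class = "ipa_error_domain")
  }
  if (any(!is.finite(V)) || any(!is.finite(y))) {
    abort("Design and outcome must be finite.", class = "ipa_error_domain")
  }
  qr_v <- qr(V)
  if (qr_v$rank < ncol(V)) {
    if (singular == "error") {
      abort(
        paste0(
          "Rank-deficient design (rank ", qr_v$rank, " < ", ncol(V),
          " columns); collinear terms or too few records. ",
          "Use singular = \"pseudoinverse\" for the minimum-norm solution."
        ),
        class = "ipa_error_rank"
      )
    }
    warn("Rank-deficient design: returning the minimum-norm (pseudoinverse) solution.")
    sv <- svd(V)
    tol <- max(dim(V)) * .Machine$double.eps * sv$d[1]
    keep <- sv$d > tol
    m <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
    m <- drop(m)
  } else {
    m <- qr.coef(qr_v, y)
  }
  names(m) <- colnames(V)
  m
}

#' Residual sum of squares of a prediction
#'
#' The model's loss function: the squared Euclidean norm of the residual
#' vector, zero exactly when predictions match the outcomes.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
#' @examples
#' ipa_loss(c(1, 2), c(1.1, 1.9)) # 0.02
ipa_loss <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have equal length.", class = "ipa_error_domain")
  }
  sum((actual - predicted)^2)
}

#' Fit diagnostics for actual vs predicted outcomes
#'
#' Computes the quantities used to judge a fit: the residual loss, the Pearson
#' correlation `r` between actual and predicted, the "variance" `r^2`, and
#' the least-squares line of predicted regressed on actual. On a training fit
#' that includes a constant term the slope of that line equals `r^2` (an OLS
#' identity), which is why slope and variance track each other in truncation
#' ladders.
#'
#' @param actual,predicted Numeric vectors, equal length `>= 3`; `actual`
#'   must not be constant.
#' @return One-row tibble: `n`, `loss`, `correlation`, `variance`, `slope`,
#'   `intercept`.
#' @export
diagnose <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 3) {
    abort("Need equal-length vectors with at least 3 records.", class = "ipa_error_domain")
  }
  if (sd(actual) == 0) {
    abort("Correlation undefined: `actual` is constant.", class = "ipa_error_domain")
  }
  r <- cor(actual, predicted)
  slope <- stats::cov(actual, predicted) / var(actual)
  tibble(
    n = length(actual),
    loss = ipa_loss(actual, predicted),
    correlation = r,
    variance = r^2,
    slope = slope,
    intercept = mean(predicted) - slope * mean(actual)
  )
}

#' Fit the interaction-expanded least-squares model
#'
#' The core estimator: normalizes the cohort (unless already normalized),
#' expands it into the single + pairwise-interaction + constant design matrix,
#' and solves for the coefficient vector in closed form. The returned model
#' bundles the coefficients with the term schema and normalization bounds
#' that give them meaning.
#'
#' By default the outcome is fitted on its raw decimal-acuity scale; with
#' `outcome_scale = "normalized"` the outcome is itself min-max normalized to
#' `\[-1, +1\]` (its bounds are then part of the model and predictions can be
#' mapped back to acuity units).
#'
#' @param data Cohort data frame containing the factor columns and the
#'   outcome column.
#' @param outcome Name of the outcome column (default `"bcva"`).
#' @param factors Ordered factor names; default the canonical seven present
#'   in `data`.
#' @param bounds Normalization bounds, or `NULL` to fit them from `data`.
#' @param normalized Set `TRUE` if `data` is already on the `\[-1, +1\]` scale.
#' @param outcome_scale `"raw"` (default) or `"normalized"`.
#' @param singular Rank-deficiency policy, see [ipa_solve()].
#' @param seed Optional integer recorded in the model provenance (for
#'   synthetic cohorts).
#' @return An object of class `ipa_model`: a list with `schema`,
#'   `coefficients`, `bounds`, `outcome`, `outcome_scale`, `diagnostics`
#'   (training fit, on the fitted scale) and `provenance`.
#' @export
#' @examples
#' coh <- simulate_cohort(100, seed = 1)
#' fit <- fit_ipa(coh)
#' glance(fit)
fit_ipa <- function(data, outcome = "bcva",
                    factors = intersect(ipa_factors(), names(data)),
                    bounds = NULL, normalized = FALSE,
                    outcome_scale = c("raw", "normalized"),
                    singular = c("error", "pseudoinverse"),
                    seed = NULL) {
  outcome_scale <- match.arg(outcome_scale)
  singular <- match.arg(singular)
  data <- as_tibble(data)
  if (!outcome %in% names(data)) {
    abort(paste0("Outcome column `", outcome, "` not found."), class = "ipa_error_schema")
  }
  y <- as.numeric(data[[outcome]])
  if (any(!is.finite(y))) {
    abort("Outcome must be finite.", class = "ipa_error_domain")
  }
  if (normalized) {
    norm <- data
    if (is.null(bounds)) bounds <- attr(data, "ipa_bounds")
  } else {
    norm <- normalize_cohort(data, bounds = bounds)
    bounds <- attr(norm, "ipa_bounds")
  }
  if (outcome_scale == "normalized") {
    ob <- bounds[bounds$factor == outcome, ]
    if (nrow(ob) == 0) {
      ob <- factor_bounds(outcome, min(y), max(y), source = "fitted")
      bounds <- dplyr::bind_rows(bounds, ob)
    }
    y_fit <- normalize_value(y, ob$min, ob$max)
  } else {
    y_fit <- y
  }
  schema <- build_term_schema(factors)
  V <- build_design_matrix(norm, schema)
  m <- ipa_solve(V, y_fit, singular = singular)
  fitted <- drop(V %*% m)
  model <- structure(
    list(
      schema = schema,
      coefficients = m,
      bounds = bounds,
      outcome = outcome,
      outcome_scale = outcome_scale,
      diagnostics = diagnose(y_fit, fitted),
      provenance = list(
        n = nrow(V),
        fitted_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = seed,
        bounds_source = paste(unique(bounds$source), collapse = "+")
      )
    ),
    class = "ipa_model"
  )
  model
}

# assemble an ipa_model from parts (used by the reference fixture and JSON IO)
new_ipa_model <- function(schema, coefficients, bounds, outcome = "bcva",
                          outcome_scale = "raw", diagnostics = NULL,
                          provenance = list()) {
  if (length(coefficients) != nrow(schema)) {
    abort(
      paste0(
        "Coefficient count (", length(coefficients),
        ") does not match schema length (", nrow(schema), ")."
      ),
      class = "ipa_error_schema"
    )
  }
  if (any(!is.finite(coefficients))) {
    abort("Coefficients must be finite.", class = "ipa_error_domain")
  }
  coefficients <- setNames(as.numeric(coefficients), schema$symbol)
  structure(
    list(
      schema = schema, coefficients = coefficients, bounds = bounds,
      outcome = outcome, outcome_scale = outcome_scale,
      diagnostics = diagnostics, provenance = provenance
    ),
    class = "ipa_model"
  )
}

#' Predict outcomes for new patients
#'
#' Normalizes `newdata` against the model's own bounds, expands it through the
#' model's term schema and returns `V M`. For a model fitted on the
#' normalized outcome scale, `scale = "raw"` (the default) maps predictions
#' back to decimal acuity through the outcome bounds stored in the model.
#'
#' @param object A fitted `ipa_model`.
#' @param newdata Cohort data frame covering the model's factors.
#' @param normalized Set `TRUE` if `newdata` is already normalized.
#' @param scale `"raw"` for decimal acuity, `"model"` for the scale the
#'   coefficients act on.
#' @param policy Out-of-range policy passed to [normalize_cohort()].
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.ipa_model <- function(object, newdata, normalized = FALSE,
                              scale = c("raw", "model"),
                              policy = "allow", ...) {
  scale <- match.arg(scale)
  norm <- if (normalized) {
    as_tibble(newdata)
  } else {
    normalize_cohort(newdata, bounds = object$bounds[object$bounds$factor != object$outcome, ],
                     policy = policy)
  }
  V <- build_design_matrix(norm, object$schema)
  pred <- drop(V %*% object$coefficients)
  if (scale == "raw" && identical(object$outcome_scale, "normalized")) {
    ob <- object$bounds[object$bounds$factor == object$outcome, ]
    if (nrow(ob) != 1) {
      abort("Model lacks outcome bounds; cannot map to the raw scale.",
        class = "ipa_error_bounds"
      )
    }
    pred <- denormalize_value(pred, ob$min, ob$max)
  }
  pred
}

#' @export
print.ipa_model <- function(x, ...) {
  k <- sum(x$schema$kind == "single")
  cat("<ipa_model> ", k, " factors, ", nrow(x$schema), " terms; outcome `",
    x$outcome, "` (", x$outcome_scale, " scale)\n",
    sep = ""
  )
  if (!is.null(x$diagnostics)) {
    d <- x$diagnostics
    cat(sprintf(
      "  training n = %d, loss = %.4f, r = %.4f, r^2 = %.4f\n",
      d$n, d$loss, d$correlation, d$variance
    ))
  }
  invisible(x)
}

#' Tidy a fitted model into one row per term
#'
#' @param x An `ipa_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `symbol`, `kind`, `estimate`, `rank`
#'   (1 = largest coefficient magnitude).
#' @export
tidy.ipa_model <- function(x, ...) {
  rt <- rank_terms(x)
  tibble(
    term = x$schema$label,
    symbol = x$schema$symbol,
    kind = x$schema$kind,
    estimate = unname(x$coefficients),
    rank = rt$rank
  )
}

#' One-row model summary
#'
#' @param x An `ipa_model`.
#' @param ... Unused.
#' @return Tibble with `n`, `n_factors`, `n_terms`, `loss`, `correlation`,
#'   `variance`, `slope`, `intercept` (training diagnostics; `NA` for models
#'   assembled from published coefficients without their training data).
#' @export
glance.ipa_model <- function(x, ...) {
  d <- x$diagnostics
  if (is.null(d)) {
    d <- tibble(
      n = x$provenance$n %||% NA_integer_, loss = NA_real_,
      correlation = NA_real_, variance = NA_real_,
      slope = NA_real_, intercept = NA_real_
    )
  }
  tibble(
    n = d$n,
    n_factors = sum(x$schema$kind == "single"),
    n_terms = nrow(x$schema),
    loss = d$loss,
    correlation = d$correlation,
    variance = d$variance,
    slope = d$slope,
    intercept = d$intercept
  )
}
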