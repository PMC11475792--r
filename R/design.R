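#' Number of model terms for k factors
#'
#' The model carries each factor singly, every unordered pair as an
#' interaction product, and one constant: `k + k(k-1)/2 + 1` terms. Seven
#' factors give the full 29-term formula; three give the reduced 7-term one.
#'
#' @param k Number of risk factors, `k >= 1`.
#' @return Integer term count.
#' @export
#' @examples
#' term_count(7) # 29
term_count <- function(k) {
  if (any(!is.finite(k)) || any(k < 1) || any(k != floor(k))) {
    abort("`k` must be a positive integer.", class = "ipa_error_domain")
  }
  as.integer(k + k * (k - 1) / 2 + 1)
}

#' Build the ordered term schema
#'
#' Enumerates the model terms in the canonical order that defines the
#' coefficient symbols: singles in the given factor order, then pairs `(i, j)`
#' with `i < j` in lexicographic index order, then the constant last. For the
#' seven canonical factors this yields `a1`...`a29`, with e.g. term 12 being
#' Age x LDL-C and term 29 the constant.
#'
#' @param factors Ordered character vector of unique factor names.
#' @return A tibble with columns `index`, `kind` (`single`/`pair`/`constant`),
#'   `f1`, `f2`, `label`, `symbol`.
#' @export
#' @examples
#' build_term_schema(c("a", "b", "c"))
build_term_schema <- function(factors = ipa_factors()) {
  factors <- as.character(factors)
  if (length(factors) < 1 || any(!nzchar(factors))) {
    abort("Need at least one non-empty factor name.", class = "ipa_error_schema")
  }
  if (anyDuplicated(factors)) {
    abort("Factor names must be unique.", class = "ipa_error_schema")
  }
  k <- length(factors)
  singles <- tibble(
    kind = "single", f1 = factors, f2 = NA_character_,
    label = factor_display(factors)
  )
  pairs <- NULL
  if (k >= 2) {
    idx <- combn(k, 2)
    pairs <- tibble(
      kind = "pair", f1 = factors[idx[1, ]], f2 = factors[idx[2, ]],
      label = paste(
        factor_display(factors[idx[1, ]]), "×",
        factor_display(factors[idx[2, ]])
      )
    )
  }
  const <- tibble(kind = "constant", f1 = NA_character_, f2 = NA_character_,
                  label = "Constant")
  schema <- dplyr::bind_rows(singles, pairs, const)
  schema$index <- seq_len(nrow(schema))
  schema$symbol <- paste0("a", schema$index)
  stopifnot(nrow(schema) == term_count(k))
  schema[, c("index", "kind", "f1", "f2", "label", "symbol")]
}

#' Expand a normalized cohort into the model design matrix
#'
#' One row per patient, one column per schema term: single columns carry the
#' normalized factor values, pair columns their elementwise products, and the
#' constant column is all ones. With inputs in `\[-1, +1\]` every entry stays in
#' `\[-1, +1\]`.
#'
#' @param data Normalized cohort (see [normalize_cohort()]).
#' @param schema Term schema from [build_term_schema()]; defaults to the
#'   schema over the canonical factors present in `data`.
#' @return Numeric matrix `n x p` with term symbols as column names, the
#'   schema as attribute `"schema"`, and patient ids as attribute `"row_ids"`.
#' @export
build_design_matrix <- function(data, schema = NULL) {
  data <- as_tibble(data)
  if (is.null(schema)) {
    schema <- build_term_schema(intersect(ipa_factors(), names(data)))
  }
  needed <- unique(stats::na.omit(c(schema$f1, schema$f2)))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(
      paste0(
        "Design schema names factor(s) absent from the table: ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "ipa_error_schema"
    )
  }
  n <- nrow(data)
  cols <- purrr::pmap(
    list(schema$kind, schema$f1, schema$f2),
    function(kind, f1, f2) {
      switch(kind,
        single = as.numeric(data[[f1]]),
        pair = as.numeric(data[[f1]]) * as.numeric(data[[f2]]),
        constant = rep(1, n),
        abort(paste0("Unknown term kind `", kind, "`."), class = "ipa_error_schema")
      )
    }
  )
  V <- do.call(cbind, cols)
  colnames(V) <- schema$symbol
  attr(V, "schema") <- schema
  attr(V, "row_ids") <- as.character(data[["patient_id"]] %||% seq_len(n))
  V
}
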