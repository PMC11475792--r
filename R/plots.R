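#' Plot the AT distribution of an agreement report
#'
#' Histogram of the per-patient AT percentages with the report's thresholds
#' drawn as vertical reference lines (on both sides when the report compares
#' `|AT|`).
#'
#' @param object An `agreement_report`.
#' @param binwidth Histogram bin width in percent (default 6).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, binwidth = 6, ...) {
  df <- tibble(at = object$at)
  thr <- object$thresholds
  vlines <- if (object$signed) thr else c(-thr, thr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$at)) +
    ggplot2::geom_histogram(
      binwidth = binwidth, boundary = 0,
      fill = "steelblue", colour = "white"
    ) +
    ggplot2::geom_vline(xintercept = vlines, linetype = "dashed") +
    ggplot2::labs(
      x = "AT (%)", y = "patients",
      title = sprintf(
        "Agreement distribution: %.2f%% +/- %.2f%% (n = %d)",
        object$at_mean, object$at_sd, object$n
      )
    )
}

#' Plot coefficient magnitudes of a fitted model
#'
#' Terms ordered by rank, bar length giving the absolute coefficient and
#' colour its sign; the quantity the factor-significance ranking is read
#' from.
#'
#' @param object An `ipa_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ipa_model <- function(object, ...) {
  rt <- rank_terms(object)
  rt$term <- stats::reorder(rt$term, -rt$rank)
  ggplot2::ggplot(rt, ggplot2::aes(
    x = abs(.data$coefficient), y = .data$term,
    fill = .data$coefficient > 0
  )) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"),
      labels = c(`TRUE` = "positive", `FALSE` = "negative"),
      name = "sign"
    ) +
    ggplot2::labs(x = "|coefficient|", y = NULL, title = "Term significance by coefficient magnitude")
}

#' Plot a truncation ladder
#'
#' Training loss and fit variance against the number of retained factors:
#' the visual counterpart of the factor-ablation table.
#'
#' @param ladder Tibble from [truncation_ladder()].
#' @return A ggplot object.
#' @export
plot_truncation_ladder <- function(ladder) {
  long <- tidyr::pivot_longer(
    ladder[, c("n_factors", "loss", "variance")],
    cols = c("loss", "variance"), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_factors, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_reverse(breaks = ladder$n_factors) +
    ggplot2::labs(
      x = "factors retained", y = NULL,
      title = "Model truncation: fit quality vs factors retained"
    )
}

#' Plot a risk grid as acuity tiles
#'
#' Tiles of predicted decimal acuity over the first two axis factors,
#' faceted over the third (if present); points predicted below the risk
#' threshold are outlined.
#'
#' @param object An `ipa_grid` from [evaluate_reduced_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ipa_grid <- function(object, ...) {
  axes <- attr(object, "axes")$factor
  if (length(axes) < 2) {
    abort("Need at least two axis factors to draw tiles.", class = "ipa_error_domain")
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[axes[2]]], y = .data[[axes[1]]], fill = .data$predicted_bcva
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = object[object$risk_flag, , drop = FALSE],
      shape = 4, size = 0.8, colour = "black"
    ) +
    ggplot2::scale_fill_viridis_c(name = "predicted\nacuity") +
    ggplot2::labs(
      x = axes[2], y = axes[1],
      title = "Predicted acuity over the factor grid (x = below risk threshold)"
    )
  if (length(axes) >= 3) {
    p <- p + ggplot2::facet_wrap(
      ggplot2::vars(!!rlang::sym(axes[3])),
      labeller = ggplot2::label_both
    )
  }
  p
}
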