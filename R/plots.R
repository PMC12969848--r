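#' Bland-Altman plot
#'
#' Differences (`estimate - reference`) against the pairwise means, with the
#' bias and 95% limits of agreement as horizontal lines.
#'
#' @param estimate,reference numeric vectors of paired TBSA values (pp).
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(estimate, reference) {
  ba <- bland_altman(estimate, reference)
  df <- tibble::tibble(avg = (estimate + reference) / 2, diff = estimate - reference)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid", colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Mean of methods (pp TBSA)",
                  y = "Difference (estimate - reference, pp)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Paired absolute-error plot
#'
#' Per-case absolute TBSA error of the model and the physician median
#' against the panel, with the non-inferiority margin and the wider 5 pp
#' band as dashed reference lines.
#'
#' @param deltas tibble from [compute_paired_deltas()].
#' @param margin non-inferiority margin to draw (default 3 pp).
#' @return a ggplot object.
#' @export
plot_paired_errors <- function(deltas, margin = 3) {
  long <- tidyr::pivot_longer(
    deltas[c("region_case_id", "model_abs_error", "physician_abs_error")],
    -"region_case_id", names_to = "method", values_to = "abs_error")
  long$method <- sub("_abs_error", "", long$method)
  ord <- deltas$region_case_id[order(deltas$panel_tbsa)]
  long$region_case_id <- factor(long$region_case_id, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region_case_id, y = .data$abs_error,
                                     colour = .data$method, shape = .data$method)) +
    ggplot2::geom_hline(yintercept = c(margin, 5), linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "Region-case (ordered by panel TBSA)",
                  y = "Absolute TBSA error (pp)",
                  title = "Per-case absolute error vs expert panel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Calibration plot for a fitted calibration line
#'
#' Scatter of estimates against the reference with the fitted OLS line and
#' the identity line.
#'
#' @param object a `calibration_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$reference, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Reference TBSA (pp)", y = "Estimated TBSA (pp)",
                  title = sprintf("Calibration: %.2f + %.2f x reference (R2 = %.2f)",
                                  object$intercept, object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Bootstrap distribution of the non-inferiority statistic
#'
#' Histogram of the cluster-bootstrap replicates of the Hodges-Lehmann
#' statistic with the point estimate, the one-sided upper bound and the
#' margin marked.
#'
#' @param object a `noninf_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.noninf_result <- function(object, ...) {
  df <- tibble::tibble(hl = object$bootstrap$replicates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hl)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$hl_estimate, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$upper_bound, colour = "darkred") +
    ggplot2::geom_vline(xintercept = object$margin, linetype = "dashed") +
    ggplot2::labs(x = "Hodges-Lehmann median of paired deltas (pp)",
                  y = "Bootstrap replicates",
                  title = sprintf("Non-inferiority bootstrap: %s", object$decision)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
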