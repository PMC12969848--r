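#' Tidy a non-inferiority result
#'
#' @param x a `noninf_result` from [primary_analysis()].
#' @param ... unused.
#' @return a one-row tibble with the estimate, bound, margin and decision.
#' @export
tidy.noninf_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$hl_estimate,
    upper_bound = x$upper_bound,
    margin = x$margin,
    decision = x$decision,
    alpha = x$alpha
  )
}

#' @rdname tidy.noninf_result
#' @export
glance.noninf_result <- function(x, ...) {
  tibble::tibble(
    n_cases = x$n_cases,
    n_patients = x$n_patients,
    n_resamples = x$n_resamples,
    decision = x$decision
  )
}

#' Tidy a calibration fit
#'
#' @param x a `calibration_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per coefficient; `glance()`: one-row model
#'   summary.
#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "reference"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname tidy.calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope,
                 r_squared = x$r_squared, n = x$n)
}
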