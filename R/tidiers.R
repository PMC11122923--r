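#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a filtration-model fit
#'
#' @param x A `filtration_fit` from [fit_time_course()] or
#'   [fit_steady_state()].
#' @param ... Unused.
#'
#' @return A tibble with one row per parameter: `term`, `estimate`, `units`.
#' @export
tidy.filtration_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "ve", "q_th"),
    estimate = c(x$model$k, x$model$ve, x$model$q_th),
    units = c("uL^2 mm^-4 min^-1", "uL", "1/min")
  )
}

#' One-row summary of a filtration-model fit
#'
#' @param x A `filtration_fit`.
#' @param ... Unused.
#'
#' @return A one-row tibble: `type`, `k`, `ve`, `rms_error`, `converged`,
#'   `n_iter`, `nobs`.
#' @export
glance.filtration_fit <- function(x, ...) {
  tibble::tibble(
    type = x$type,
    k = x$model$k,
    ve = x$model$ve,
    rms_error = x$rms_error,
    converged = x$converged,
    n_iter = x$n_iter,
    nobs = nrow(x$data)
  )
}
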