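#' Construct a filtration curve
#'
#' A filtration curve is one device run: plasma volume sampled over time,
#' tagged with the effective filtration area of the device. Stored as a tibble
#' with columns `time_s` and `volume_uL` plus `area_mm2`/`label` attributes,
#' so it pipes straight into dplyr/ggplot2 while keeping its metadata.
#'
#' @param time_s Sample times in seconds, strictly increasing, starting >= 0.
#' @param volume_uL Plasma volumes in uL, non-negative.
#' @param area_mm2 Effective filtration area of the device (mm^2).
#' @param label Optional free-text label for the run.
#'
#' @return A tibble of class `filtration_curve`.
#' @examples
#' filtration_curve(c(0, 30, 60), c(0, 1.2, 1.7), area_mm2 = 28.26)
#' @export
filtration_curve <- function(time_s, volume_uL, area_mm2, label = "") {
  if (length(time_s) != length(volume_uL)) {
    abort("`time_s` and `volume_uL` must have equal length.")
  }
  if (length(time_s) < 3) abort("A filtration curve needs at least 3 samples.")
  if (any(diff(time_s) <= 0) || time_s[1] < 0) {
    abort("`time_s` must be strictly increasing and start at >= 0.")
  }
  if (any(volume_uL < 0)) abort("`volume_uL` must be >= 0.")
  if (!is.numeric(area_mm2) || length(area_mm2) != 1 || area_mm2 <= 0) {
    abort("`area_mm2` must be a single positive number.")
  }
  out <- tibble::tibble(time_s = as.numeric(time_s), volume_uL = as.numeric(volume_uL))
  attr(out, "area_mm2") <- as.numeric(area_mm2)
  attr(out, "label") <- label
  class(out) <- c("filtration_curve", class(out))
  out
}

#' @rdname filtration_curve
#' @param curve A `filtration_curve`.
#' @export
curve_area <- function(curve) {
  a <- attr(curve, "area_mm2", exact = TRUE)
  if (is.null(a)) abort("Not a filtration_curve: missing `area_mm2` attribute.")
  a
}

#' Construct a calibration set
#'
#' Pairs of (effective filtration area, steady-state plasma volume) measured
#' across devices, the input to [fit_steady_state()].
#'
#' @param area_mm2 Effective filtration areas (mm^2), positive.
#' @param vq_uL Steady-state plasma volumes (uL), non-negative.
#' @param replicate Optional replicate identifier per row.
#'
#' @return A tibble of class `calibration_set` with columns `area_mm2`,
#'   `vq_uL` and (if given) `replicate`.
#' @export
calibration_set <- function(area_mm2, vq_uL, replicate = NULL) {
  if (length(area_mm2) != length(vq_uL)) {
    abort("`area_mm2` and `vq_uL` must have equal length.")
  }
  if (any(area_mm2 <= 0)) abort("All areas must be > 0.")
  if (any(vq_uL < 0)) abort("All volumes must be >= 0.")
  out <- tibble::tibble(area_mm2 = as.numeric(area_mm2), vq_uL = as.numeric(vq_uL))
  if (!is.null(replicate)) out$replicate <- replicate
  class(out) <- c("calibration_set", class(out))
  out
}

#' Detect the steady-state point of a sampled filtration curve
#'
#' Applies the relative-rate criterion to discrete data: for each interval the
#' backward-difference rate `q_i = (V_i - V_{i-1}) / ((t_i - t_{i-1}) V_i)` is
#' computed in per-minute units (normalising by the current volume keeps q
#' defined whenever `V_i > 0`; intervals ending at zero volume are skipped).
#' The steady state is declared at the first sample where `q <= q_th` has held
#' for `consecutive` successive intervals — requiring several intervals
#' suppresses spurious early detections from measurement noise.
#'
#' @param curve A [filtration_curve()] (or a data frame with `time_s`,
#'   `volume_uL` columns).
#' @param q_th Relative-rate threshold, fraction per minute. Default 0.05.
#' @param consecutive Number of successive sub-threshold intervals required.
#'   Default 3.
#'
#' @return A one-row tibble: `tau_q_s` (detected time, s), `v_q_uL` (volume at
#'   detection), `index` (row index of the detection sample), `achieved`
#'   (logical; `FALSE` with the last index if the criterion is never met).
#' @export
detect_steady_state <- function(curve, q_th = 0.05, consecutive = 3) {
  if (!all(c("time_s", "volume_uL") %in% names(curve))) {
    abort("`curve` must have `time_s` and `volume_uL` columns.")
  }
  if (consecutive < 1) abort("`consecutive` must be >= 1.")
  n <- nrow(curve)
  if (n < consecutive + 1) {
    abort(sprintf("Curve has %d points; need at least consecutive + 1 = %d.", n, consecutive + 1))
  }
  t_min <- curve$time_s / 60
  v <- curve$volume_uL
  dv <- diff(v)
  dt <- diff(t_min)
  v_now <- v[-1]
  q <- ifelse(v_now > 0, dv / (dt * v_now), NA_real_)
  ok <- !is.na(q) & q <= q_th
  run <- 0L
  hit <- NA_integer_
  for (i in seq_along(ok)) {
    if (is.na(q[i])) next # zero-volume interval: neither hit nor reset
    run <- if (ok[i]) run + 1L else 0L
    if (run >= consecutive) {
      hit <- i + 1L # interval i ends at curve row i + 1
      break
    }
  }
  achieved <- !is.na(hit)
  idx <- if (achieved) hit else n
  tibble::tibble(
    tau_q_s = curve$time_s[idx],
    v_q_uL = v[idx],
    index = idx,
    achieved = achieved
  )
}

# Shared Levenberg-Marquardt driver on (log k, log ve') with ve' = ve + eps,
# so positivity is structural rather than constrained. Deterministic: fixed
# initialisation, ftol 1e-10, up to 1000 iterations.
.VE_EPS <- 1e-8

.fit_lm <- function(resid_fun, k0, ve0, q_th, data, type) {
  par0 <- c(log_k = log(k0), log_ve = log(ve0 + .VE_EPS))
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(p) resid_fun(exp(p[[1]]), exp(p[[2]]) - .VE_EPS),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 1000)
  )
  k_hat <- exp(fit$par[[1]])
  ve_hat <- max(exp(fit$par[[2]]) - .VE_EPS, 0)
  res <- resid_fun(k_hat, ve_hat)
  structure(
    list(
      model = filtration_model(k = k_hat, ve = ve_hat, q_th = q_th),
      residuals = res,
      rms_error = sqrt(mean(res^2)),
      converged = fit$info %in% 1:4,
      n_iter = fit$niter,
      data = data,
      type = type
    ),
    class = "filtration_fit"
  )
}

#' Fit the filtration model to time-course data
#'
#' Unweighted least-squares fit of the closed-form volume-time law
#' `V(tau) = sqrt(k A^2 tau + Ve^2) - Ve` to one or more filtration curves,
#' sharing a single (k, ve) across curves of different areas. Positivity of
#' both parameters is enforced by optimising on the log scale; the fit starts
#' from the pure square-root law (`ve = 0`, k from a through-origin fit of
#' `V^2` against `A^2 tau`), making results deterministic.
#'
#' @param curves A single [filtration_curve()] or a list of them.
#' @param q_th Steady-state threshold carried into the fitted model
#'   (fraction/min). Default 0.05.
#'
#' @return A `filtration_fit` object: `$model` (the fitted
#'   [filtration_model()]), `$residuals` (observed - predicted, uL),
#'   `$rms_error`, `$converged`, `$n_iter`. Supports [generics::tidy()],
#'   [generics::glance()], [predict()] and [ggplot2::autoplot()].
#' @export
fit_time_course <- function(curves, q_th = 0.05) {
  if (inherits(curves, "filtration_curve") || is.data.frame(curves)) curves <- list(curves)
  if (length(curves) < 1) abort("Need at least one curve.")
  for (cv in curves) {
    if (!all(c("time_s", "volume_uL") %in% names(cv)) || nrow(cv) < 3) {
      abort("Each curve needs columns `time_s`, `volume_uL` and >= 3 points.")
    }
    if (all(cv$volume_uL == 0)) abort("Degenerate curve: all volumes are zero.")
  }
  tau <- unlist(lapply(curves, function(cv) cv$time_s / 60))
  vol <- unlist(lapply(curves, function(cv) cv$volume_uL))
  area <- unlist(lapply(curves, function(cv) rep(curve_area(cv), nrow(cv))))
  pos <- tau > 0 & vol > 0
  if (sum(pos) < 2) abort("Curve data are under-determined: need >= 2 positive samples.")
  # ve = 0 start: V^2 = k A^2 tau through the origin
  k0 <- sum(vol[pos]^2 * area[pos]^2 * tau[pos]) / sum((area[pos]^2 * tau[pos])^2)
  if (!is.finite(k0) || k0 <= 0) k0 <- 1e-3
  resid_fun <- function(k, ve) vol - (sqrt(k * area^2 * tau + ve^2) - ve)
  .fit_lm(resid_fun, k0, 0, q_th,
    data = tibble::tibble(tau_min = tau, area_mm2 = area, volume_uL = vol),
    type = "time_course"
  )
}

#' Fit the filtration model to an area-volume calibration
#'
#' Least-squares fit of the steady-state law
#' `Vq(A) = sqrt(k A^2/(2 q_th) + Ve^2/4) - Ve/2` to measured
#' (area, steady-state volume) pairs. Initial k comes from a through-origin
#' linear fit of Vq against A (the `ve = 0` regime); positivity is enforced on
#' the log scale as in [fit_time_course()].
#'
#' @param cal A [calibration_set()] (or data frame with `area_mm2`, `vq_uL`).
#' @param q_th Steady-state threshold (fraction/min). Default 0.05.
#'
#' @return A `filtration_fit` object (see [fit_time_course()]).
#' @export
fit_steady_state <- function(cal, q_th = 0.05) {
  if (!all(c("area_mm2", "vq_uL") %in% names(cal))) {
    abort("`cal` must have `area_mm2` and `vq_uL` columns.")
  }
  if (length(unique(cal$area_mm2)) < 2) {
    abort("Need at least 2 distinct areas to identify the model.")
  }
  A <- cal$area_mm2
  vq <- cal$vq_uL
  slope <- sum(A * vq) / sum(A^2) # through-origin Vq = A sqrt(k/(2 q_th))
  k0 <- 2 * q_th * slope^2
  if (!is.finite(k0) || k0 <= 0) k0 <- 1e-3
  resid_fun <- function(k, ve) {
    vq - (sqrt(k * A^2 / (2 * q_th) + 0.25 * ve^2) - 0.5 * ve)
  }
  .fit_lm(resid_fun, k0, 0, q_th,
    data = tibble::tibble(area_mm2 = A, vq_uL = vq),
    type = "steady_state"
  )
}

#' @export
print.filtration_fit <- function(x, ...) {
  cat(sprintf(
    "<filtration_fit: %s, %d points>\n", x$type, nrow(x$data)
  ))
  cat(sprintf(
    "  k = %.5g uL^2 mm^-4 min^-1, Ve = %.5g uL (q_th = %.3g /min)\n",
    x$model$k, x$model$ve, x$model$q_th
  ))
  cat(sprintf(
    "  rms error = %.4g uL, converged = %s (%d iterations)\n",
    x$rms_error, x$converged, x$n_iter
  ))
  invisible(x)
}

#' Predictions from a fitted filtration model
#'
#' @param object A `filtration_fit`.
#' @param newdata Optional tibble. For a time-course fit: columns `tau_min`
#'   and `area_mm2`. For a steady-state fit: column `area_mm2`. Defaults to
#'   the training data.
#' @param ... Unused.
#' @return Numeric vector of predicted volumes (uL).
#' @export
predict.filtration_fit <- function(object, newdata = NULL, ...) {
  d <- newdata %||% object$data
  if (object$type == "time_course") {
    volume_at_time(object$model, d$area_mm2, d$tau_min)
  } else {
    steady_state_volume(object$model, d$area_mm2)
  }
}
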