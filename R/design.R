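# Range over which the steady-state area-volume calibration has been
# validated on the bench; designs outside it are computed but flagged.
.VALIDATED_RANGE_UL <- c(5, 30)

#' Effective filtration area required for a target plasma volume
#'
#' Inverts the steady-state law in closed form:
#' `A = sqrt(2 q_th * target * (target + Ve) / k)`, so that
#' `steady_state_volume(model, A)` returns exactly the target. Feasibility is
#' checked against the geometry's minimum area (below which inlet capillarity
#' stalls the flow) and against the validated 5-30 uL design range
#' (out-of-range targets are still computed, but flagged).
#'
#' @param target Target plasma volume(s), uL, strictly positive. Vectorised.
#' @param model A [filtration_model()] (typically a fitted one).
#' @param geom A [device_geometry()]; only `A_min` is used. Default bound
#'   7 mm^2.
#'
#' @return A tibble with one row per target: `target_uL`, `area_mm2`,
#'   `predicted_uL`, `rel_error`, `feasible`, `reason`.
#' @examples
#' m <- filtration_model(k = 0.1, ve = 0)
#' required_area(10, m) # 10 mm^2
#' @export
required_area <- function(target, model, geom = device_geometry()) {
  stopifnot(inherits(model, "filtration_model"), inherits(geom, "device_geometry"))
  if (length(target) < 1) abort("`target` must be nonempty.")
  if (any(target <= 0)) abort("`target` volumes must be > 0.")
  A <- sqrt(2 * model$q_th * target * (target + model$ve) / model$k)
  predicted <- steady_state_volume(model, A)
  below_min <- A < geom$A_min
  out_of_range <- target < .VALIDATED_RANGE_UL[1] | target > .VALIDATED_RANGE_UL[2]
  reason <- dplyr::case_when(
    below_min ~ sprintf(
      "required area %.3g mm^2 is below the %.3g mm^2 minimum (inlet capillary stall)",
      A, geom$A_min
    ),
    out_of_range ~ sprintf(
      "target outside the validated %g-%g uL range (computed, unvalidated)",
      .VALIDATED_RANGE_UL[1], .VALIDATED_RANGE_UL[2]
    ),
    .default = ""
  )
  tibble::tibble(
    target_uL = as.numeric(target),
    area_mm2 = A,
    predicted_uL = predicted,
    rel_error = (predicted - target) / target,
    feasible = !below_min,
    reason = reason
  )
}

#' Design report over a grid of target volumes
#'
#' Computes [required_area()] for each target under the design model, then
#' re-evaluates the designed areas under an evaluation model (by default the
#' same one). Supplying a different evaluation model supports the
#' calibrate-on-noisy-data / evaluate-on-truth experiment: `rel_error` then
#' measures how far the volume actually delivered by each designed device
#' deviates from its target.
#'
#' @param targets Target plasma volumes (uL), nonempty, positive.
#' @param model Design [filtration_model()] (e.g. fitted from calibration).
#' @param geom A [device_geometry()] for the feasibility bound.
#' @param eval_model Model used to evaluate the delivered volume at the
#'   designed areas; defaults to `model`.
#'
#' @return A tibble, one row per target, columns as in [required_area()] with
#'   `predicted_uL` and `rel_error` computed under `eval_model`.
#' @export
design_report <- function(targets, model, geom = device_geometry(), eval_model = model) {
  if (length(targets) < 1) abort("`targets` must be nonempty.")
  stopifnot(inherits(eval_model, "filtration_model"))
  out <- required_area(targets, model, geom)
  delivered <- steady_state_volume(eval_model, out$area_mm2)
  out$predicted_uL <- delivered
  out$rel_error <- (delivered - out$target_uL) / out$target_uL
  out
}
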