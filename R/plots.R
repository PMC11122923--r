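#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a filtration curve
#'
#' Measured plasma volume against time, optionally with the closed-form curve
#' of a model overlaid.
#'
#' @param object A [filtration_curve()].
#' @param model Optional [filtration_model()] to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filtration_curve <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s / 60, y = .data$volume_uL)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::labs(
      x = "Filtration time (min)", y = "Plasma volume (uL)",
      title = sprintf("Filtration curve, A = %.4g mm^2", curve_area(object))
    )
  if (!is.null(model)) {
    grid <- tibble::tibble(time_s = seq(0, max(object$time_s), length.out = 200))
    grid$volume_uL <- volume_at_time(model, curve_area(object), grid$time_s / 60)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Plot a filtration-model fit
#'
#' Observed data with the fitted curve: volume vs time for time-course fits,
#' steady-state volume vs area for calibration fits.
#'
#' @param object A `filtration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filtration_fit <- function(object, ...) {
  d <- object$data
  if (object$type == "steady_state") {
    grid <- tibble::tibble(area_mm2 = seq(0, max(d$area_mm2) * 1.05, length.out = 200))
    grid$vq_uL <- steady_state_volume(object$model, grid$area_mm2)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$area_mm2, y = .data$vq_uL)) +
      ggplot2::geom_point(colour = "grey30") +
      ggplot2::geom_line(data = grid, colour = "firebrick") +
      ggplot2::labs(
        x = "Effective filtration area (mm^2)",
        y = "Steady-state plasma volume (uL)",
        title = sprintf(
          "Steady-state calibration fit: k = %.3g, Ve = %.3g uL",
          object$model$k, object$model$ve
        )
      )
  } else {
    d$predicted <- predict(object)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$tau_min, y = .data$volume_uL,
                                    group = factor(.data$area_mm2))) +
      ggplot2::geom_point(ggplot2::aes(colour = factor(.data$area_mm2))) +
      ggplot2::geom_line(ggplot2::aes(y = .data$predicted, colour = factor(.data$area_mm2))) +
      ggplot2::labs(
        x = "Filtration time (min)", y = "Plasma volume (uL)",
        colour = "Area (mm^2)",
        title = sprintf(
          "Time-course fit: k = %.3g, Ve = %.3g uL",
          object$model$k, object$model$ve
        )
      )
  }
}

#' Plot a design report
#'
#' Delivered (or predicted) volume against target, with the 10% error band
#' within which the reference devices were validated.
#'
#' @param report A tibble from [design_report()].
#' @return A ggplot object.
#' @export
plot_design_report <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$target_uL, y = .data$predicted_uL)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$target_uL * 0.9, ymax = .data$target_uL * 1.1),
      alpha = 0.15, fill = "steelblue"
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$feasible), size = 3, colour = "firebrick") +
    ggplot2::labs(
      x = "Target plasma volume (uL)", y = "Delivered plasma volume (uL)",
      shape = "Feasible", title = "Designed areas: delivered vs target volume (10% band)"
    )
}
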