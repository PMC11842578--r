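#' Plot a force trace
#'
#' Transverse, axial and total force against time, with the annotated
#' rupture sample marked when present.
#'
#' @param object A [force_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot force_trace
#' @export
autoplot.force_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("time_s", "ft_mN", "fz_mN", "f_total_mN")],
    -"time_s", names_to = "channel", values_to = "force_mN"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$force_mN,
                                          colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(ft_mN = "#1b9e77", fz_mN = "#7570b3",
                 f_total_mN = "#d95f02"),
      labels = c(ft_mN = "transverse", fz_mN = "axial",
                 f_total_mN = "total")
    ) +
    ggplot2::labs(x = "time (s)", y = "force (mN)", colour = NULL) +
    ggplot2::theme_minimal()
  ri <- rupture_annotation(object)
  if (!is.null(ri)) {
    p <- p + ggplot2::geom_vline(xintercept = object$time_s[ri],
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot calibration fit quality
#'
#' Decoded against true force per axis with the fitted through-origin
#' slope; a perfectly calibrated sensor falls on the identity line.
#'
#' @param object A fitted [fbg_calibration()] (needs its fit report).
#' @param sweep The sweep the model was fitted on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fbg_calibration
#' @export
autoplot.fbg_calibration <- function(object, sweep, ...) {
  pred <- predict_forces(sweep, object)
  long <- dplyr::bind_rows(
    tibble(axis = "fx", true_mN = sweep$fx_mN, est_mN = pred$fx_hat_mN),
    tibble(axis = "fy", true_mN = sweep$fy_mN, est_mN = pred$fy_hat_mN),
    tibble(axis = "fz", true_mN = sweep$fz_mN, est_mN = pred$fz_hat_mN)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$true_mN, .data$est_mN)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50",
                         linetype = "dashed") +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(x = "applied force (mN)", y = "decoded force (mN)") +
    ggplot2::theme_minimal()
}

#' Plot grouped positioning-error summaries
#'
#' Box-style display of the per-group quartiles with means and outliers.
#'
#' @param object An `error_summary` from
#'   [summarize_positioning_errors()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot error_summary
#' @export
autoplot.error_summary <- function(object, ...) {
  pts <- tidyr::unnest(object[, c("group", "outliers")],
                       "outliers")
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$group))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                           width = 0.4) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median), shape = 3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), colour = "red",
                        size = 1) +
    (if (nrow(pts)) ggplot2::geom_point(
      data = pts, ggplot2::aes(x = factor(.data$group), y = .data$outliers),
      shape = 1) else NULL) +
    ggplot2::labs(x = "group", y = "positioning error (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a transport simulation
#'
#' True and measured positions of the transported cell over time.
#'
#' @param object A `transport_sim` from [simulate_transport()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transport_sim
#' @export
autoplot.transport_sim <- function(object, ...) {
  traj <- object$trajectory
  p <- ggplot2::ggplot(traj, ggplot2::aes(.data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$x_um)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$measured_um), size = 0.3,
                        alpha = 0.5) +
    ggplot2::labs(x = "time (s)", y = "position (µm)") +
    ggplot2::theme_minimal()
  if (isTRUE(object$settled)) {
    p <- p + ggplot2::geom_vline(xintercept = object$settle_time_s,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
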