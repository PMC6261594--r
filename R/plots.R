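#' Plot a force/power series
#'
#' Transient aerodynamic force components and power against time.
#'
#' @param series Force/power tibble (`time_s`, `Fx_N`, `Fy_N`, `Fz_N`,
#'   `P_W`).
#' @return A ggplot object.
#' @export
plot_force_power <- function(series) {
  long <- tidyr::pivot_longer(series,
                              dplyr::any_of(c("Fx_N", "Fy_N", "Fz_N", "P_W")),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Transient aerodynamic force and power")
}

#' @exportS3Method ggplot2::autoplot
autoplot.simulation_result <- function(object, ...) plot_force_power(object$series)

#' @exportS3Method ggplot2::autoplot
autoplot.flight_metrics <- function(object, ...) {
  ggplot2::ggplot(object$area_series,
                  ggplot2::aes(x = .data$time_s, y = 1e4 * .data$area_m2,
                               colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(area ~ (cm^2)),
                  title = "Planform area over the flap cycles")
}

#' @exportS3Method ggplot2::autoplot
autoplot.cycle_stats <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~column, scales = "free_y") +
    ggplot2::labs(x = "flap cycle", y = "cycle mean",
                  title = "Cycle-averaged force and power")
}

#' Plot marker trajectories
#'
#' Wingtip-height traces coloured by region; a quick look at the flapping
#' record.
#'
#' @param traj Marker-trajectory tibble.
#' @return A ggplot object.
#' @export
plot_marker_trajectories <- function(traj) {
  ggplot2::ggplot(traj[traj$valid, ],
                  ggplot2::aes(x = .data$time_s, y = .data$z_m,
                               group = .data$marker_id,
                               colour = .data$region)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (s)", y = "z (m)", title = "Marker heights")
}
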