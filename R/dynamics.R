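#' Predict the flight trajectory from a force series (lumped mass)
#'
#' Classic fourth-order Runge-Kutta integration of
#' `d^2 x / dt^2 = F_aero(t)/M - g z_hat`, treating the animal as a point
#' mass. The aerodynamic force components are interpolated linearly between
#' series samples; weight is added here because the surface-integrated force
#' is aerodynamic only.
#'
#' @param series Force/power tibble (`time_s`, `Fx_N`, `Fy_N`, `Fz_N`).
#' @param M Body mass (kg).
#' @param g Gravitational acceleration (m/s^2); set 0 to integrate the raw
#'   force.
#' @param x0,v0 Initial position and velocity (length 3, m and m/s).
#' @param t_range Integration interval (defaults to the series range); must
#'   lie inside the series.
#' @param dt RK4 step (s); defaults to half the median series spacing.
#' @return Trajectory tibble: `time_s`, `x_m`, `y_m`, `z_m`, `vx_m_s`,
#'   `vy_m_s`, `vz_m_s`.
#' @export
predict_trajectory <- function(series, M, g = 9.81, x0 = c(0, 0, 0),
                               v0 = c(0, 0, 0), t_range = NULL, dt = NULL) {
  fw_assert(M > 0, "mass must be positive")
  tt <- series$time_s
  if (is.null(t_range)) t_range <- range(tt)
  fw_assert(t_range[1] >= min(tt) - 1e-12 && t_range[2] <= max(tt) + 1e-12,
            "requested interval [%.4g, %.4g] outside the force series [%.4g, %.4g]",
            t_range[1], t_range[2], min(tt), max(tt))
  if (is.null(dt)) dt <- median(diff(tt)) / 2
  fx <- approxfun(tt, series$Fx_N, rule = 2)
  fy <- approxfun(tt, series$Fy_N, rule = 2)
  fz <- approxfun(tt, series$Fz_N, rule = 2)
  acc <- function(t) c(fx(t), fy(t), fz(t)) / M - c(0, 0, g)

  n <- max(1L, ceiling((t_range[2] - t_range[1]) / dt - 1e-9))
  dt <- (t_range[2] - t_range[1]) / n
  x <- matrix(0, n + 1, 3); v <- matrix(0, n + 1, 3)
  x[1, ] <- x0; v[1, ] <- v0
  t <- t_range[1]
  for (i in seq_len(n)) {
    a1 <- acc(t)
    k1x <- v[i, ];               k1v <- a1
    a2 <- acc(t + dt / 2)
    k2x <- v[i, ] + dt / 2 * k1v; k2v <- a2
    k3x <- v[i, ] + dt / 2 * k2v; k3v <- a2
    a4 <- acc(t + dt)
    k4x <- v[i, ] + dt * k3v;     k4v <- a4
    x[i + 1, ] <- x[i, ] + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    v[i + 1, ] <- v[i, ] + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    t <- t + dt
  }
  tibble(time_s = t_range[1] + dt * (0:n),
         x_m = x[, 1], y_m = x[, 2], z_m = x[, 3],
         vx_m_s = v[, 1], vy_m_s = v[, 2], vz_m_s = v[, 3])
}

#' Compare a predicted trajectory with an observed one
#'
#' The observed record is resampled onto the predicted times by natural
#' cubic-spline interpolation; per-axis RMS position errors, the
#' final-position offset vector and (when velocities are present in both)
#' per-axis velocity RMS errors are reported.
#'
#' @param pred,obs Trajectory tibbles (`time_s`, `x_m`, `y_m`, `z_m`,
#'   optionally `vx_m_s` ...). Time ranges must overlap in at least 2
#'   predicted samples.
#' @return A list of class `trajectory_comparison`: `rms_m` (length 3),
#'   `final_offset_m` (length 3), `rms_velocity_m_s` (length 3 or NULL),
#'   `n_samples`.
#' @export
compare_trajectory <- function(pred, obs) {
  t0 <- max(min(pred$time_s), min(obs$time_s))
  t1 <- min(max(pred$time_s), max(obs$time_s))
  keep <- pred$time_s >= t0 - 1e-12 & pred$time_s <= t1 + 1e-12
  fw_assert(sum(keep) >= 2, "fewer than 2 overlapping samples")
  tt <- pred$time_s[keep]
  res <- function(col) {
    oi <- spline(obs$time_s, obs[[col]], xout = tt, method = "natural")$y
    pred[[col]][keep] - oi
  }
  dx <- res("x_m"); dy <- res("y_m"); dz <- res("z_m")
  rms <- function(e) sqrt(mean(e^2))
  vel_cols <- c("vx_m_s", "vy_m_s", "vz_m_s")
  rmsv <- if (all(vel_cols %in% names(pred)) && all(vel_cols %in% names(obs))) {
    setNames(vapply(vel_cols, function(cn) rms(res(cn)), numeric(1)),
             c("x", "y", "z"))
  } else NULL
  structure(list(
    rms_m = c(x = rms(dx), y = rms(dy), z = rms(dz)),
    final_offset_m = c(x = tail(dx, 1), y = tail(dy, 1), z = tail(dz, 1)),
    rms_velocity_m_s = rmsv, n_samples = length(tt)),
    class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat("<trajectory_comparison>\n")
  cat(sprintf("  RMS position error   (m):  x %.4g, y %.4g, z %.4g\n",
              x$rms_m[1], x$rms_m[2], x$rms_m[3]))
  cat(sprintf("  final position offset (m): x %+.4g, y %+.4g, z %+.4g\n",
              x$final_offset_m[1], x$final_offset_m[2], x$final_offset_m[3]))
  if (!is.null(x$rms_velocity_m_s))
    cat(sprintf("  RMS velocity error (m/s):  x %.4g, y %.4g, z %.4g\n",
                x$rms_velocity_m_s[1], x$rms_velocity_m_s[2],
                x$rms_velocity_m_s[3]))
  invisible(x)
}

#' Tidy a trajectory comparison
#'
#' @param x A `trajectory_comparison`.
#' @param ... Unused.
#' @return Tibble `axis`, `rms_m`, `final_offset_m`, `rms_velocity_m_s`.
#' @exportS3Method generics::tidy
tidy.trajectory_comparison <- function(x, ...) {
  tibble(axis = c("x", "y", "z"),
         rms_m = as.numeric(x$rms_m),
         final_offset_m = as.numeric(x$final_offset_m),
         rms_velocity_m_s = if (is.null(x$rms_velocity_m_s)) NA_real_ else
           as.numeric(x$rms_velocity_m_s))
}
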