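#' Segment a wingtip-height series into flap cycles
#'
#' Cycle boundaries are successive maxima of the tip-z series (downstroke
#' start), located sub-sample by quadratic interpolation around each discrete
#' peak.
#'
#' @param time Sample times (s), strictly increasing.
#' @param z Tip height series (m), same length.
#' @return A tibble with one row per complete cycle: `start_s`, `end_s`,
#'   `period_s`. Empty (zero rows) when fewer than two interior maxima exist.
#' @export
segment_cycles <- function(time, z) {
  fw_assert(length(time) == length(z) && length(time) >= 3,
            "time and z must have equal length >= 3")
  pk <- interp_extrema(time, z, "max")
  if (nrow(pk) < 2) {
    return(tibble(start_s = numeric(), end_s = numeric(), period_s = numeric()))
  }
  tibble(start_s = head(pk$t, -1), end_s = tail(pk$t, -1),
         period_s = diff(pk$t))
}

# interior extrema with quadratic (3-point parabola) refinement
interp_extrema <- function(time, z, which = c("max", "min")) {
  which <- match.arg(which)
  s <- if (which == "max") z else -z
  n <- length(s)
  i <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  if (!length(i)) return(tibble(t = numeric(), value = numeric()))
  t0 <- time[i]
  dt1 <- time[i] - time[i - 1L]
  dt2 <- time[i + 1L] - time[i]
  y0 <- s[i - 1L]; y1 <- s[i]; y2 <- s[i + 1L]
  # parabola through three (possibly unevenly spaced) points
  denom <- dt1 * dt2 * (dt1 + dt2)
  a <- (dt1 * (y2 - y1) - dt2 * (y1 - y0)) / denom
  b <- (dt1^2 * (y2 - y1) + dt2^2 * (y1 - y0)) / denom
  shift <- ifelse(abs(a) > 1e-300, -b / (2 * a), 0)
  shift <- pmax(pmin(shift, dt2), -dt1)
  val <- y1 + b * shift + a * shift^2
  sgn <- if (which == "max") 1 else -1
  tibble(t = t0 + shift, value = sgn * val)
}

#' Kinematic flight metrics from marker trajectories
#'
#' Measures every kinematic quantity the pipeline reports: span (maximum
#' tip-to-tip distance), plunge amplitude h_a (half the interpolated tip-z
#' peak-to-peak, averaged over wings and flaps), flap frequency f (reciprocal
#' mean peak-to-peak period), stroke-plane angle (least-squares line through
#' the body-relative wingtip path in the x-z plane, per cycle), mean forward
#' speed U_inf (mean body-marker speed), maximum projected planform area S,
#' and the derived numbers c_m = S/b, A_R = b^2/S, Q = M g/S,
#' Re = rho U_inf c_m / mu, St = 2 f h_a / U_inf, and reduced frequency
#' k = pi f c_m / U_inf.
#'
#' @param traj Marker-trajectory tibble spanning at least one flap cycle.
#' @param params A [flight_params()] object supplying air properties, mass
#'   and gravity. `U_inf` and `c_m` in `params` are *not* used; they are
#'   measured from the data.
#' @param mesh Optional [build_control_mesh()] result (built internally when
#'   `NULL`) used for the planform-area series.
#' @return An object of class `flight_metrics`; see [tidy.flight_metrics()].
#' @export
kinematic_metrics <- function(traj, params = flight_params(), mesh = NULL) {
  traj <- traj[traj$valid, , drop = FALSE]
  if (is.null(mesh)) mesh <- build_control_mesh(traj)

  ref <- traj[traj$frame == mesh$ref_frame, , drop = FALSE]
  tip_of <- function(side) {
    cand <- ref[startsWith(ref$region, side), , drop = FALSE]
    if (!nrow(cand)) return(NA_integer_)
    cand$marker_id[which.max(abs(cand$y_m))]
  }
  tips <- c(right = tip_of("right"), left = tip_of("left"))
  tips <- tips[!is.na(tips)]
  fw_assert(length(tips) >= 1, "no wing markers found to act as wingtips")

  body_ids <- unique(traj$marker_id[traj$region %in% c("body", "tail")])
  body <- traj |>
    dplyr::filter(if (length(body_ids)) .data$marker_id %in% body_ids else TRUE) |>
    dplyr::group_by(.data$frame, .data$time_s) |>
    dplyr::summarise(x = mean(.data$x_m), y = mean(.data$y_m),
                     z = mean(.data$z_m), .groups = "drop") |>
    dplyr::arrange(.data$time_s)
  dtm <- diff(body$time_s)
  speed <- row_norms(cbind(diff(body$x), diff(body$y), diff(body$z))) / dtm
  u_inf <- mean(speed)

  per_wing <- lapply(names(tips), function(w) {
    tp <- traj[traj$marker_id == tips[[w]], , drop = FALSE]
    tp <- tp[order(tp$time_s), ]
    cyc <- segment_cycles(tp$time_s, tp$z_m)
    if (nrow(cyc) == 0) return(NULL)
    maxima <- interp_extrema(tp$time_s, tp$z_m, "max")
    minima <- interp_extrema(tp$time_s, tp$z_m, "min")
    h <- vapply(seq_len(nrow(cyc)), function(i) {
      zmax <- mean(maxima$value[maxima$t >= cyc$start_s[i] - 1e-9 &
                                  maxima$t <= cyc$end_s[i] + 1e-9])
      zmin <- min(minima$value[minima$t > cyc$start_s[i] &
                                 minima$t < cyc$end_s[i]])
      (zmax - zmin) / 2
    }, numeric(1))
    # body-relative tip path per cycle -> stroke-plane angle
    bx <- approx(body$time_s, body$x, xout = tp$time_s, rule = 2)$y
    bz <- approx(body$time_s, body$z, xout = tp$time_s, rule = 2)$y
    ang <- vapply(seq_len(nrow(cyc)), function(i) {
      inc <- tp$time_s >= cyc$start_s[i] & tp$time_s <= cyc$end_s[i]
      xr <- tp$x_m[inc] - bx[inc]
      zr <- tp$z_m[inc] - bz[inc]
      v <- svd(cbind(xr - mean(xr), zr - mean(zr)))$v[, 1]
      atan2(abs(v[2]), abs(v[1])) * 180 / pi
    }, numeric(1))
    list(period = cyc$period_s, h_a = h, angle = ang)
  })
  per_wing <- per_wing[!vapply(per_wing, is.null, TRUE)]
  fw_assert(length(per_wing) > 0,
            "fewer than 2 tip-z maxima: cycle metrics unavailable")

  period <- mean(unlist(lapply(per_wing, `[[`, "period")))
  h_a <- mean(unlist(lapply(per_wing, `[[`, "h_a")))
  stroke_angle <- mean(unlist(lapply(per_wing, `[[`, "angle")))
  f <- 1 / period

  # span: max tip-to-tip distance over frames (needs both wings)
  span <- if (length(tips) == 2) {
    tr <- traj[traj$marker_id == tips[["right"]], c("frame", "x_m", "y_m", "z_m")]
    tl <- traj[traj$marker_id == tips[["left"]], c("frame", "x_m", "y_m", "z_m")]
    m <- dplyr::inner_join(tr, tl, by = "frame", suffix = c("_r", "_l"))
    max(row_norms(cbind(m$x_m_r - m$x_m_l, m$y_m_r - m$y_m_l,
                        m$z_m_r - m$z_m_l)))
  } else NA_real_

  area_series <- planform_area_series(traj, mesh)
  S <- max(area_series$area_m2)

  c_m <- S / span
  res <- list(
    span_m = span, plunge_amplitude_m = h_a, flap_frequency_hz = f,
    period_s = period, stroke_plane_angle_deg = stroke_angle,
    U_inf_m_s = u_inf, planform_area_max_m2 = S, mean_chord_m = c_m,
    aspect_ratio = span^2 / S, wing_loading_N_m2 = params$M * params$g / S,
    reynolds = params$rho * u_inf * c_m / params$mu,
    strouhal = 2 * f * h_a / u_inf,
    reduced_frequency = pi * f * c_m / u_inf,
    n_cycles = sum(vapply(per_wing, function(w) length(w$period), 1L)) /
      length(per_wing),
    area_series = area_series)
  structure(res, class = "flight_metrics")
}

#' Planform-area time series from a control mesh
#'
#' Projected area (`sum(area * |n_z|)`) of the control mesh evaluated at the
#' marker positions of every frame, total and by region.
#'
#' @param traj Marker-trajectory tibble.
#' @param mesh A [build_control_mesh()] result.
#' @return Tibble `frame`, `time_s`, `region`, `area_m2` (with `region =
#'   "total"` rows included).
#' @export
planform_area_series <- function(traj, mesh = NULL) {
  if (is.null(mesh)) mesh <- build_control_mesh(traj)
  frames <- sort(unique(traj$frame))
  rows <- purrr::map(frames, function(fr) {
    sub <- traj[traj$frame == fr, , drop = FALSE]
    pos <- matrix(NA_real_, length(mesh$control_ids), 3)
    m <- match(mesh$control_ids, sub$marker_id)
    pos[, 1] <- sub$x_m[m]; pos[, 2] <- sub$y_m[m]; pos[, 3] <- sub$z_m[m]
    ok <- stats::complete.cases(pos) & sub$valid[m]
    use <- rowSums(matrix(!ok[mesh$tri], ncol = 3)) == 0
    a <- pos[mesh$tri[use, 1], , drop = FALSE]
    b <- pos[mesh$tri[use, 2], , drop = FALSE]
    cc <- pos[mesh$tri[use, 3], , drop = FALSE]
    cr <- cross3(b - a, cc - a)
    proj <- abs(cr[, 3]) / 2
    reg <- mesh$tri_region[use]
    t_s <- sub$time_s[1]
    dplyr::bind_rows(
      tibble(frame = fr, time_s = t_s, region = "total", area_m2 = sum(proj)),
      tibble(frame = fr, time_s = t_s, region = reg, area_m2 = proj) |>
        dplyr::group_by(.data$frame, .data$time_s, .data$region) |>
        dplyr::summarise(area_m2 = sum(.data$area_m2), .groups = "drop"))
  })
  dplyr::bind_rows(rows)
}

#' Strouhal number
#'
#' `St = 2 f h_a / U_inf`: the ratio of stroke speed scale to flight speed.
#'
#' @param f Flap frequency (Hz).
#' @param h_a Plunge amplitude (m).
#' @param U_inf Flight speed (m/s).
#' @return Dimensionless Strouhal number.
#' @export
strouhal_number <- function(f, h_a, U_inf) 2 * f * h_a / U_inf

#' Chord Reynolds number
#'
#' `Re = rho U_inf c_m / mu`.
#'
#' @param params A [flight_params()] object.
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(params) {
  params$rho * params$U_inf * params$c_m / params$mu
}

#' @export
print.flight_metrics <- function(x, ...) {
  cat("<flight_metrics>\n")
  cat(sprintf("  span %.3f m, h_a %.4f m, f %.3f Hz (period %.1f ms)\n",
              x$span_m, x$plunge_amplitude_m, x$flap_frequency_hz,
              1000 * x$period_s))
  cat(sprintf("  stroke plane %.1f deg, U_inf %.3f m/s, S_max %.4f m^2\n",
              x$stroke_plane_angle_deg, x$U_inf_m_s, x$planform_area_max_m2))
  cat(sprintf("  c_m %.4f m, A_R %.2f, Q %.2f N/m^2, Re %.0f, St %.3f, k %.3f\n",
              x$mean_chord_m, x$aspect_ratio, x$wing_loading_N_m2,
              x$reynolds, x$strouhal, x$reduced_frequency))
  invisible(x)
}

#' Tidy a flight-metrics object
#'
#' @param x A `flight_metrics` object.
#' @param ... Unused.
#' @return A two-column tibble `metric`, `value`.
#' @exportS3Method generics::tidy
tidy.flight_metrics <- function(x, ...) {
  keep <- setdiff(names(x), "area_series")
  tibble(metric = keep, value = unlist(x[keep], use.names = FALSE))
}

#' One-row summary of a flight-metrics object
#'
#' @param x A `flight_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble of the headline dimensionless numbers.
#' @exportS3Method generics::glance
glance.flight_metrics <- function(x, ...) {
  tibble(strouhal = x$strouhal, reynolds = x$reynolds,
         aspect_ratio = x$aspect_ratio,
         reduced_frequency = x$reduced_frequency,
         flap_frequency_hz = x$flap_frequency_hz,
         plunge_amplitude_m = x$plunge_amplitude_m)
}
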