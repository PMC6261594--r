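#' Integrate aerodynamic force over the thin surface
#'
#' `F = sum over elements and sides of (tau - p n_side) A`, with the side
#' normal outward from each face of the thin surface. The net force is the
#' vector sum of the per-side contributions.
#'
#' @param loads A [surface_loads()] tibble (both sides of every element).
#' @return A list with `force` (length-3, N), `by_region` (tibble of
#'   per-region force components) and `time` (s).
#' @export
integrate_forces <- function(loads) {
  sides <- loads |>
    dplyr::count(.data$element) |>
    dplyr::filter(.data$n < 2)
  fw_assert(nrow(sides) == 0, "element %s is missing one side of load data",
            paste(head(sides$element, 3), collapse = ", "))
  fx <- (loads$tau_x - loads$p_Pa * loads$n_x) * loads$area_m2
  fy <- (loads$tau_y - loads$p_Pa * loads$n_y) * loads$area_m2
  fz <- (loads$tau_z - loads$p_Pa * loads$n_z) * loads$area_m2
  by_region <- tibble(region = loads$region, Fx_N = fx, Fy_N = fy, Fz_N = fz) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum), .groups = "drop")
  list(force = c(Fx_N = sum(fx), Fy_N = sum(fy), Fz_N = sum(fz)),
       by_region = by_region, time = attr(loads, "time"))
}

#' Lift coefficient
#'
#' `C_L = F_z / (0.5 rho U_inf^2 S)` with S the maximum observed planform
#' area over the flap cycle. Vectorized over `F_z`.
#'
#' @param F_z Vertical aerodynamic force (N), scalar or vector.
#' @param params A [flight_params()] (supplies rho and U_inf).
#' @param S_max Maximum planform area (m^2); defaults to `params$S_ref`.
#' @return Dimensionless lift coefficient(s).
#' @export
lift_coefficient <- function(F_z, params = flight_params(),
                             S_max = params$S_ref) {
  fw_assert(S_max > 0, "S_max must be positive")
  F_z / (0.5 * params$rho * params$U_inf^2 * S_max)
}

#' Aerodynamic power exerted by the wing on the fluid
#'
#' `P = sum over elements and sides of (p n_side - tau) . v_wing A`: the rate
#' of work done by the moving surface against the fluid loads. For a rigid
#' surface translating at velocity v this equals `-(F . v)` with F from
#' [integrate_forces()], exactly.
#'
#' @param loads A [surface_loads()] tibble.
#' @param surface Optional `immersed_surface`; when supplied its time stamp
#'   must match the loads'.
#' @return Power (W).
#' @export
aerodynamic_power <- function(loads, surface = NULL) {
  if (!is.null(surface)) {
    fw_assert(isTRUE(all.equal(attr(loads, "time"), surface$time)),
              "loads (t = %.5g) and surface (t = %.5g) are at different times",
              attr(loads, "time"), surface$time)
  }
  sum(((loads$p_Pa * loads$n_x - loads$tau_x) * loads$vel_x +
         (loads$p_Pa * loads$n_y - loads$tau_y) * loads$vel_y +
         (loads$p_Pa * loads$n_z - loads$tau_z) * loads$vel_z) *
        loads$area_m2)
}

#' Estimate the flap period of a force/power series by autocorrelation
#'
#' Used to segment a series that carries no wingtip position. The
#' autocorrelation of the (linearly detrended) power column is searched for
#' a local maximum near the supplied nominal period, refined by quadratic
#' interpolation.
#'
#' @param series Force/power tibble (`time_s`, ..., `P_W`).
#' @param nominal_period_s Seed period (s), e.g. 0.138.
#' @param column Column used for the autocorrelation (default `P_W`).
#' @return Estimated period (s).
#' @export
estimate_flap_period <- function(series, nominal_period_s, column = "P_W") {
  x <- series[[column]]
  t <- series$time_s
  dt <- median(diff(t))
  x <- x - mean(x)
  n <- length(x)
  lag_max <- min(n - 2, round(1.5 * nominal_period_s / dt))
  ac <- vapply(seq_len(lag_max), function(l) {
    sum(x[1:(n - l)] * x[(l + 1):n]) / (n - l)
  }, numeric(1))
  lo <- max(2, floor(0.6 * nominal_period_s / dt))
  hi <- min(lag_max - 1, ceiling(1.4 * nominal_period_s / dt))
  fw_assert(hi > lo, "series too short to estimate a period near %.3g s",
            nominal_period_s)
  win <- lo:hi
  pk <- win[which.max(ac[win])]
  # quadratic refinement
  y0 <- ac[pk - 1]; y1 <- ac[pk]; y2 <- ac[pk + 1]
  denom <- y0 - 2 * y1 + y2
  shift <- if (abs(denom) > 1e-300) 0.5 * (y0 - y2) / denom else 0
  (pk + shift) * dt
}

#' Construct cycle intervals from a period
#'
#' @param series Force/power tibble.
#' @param period_s Flap period (s).
#' @param t0 Start of the first cycle (defaults to the series start).
#' @return Cycle tibble (`start_s`, `end_s`, `period_s`) for every complete
#'   cycle inside the series.
#' @export
cycles_from_period <- function(series, period_s, t0 = min(series$time_s)) {
  t_end <- max(series$time_s)
  n <- floor((t_end - t0) / period_s + 1e-9)
  fw_assert(n >= 1, "series does not span one full period")
  starts <- t0 + period_s * (seq_len(n) - 1)
  tibble(start_s = starts, end_s = starts + period_s,
         period_s = period_s)
}

#' Cycle-averaged force and power statistics
#'
#' Time-weighted (trapezoidal) means of every force/power column over each
#' complete cycle and over the union of complete cycles.
#'
#' @param series Force/power tibble (`time_s`, `Fx_N`, `Fy_N`, `Fz_N`,
#'   `P_W`, ...).
#' @param cycles Cycle intervals, from [segment_cycles()] (on tip-z) or
#'   [cycles_from_period()].
#' @return An object of class `cycle_stats`; see [tidy.cycle_stats()].
#' @export
cycle_average <- function(series, cycles) {
  fw_assert(nrow(cycles) >= 1, "empty cycle list")
  cols <- setdiff(names(series), "time_s")
  trap_mean <- function(a, b) {
    tt <- series$time_s
    inside <- tt > a & tt < b
    ts <- c(a, tt[inside], b)
    vals <- vapply(cols, function(cn) {
      y <- c(approx(tt, series[[cn]], a, rule = 2)$y,
             series[[cn]][inside],
             approx(tt, series[[cn]], b, rule = 2)$y)
      sum(diff(ts) * (head(y, -1) + tail(y, -1)) / 2) / (b - a)
    }, numeric(1))
    setNames(vals, cols)
  }
  per <- purrr::map(seq_len(nrow(cycles)), function(i) {
    v <- trap_mean(cycles$start_s[i], cycles$end_s[i])
    dplyr::bind_cols(tibble(cycle = i, start_s = cycles$start_s[i],
                            end_s = cycles$end_s[i]), as_tibble(as.list(v)))
  }) |> dplyr::bind_rows()
  dur <- per$end_s - per$start_s
  overall <- as_tibble(as.list(vapply(cols, function(cn)
    sum(per[[cn]] * dur) / sum(dur), numeric(1))))
  structure(list(per_cycle = per, overall = overall, cycles = cycles),
            class = "cycle_stats")
}

#' @export
print.cycle_stats <- function(x, ...) {
  cat(sprintf("<cycle_stats> %d cycles\n", nrow(x$per_cycle)))
  print(x$per_cycle)
  cat("overall (duration-weighted):\n")
  print(x$overall)
  invisible(x)
}

#' Tidy cycle statistics
#'
#' @param x A `cycle_stats` object.
#' @param ... Unused.
#' @return Long tibble: `cycle` (`"overall"` for the union), `column`,
#'   `mean`.
#' @exportS3Method generics::tidy
tidy.cycle_stats <- function(x, ...) {
  per <- tidyr::pivot_longer(x$per_cycle,
                             -c("cycle", "start_s", "end_s"),
                             names_to = "column", values_to = "mean") |>
    dplyr::mutate(cycle = as.character(.data$cycle)) |>
    dplyr::select("cycle", "column", "mean")
  ov <- tidyr::pivot_longer(x$overall, dplyr::everything(),
                            names_to = "column", values_to = "mean") |>
    dplyr::mutate(cycle = "overall") |>
    dplyr::select("cycle", "column", "mean")
  dplyr::bind_rows(per, ov)
}

#' One-row summary of cycle statistics
#'
#' @param x A `cycle_stats` object.
#' @param ... Unused.
#' @return One-row tibble of the overall means plus the cycle count.
#' @exportS3Method generics::glance
glance.cycle_stats <- function(x, ...) {
  dplyr::bind_cols(tibble(n_cycles = nrow(x$per_cycle)), x$overall)
}
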