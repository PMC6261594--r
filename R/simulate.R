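#' Run an immersed-boundary flow simulation
#'
#' Advances the solver over `n_steps`, moving the immersed surface each step
#' (static surface, or time-dependent via spline kinematics with the frame
#' velocity subtracted), sampling surface loads into a force/power series,
#' and optionally writing VTK snapshots. Passing the returned `state` back in
#' continues the run bit-identically (checkpoint/restart).
#'
#' @param grid A [build_grid()] result.
#' @param cfg A [solver_config()]; `cfg$dt` fixed here for the whole run (from
#'   [stable_dt()] when `NULL`).
#' @param n_steps Number of time steps.
#' @param surface Either `NULL`, a static `immersed_surface`, or a function
#'   `function(t, dt) -> immersed_surface` (see [evaluate_surface()]).
#' @param state Optional [flow_state()] to continue from (restart); defaults
#'   to a uniform free-stream state from the `xlo` boundary velocity.
#' @param loads_every Sample forces/power every this many steps (0 = never).
#' @param snapshot_every Write a VTK snapshot every this many steps (0 =
#'   never).
#' @param snapshot_dir Directory for snapshots.
#' @param probe_factor Load-sampling offset (grid spacings).
#' @param quiet Suppress per-step residual logging.
#' @return A list of class `simulation_result`: final `state`, `series`
#'   (force/power tibble with columns `time_s`, `Fx_N`, `Fy_N`, `Fz_N`,
#'   `P_W`), `snapshots` (paths), `dt`.
#' @export
run_simulation <- function(grid, cfg, n_steps, surface = NULL, state = NULL,
                           loads_every = 1, snapshot_every = 0,
                           snapshot_dir = NULL, probe_factor = 1.8,
                           quiet = TRUE) {
  if (is.null(state)) {
    u0 <- if (!is.null(cfg$bc$xlo) && cfg$bc$xlo$type == "dirichlet")
      cfg$bc$xlo$u else c(0, 0, 0)
    state <- flow_state(grid, u0)
  }
  static_surface <- inherits(surface, "immersed_surface")
  surface_fn <- if (is.function(surface)) surface else NULL

  if (is.null(cfg$dt)) cfg$dt <- stable_dt(state, grid, cfg)
  dt <- cfg$dt

  ib_static <- if (static_surface) build_ib_map(grid, surface, cfg) else NULL

  rows <- list()
  snaps <- character(0)
  for (s in seq_len(n_steps)) {
    t_new <- state$time + dt
    surf <- if (static_surface) surface
    else if (!is.null(surface_fn)) surface_fn(t_new, dt)
    else NULL
    ib <- if (static_surface) ib_static
    else if (!is.null(surf)) build_ib_map(grid, surf, cfg)
    else NULL
    state <- step_flow(state, grid, cfg, ib = ib)
    if (!quiet) {
      message(sprintf("step %d t=%.5g max|div|=%.3g", state$step, state$time,
                      state$max_div))
    }
    if (!is.null(surf) && loads_every > 0 && s %% loads_every == 0) {
      loads <- surface_loads(state, grid, surf, cfg,
                             probe_factor = probe_factor)
      fr <- integrate_forces(loads)
      rows[[length(rows) + 1L]] <- tibble(
        time_s = state$time, Fx_N = fr$force[["Fx_N"]],
        Fy_N = fr$force[["Fy_N"]], Fz_N = fr$force[["Fz_N"]],
        P_W = aerodynamic_power(loads))
    }
    if (snapshot_every > 0 && s %% snapshot_every == 0 &&
        !is.null(snapshot_dir)) {
      snaps <- c(snaps, write_vtk_rectilinear(
        state, grid, file.path(snapshot_dir,
                               sprintf("flow_%06d.vtk", state$step))))
    }
  }
  series <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(time_s = numeric(), Fx_N = numeric(), Fy_N = numeric(),
           Fz_N = numeric(), P_W = numeric())
  structure(list(state = state, series = series, snapshots = snaps, dt = dt),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d steps to t = %.5g s (dt = %.3g s)\n",
              x$state$step, x$state$time, x$dt))
  if (nrow(x$series)) {
    cat(sprintf("  mean force (N): Fx %.4g, Fy %.4g, Fz %.4g; mean power %.4g W\n",
                mean(x$series$Fx_N), mean(x$series$Fy_N),
                mean(x$series$Fz_N), mean(x$series$P_W)))
  }
  invisible(x)
}

#' Surface provider from spline kinematics for a moving-frame simulation
#'
#' Wraps [evaluate_surface()] into the `function(t, dt)` form
#' [run_simulation()] expects, subtracting the frame velocity.
#'
#' @param splines A [spline_kinematics()] object.
#' @param fine A [refine_mesh()] result.
#' @param cfg The [solver_config()] (supplies `frame_velocity`).
#' @param t_offset Shift between simulation time and kinematic time (s):
#'   kinematics are evaluated at `t + t_offset`, letting a simulation start
#'   at t = 0 use the spline interval's interior.
#' @return A function `(t, dt) -> immersed_surface`.
#' @export
surface_provider <- function(splines, fine, cfg, t_offset = 0) {
  function(t, dt) {
    evaluate_surface(splines, fine, t + t_offset, dt_history = dt,
                     frame_velocity = cfg$frame_velocity)
  }
}
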