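#' Read and validate a pipeline configuration file
#'
#' YAML with a versioned schema. Top-level sections: `seed`, `motion`
#' (fields of [wing_motion_params()]), `camera` (`pixel_noise_sd`,
#' `occlusion_rate`), `flight` (fields of [flight_params()]), `solver`
#' (`nu`, `rho`, `cfl`, `dt`, `les`, `frame_velocity`, `U_inf`,
#' `cells_per_chord`, `domain_chords`, `refined_chords`, `growth`), `paths`
#' (`markers`, `observations`, `force_power`, `trajectory`, `out_dir`) and
#' `output` (`snapshot_every`, `loads_every`, `n_steps`). Unknown keys are
#' rejected with a message naming the key.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config` list with constructor defaults
#'   filled in.
#' @export
read_pipeline_config <- function(path) {
  fw_assert(file.exists(path), "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  schema <- list(
    version = NULL,
    seed = NULL,
    motion = names(formals(wing_motion_params)),
    camera = c("pixel_noise_sd", "occlusion_rate"),
    flight = names(formals(flight_params)),
    solver = c("nu", "rho", "cfl", "dt", "les", "frame_velocity", "U_inf",
               "cells_per_chord", "domain_chords", "refined_chords",
               "growth", "p_tol", "ib_band"),
    paths = c("markers", "observations", "force_power", "trajectory",
              "out_dir"),
    output = c("snapshot_every", "loads_every", "n_steps", "target_edge_m"))
  unknown_top <- setdiff(names(raw), names(schema))
  fw_assert(length(unknown_top) == 0, "unknown config key: %s",
            paste(unknown_top, collapse = ", "))
  for (sec in names(raw)) {
    allowed <- schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(raw[[sec]]), allowed)
    fw_assert(length(bad) == 0, "unknown config key: %s",
              paste(paste0(sec, ".", bad), collapse = ", "))
  }
  cfg <- raw
  cfg$seed <- cfg$seed %||% 1L
  mo <- cfg$motion %||% list()
  if (!is.null(cfg$seed) && is.null(mo$seed)) mo$seed <- cfg$seed
  cfg$motion <- do.call(wing_motion_params, mo)
  cfg$flight <- do.call(flight_params, cfg$flight %||% list())
  cfg$camera <- modifyList(list(pixel_noise_sd = 0.5, occlusion_rate = 0.02),
                           cfg$camera %||% list())
  cfg$solver <- modifyList(
    list(nu = cfg$flight$mu / cfg$flight$rho, rho = cfg$flight$rho,
         cfl = 0.4, dt = NULL, les = FALSE, frame_velocity = 2.5,
         U_inf = cfg$flight$U_inf, cells_per_chord = 10,
         domain_chords = c(8, 5, 5), refined_chords = c(3, 3, 3),
         growth = 1.15, p_tol = 1e-8, ib_band = 1.0),
    cfg$solver %||% list())
  cfg$output <- modifyList(list(snapshot_every = 0, loads_every = 1,
                                n_steps = 20, target_edge_m = 0.01),
                           cfg$output %||% list())
  cfg$paths <- cfg$paths %||% list()
  structure(cfg, class = "pipeline_config")
}

# grid + solver_config from the config's solver section
config_to_solver <- function(cfg) {
  sv <- cfg$solver
  cm <- cfg$flight$c_m
  h <- cm / sv$cells_per_chord
  dom <- sv$domain_chords * cm
  refined <- sv$refined_chords * cm
  grid <- build_grid(
    xlim = c(-dom[1] / 4, 3 * dom[1] / 4),
    ylim = c(-dom[2] / 2, dom[2] / 2),
    zlim = c(-dom[3] / 2, dom[3] / 2),
    refined = list(x = c(-refined[1] / 2, refined[1] / 2),
                   y = c(-refined[2] / 2, refined[2] / 2),
                   z = c(-refined[3] / 2, refined[3] / 2)),
    spacing = h, growth = sv$growth)
  # wind-tunnel view of the moving frame: free stream at the frame speed,
  # wing kinematics advanced at (U_inf - frame_velocity) ~ a perturbation
  scfg <- solver_config(nu = sv$nu, rho = sv$rho, dt = sv$dt, cfl = sv$cfl,
                        les = sv$les, frame_velocity = sv$frame_velocity,
                        bc = bc_tunnel(c(sv$frame_velocity, 0, 0)),
                        p_tol = sv$p_tol, ib_band = sv$ib_band)
  list(grid = grid, cfg = scfg)
}
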