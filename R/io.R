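#' Read and write the marker-trajectory CSV
#'
#' Canonical columns: `frame`, `time_s`, `marker_id`, `region`, `x_m`,
#' `y_m`, `z_m`, `valid`. Invalid rows keep NA coordinates. Writing then
#' reading reproduces finite values exactly (full-precision formatting).
#'
#' @param traj Marker-trajectory tibble.
#' @param path File path.
#' @return `read_marker_csv()` returns the trajectory tibble;
#'   `write_marker_csv()` returns `path` invisibly.
#' @export
write_marker_csv <- function(traj, path) {
  readr::write_csv(traj[, c("frame", "time_s", "marker_id", "region",
                            "x_m", "y_m", "z_m", "valid")], path)
  invisible(path)
}

#' @rdname write_marker_csv
#' @export
read_marker_csv <- function(path) {
  fw_assert(file.exists(path), "file not found: %s", path)
  out <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      frame = readr::col_integer(),
                      time_s = readr::col_double(),
                      marker_id = readr::col_integer(),
                      region = readr::col_character(),
                      x_m = readr::col_double(),
                      y_m = readr::col_double(),
                      z_m = readr::col_double(),
                      valid = readr::col_logical())),
    warning = function(w) fw_stop("malformed marker CSV %s: %s", path,
                                  conditionMessage(w)))
  need <- c("frame", "time_s", "marker_id", "x_m", "y_m", "z_m")
  miss <- setdiff(need, names(out))
  fw_assert(length(miss) == 0, "marker CSV is missing column(s): %s",
            paste(miss, collapse = ", "))
  if (!"valid" %in% names(out)) out$valid <- stats::complete.cases(out[, c("x_m", "y_m", "z_m")])
  if (!"region" %in% names(out)) out$region <- "unknown"
  tcheck <- out |>
    dplyr::distinct(.data$frame, .data$time_s) |>
    dplyr::arrange(.data$frame)
  fw_assert(all(diff(tcheck$time_s) > 0),
            "marker CSV times are not strictly increasing with frame")
  out$valid <- out$valid & stats::complete.cases(out[, c("x_m", "y_m", "z_m")])
  out
}

#' Read and write the 2D observation CSV
#'
#' Columns: `camera_id`, `frame`, `marker_id`, `u_px`, `v_px`.
#'
#' @param obs Observation tibble.
#' @param path File path.
#' @return The observation tibble (reader) or `path` invisibly (writer).
#' @export
write_observation_csv <- function(obs, path) {
  readr::write_csv(obs[, c("camera_id", "frame", "marker_id", "u_px", "v_px")],
                   path)
  invisible(path)
}

#' @rdname write_observation_csv
#' @export
read_observation_csv <- function(path) {
  fw_assert(file.exists(path), "file not found: %s", path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("camera_id", "frame", "marker_id", "u_px", "v_px")
  miss <- setdiff(need, names(out))
  fw_assert(length(miss) == 0, "observation CSV is missing column(s): %s",
            paste(miss, collapse = ", "))
  out
}

# header aliases accepted by the force/power reader (case-insensitive)
force_power_aliases <- list(
  time_s = c("time_s", "time", "t", "t_s", "time_sec", "time (s)"),
  Fx_N = c("fx_n", "fx", "force_x", "force_x_n", "f_x", "fx (n)"),
  Fy_N = c("fy_n", "fy", "force_y", "force_y_n", "f_y", "fy (n)"),
  Fz_N = c("fz_n", "fz", "force_z", "force_z_n", "f_z", "lift", "fz (n)"),
  P_W = c("p_w", "p", "power", "power_w", "aero_power", "p (w)"),
  tip_z_m = c("tip_z_m", "tip_z", "tipz", "wingtip_z"))

#' Read and write the canonical force/power CSV
#'
#' Canonical columns `time_s`, `Fx_N`, `Fy_N`, `Fz_N`, `P_W` (optional
#' `tip_z_m`). The reader tolerates common header aliases (e.g. `time`,
#' `Fx`, `power`) and accepts an explicit `column_map` for first contact
#' with an externally deposited file; unknown layouts error naming the
#' unmatched columns.
#'
#' @param series Force/power tibble.
#' @param path File path.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's actual headers, e.g. `c(time_s = "T", Fz_N = "Lift")`.
#' @return The canonical tibble (reader) or `path` invisibly (writer).
#' @export
write_force_power_csv <- function(series, path) {
  readr::write_csv(series, path)
  invisible(path)
}

#' @rdname write_force_power_csv
#' @export
read_force_power_csv <- function(path, column_map = NULL) {
  fw_assert(file.exists(path), "file not found: %s", path)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  out <- list()
  lower <- tolower(trimws(names(raw)))
  for (canon in names(force_power_aliases)) {
    src <- NA_character_
    if (!is.null(column_map) && canon %in% names(column_map)) {
      src <- column_map[[canon]]
      fw_assert(src %in% names(raw), "column '%s' (mapped to %s) not in %s",
                src, canon, path)
    } else {
      hit <- which(lower %in% force_power_aliases[[canon]])
      if (length(hit)) src <- names(raw)[hit[1]]
    }
    if (!is.na(src)) out[[canon]] <- as.numeric(raw[[src]])
  }
  need <- c("time_s", "Fx_N", "Fy_N", "Fz_N")
  miss <- setdiff(need, names(out))
  fw_assert(length(miss) == 0,
            "force/power CSV %s: could not identify column(s) %s (headers: %s)",
            path, paste(miss, collapse = ", "),
            paste(names(raw), collapse = ", "))
  out <- as_tibble(out)
  fw_assert(all(diff(out$time_s) > 0), "times must be strictly increasing")
  out
}

#' Read an observed trajectory CSV
#'
#' Columns `time_s`, `x_m`, `y_m`, `z_m` (optional velocities).
#'
#' @param path File path.
#' @return Trajectory tibble.
#' @export
read_trajectory_csv <- function(path) {
  fw_assert(file.exists(path), "file not found: %s", path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("time_s", "x_m", "y_m", "z_m"), names(out))
  fw_assert(length(miss) == 0, "trajectory CSV is missing column(s): %s",
            paste(miss, collapse = ", "))
  out
}

# ---- VTK / STL writers (legacy ASCII) ----

#' Write a flow state as a legacy VTK rectilinear grid
#'
#' Cell-centered velocity (interpolated), pressure and eddy viscosity as
#' point data on the cell-center lattice.
#'
#' @param state A [flow_state()].
#' @param grid The grid.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_rectilinear <- function(state, grid, path) {
  uc <- center_velocity(state, grid)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("flapwing flow snapshot t=%.9g", state$time)
  wl("ASCII")
  wl("DATASET RECTILINEAR_GRID")
  wl("DIMENSIONS %d %d %d", grid$nx, grid$ny, grid$nz)
  wl("X_COORDINATES %d double", grid$nx)
  wl(paste(format(grid$xc, digits = 17), collapse = " "))
  wl("Y_COORDINATES %d double", grid$ny)
  wl(paste(format(grid$yc, digits = 17), collapse = " "))
  wl("Z_COORDINATES %d double", grid$nz)
  wl(paste(format(grid$zc, digits = 17), collapse = " "))
  n <- grid$n_cells
  wl("POINT_DATA %d", n)
  wl("VECTORS velocity double")
  writeLines(paste(as.vector(uc$u), as.vector(uc$v), as.vector(uc$w)), con)
  wl("SCALARS pressure double 1")
  wl("LOOKUP_TABLE default")
  writeLines(format(as.vector(state$p), digits = 17), con)
  wl("SCALARS eddy_viscosity double 1")
  wl("LOOKUP_TABLE default")
  writeLines(format(as.vector(state$nu_t), digits = 17), con)
  invisible(path)
}

#' Read back a legacy VTK rectilinear grid written by this package
#'
#' Minimal reader used for round-trip checks of snapshot output.
#'
#' @param path `.vtk` file path.
#' @return List with `x`, `y`, `z` coordinate vectors and `point_data`
#'   (named list of numeric vectors/matrices).
#' @export
read_vtk_rectilinear <- function(path) {
  ln <- readLines(path)
  fw_assert(any(grepl("DATASET RECTILINEAR_GRID", ln)),
            "%s is not a rectilinear-grid VTK file", path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "",
                                         grep("^DIMENSIONS", ln, value = TRUE))),
                              "\\s+")[[1]])
  get_coords <- function(axis) {
    i <- grep(sprintf("^%s_COORDINATES", axis), ln)
    as.numeric(strsplit(trimws(ln[i + 1]), "\\s+")[[1]])
  }
  x <- get_coords("X"); y <- get_coords("Y"); z <- get_coords("Z")
  n <- prod(dims)
  pd <- list()
  iv <- grep("^VECTORS", ln)
  if (length(iv)) {
    nm <- strsplit(ln[iv], "\\s+")[[1]][2]
    vals <- do.call(rbind, lapply(ln[(iv + 1):(iv + n)], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
    pd[[nm]] <- vals
  }
  for (is_ in grep("^SCALARS", ln)) {
    nm <- strsplit(ln[is_], "\\s+")[[1]][2]
    vals <- as.numeric(ln[(is_ + 2):(is_ + 1 + n)])
    pd[[nm]] <- vals
  }
  list(x = x, y = y, z = z, dims = dims, point_data = pd)
}

#' Write an immersed surface as VTK poly-data
#'
#' Triangles with optional per-element cell data (e.g. pressure difference).
#'
#' @param surface An `immersed_surface`.
#' @param path Output `.vtk` path.
#' @param cell_data Optional named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk_surface <- function(surface, path, cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  V <- surface$vertices; Tr <- surface$tri
  wl("# vtk DataFile Version 3.0")
  wl("flapwing surface t=%.9g", surface$time)
  wl("ASCII")
  wl("DATASET POLYDATA")
  wl("POINTS %d double", nrow(V))
  writeLines(paste(V[, 1], V[, 2], V[, 3]), con)
  wl("POLYGONS %d %d", nrow(Tr), 4 * nrow(Tr))
  writeLines(paste(3, Tr[, 1] - 1L, Tr[, 2] - 1L, Tr[, 3] - 1L), con)
  if (!is.null(cell_data)) {
    wl("CELL_DATA %d", nrow(Tr))
    for (nm in names(cell_data)) {
      wl("SCALARS %s double 1", nm)
      wl("LOOKUP_TABLE default")
      writeLines(format(cell_data[[nm]], digits = 17), con)
    }
  }
  invisible(path)
}

#' Write an immersed surface as ASCII STL
#'
#' @param surface An `immersed_surface`.
#' @param path Output `.stl` path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surface, path) {
  el <- surface$elements
  V <- surface$vertices; Tr <- surface$tri
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid flapwing", con)
  for (i in seq_len(nrow(Tr))) {
    writeLines(sprintf("  facet normal %g %g %g",
                       el$normal_x[i], el$normal_y[i], el$normal_z[i]), con)
    writeLines("    outer loop", con)
    for (v in Tr[i, ]) {
      writeLines(sprintf("      vertex %g %g %g", V[v, 1], V[v, 2], V[v, 3]),
                 con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid flapwing", con)
  invisible(path)
}

#' Write a numbered VTK time series with an index file
#'
#' @param objects List of `immersed_surface` or [flow_state()] objects (all
#'   the same type).
#' @param directory Output directory (created if needed).
#' @param cadence Write every `cadence`-th object (the first object is index
#'   0 and is always eligible).
#' @param grid Required when writing flow states.
#' @param prefix File-name prefix.
#' @return Paths of the files written (the `.series` JSON index last),
#'   invisibly.
#' @export
write_vtk_series <- function(objects, directory, cadence = 1, grid = NULL,
                             prefix = "snapshot") {
  fw_assert(dir.exists(directory) || dir.create(directory, recursive = TRUE),
            "cannot create directory %s", directory)
  idx <- seq_along(objects) - 1L
  keep <- idx %% cadence == 0
  files <- character(0)
  times <- numeric(0)
  for (i in which(keep)) {
    ob <- objects[[i]]
    f <- file.path(directory, sprintf("%s_%06d.vtk", prefix, idx[i]))
    if (inherits(ob, "immersed_surface")) {
      write_vtk_surface(ob, f)
      times <- c(times, ob$time)
    } else if (inherits(ob, "flow_state")) {
      fw_assert(!is.null(grid), "grid needed to write flow states")
      write_vtk_rectilinear(ob, grid, f)
      times <- c(times, ob$time)
    } else {
      fw_stop("unsupported object of class %s", class(ob)[1])
    }
    files <- c(files, f)
  }
  index <- file.path(directory, paste0(prefix, ".vtk.series"))
  jsonlite::write_json(
    list(`file-series-version` = "1.0",
         files = purrr::map2(basename(files), times,
                             function(f, t) list(name = f, time = t))),
    index, auto_unbox = TRUE, digits = NA)
  invisible(c(files, index))
}
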