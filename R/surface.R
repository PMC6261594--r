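#' Natural cubic spline kinematics for the control points
#'
#' Fits one natural cubic spline per control point per coordinate over the
#' frame times. The splines interpolate the samples exactly at the frame
#' times and are C2 inside the record, giving a continuous description of the
#' control-point motion that the solver can evaluate at any time step.
#'
#' @param traj Marker-trajectory tibble.
#' @param mesh A [build_control_mesh()] result (defines the control-point
#'   ordering).
#' @return An object of class `spline_kinematics` with the valid time
#'   interval in `$t_range`.
#' @export
spline_kinematics <- function(traj, mesh) {
  ids <- mesh$control_ids
  sub <- traj[traj$marker_id %in% ids & traj$valid, , drop = FALSE]
  fns <- lapply(ids, function(id) {
    s <- sub[sub$marker_id == id, , drop = FALSE]
    fw_assert(nrow(s) >= 4, "control point %s has fewer than 4 valid frames",
              format(id))
    s <- s[order(s$time_s), ]
    list(x = splinefun(s$time_s, s$x_m, method = "natural"),
         y = splinefun(s$time_s, s$y_m, method = "natural"),
         z = splinefun(s$time_s, s$z_m, method = "natural"))
  })
  structure(list(fns = fns, ids = ids,
                 t_range = range(sub$time_s)),
            class = "spline_kinematics")
}

# control positions (n x 3) at time t
control_positions <- function(splines, t) {
  n <- length(splines$fns)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    f <- splines$fns[[i]]
    out[i, ] <- c(f$x(t), f$y(t), f$z(t))
  }
  out
}

#' Evaluate the moving immersed surface at a time instant
#'
#' Places every fine vertex by barycentric interpolation of the spline-
#' evaluated control points, then computes per-element centroid, unit normal,
#' area, velocity and acceleration. Velocity uses the second-order backward
#' difference over `{t, t - dt, t - 2 dt}`
#' (`(3 x_t - 4 x_{t-dt} + x_{t-2dt}) / (2 dt)`), acceleration the
#' second difference over the same stencil, matching how a flow solver sees
#' the surface move between its own time steps.
#'
#' @param splines A [spline_kinematics()] object.
#' @param fine A [refine_mesh()] result.
#' @param t Evaluation time (s).
#' @param dt_history Backward-difference step (s); normally the solver time
#'   step. `t - 2 * dt_history` must lie inside the spline interval.
#' @param frame_velocity Streamwise speed (m/s) subtracted from the surface
#'   motion and position when simulating in a moving reference frame.
#' @return An object of class `immersed_surface`: element tibble
#'   (`centroid_*`, `normal_*`, `area_m2`, `vel_*`, `acc_*`, `region`) plus
#'   vertex positions and connectivity for mesh output.
#' @export
evaluate_surface <- function(splines, fine, t, dt_history,
                             frame_velocity = 0) {
  lo <- splines$t_range[1] - 1e-9
  hi <- splines$t_range[2] + 1e-9
  fw_assert(t - 2 * dt_history >= lo && t <= hi,
            "time %.4g s (with history %.4g s) outside the spline interval [%.4g, %.4g]",
            t, dt_history, splines$t_range[1], splines$t_range[2])

  pos_at <- function(tt) {
    p <- control_positions(splines, tt)
    p[, 1] <- p[, 1] - frame_velocity * tt
    fine_vertex_positions(fine, p)
  }
  v0 <- pos_at(t)
  v1 <- pos_at(t - dt_history)
  v2 <- pos_at(t - 2 * dt_history)
  vel_v <- (3 * v0 - 4 * v1 + v2) / (2 * dt_history)
  acc_v <- (v0 - 2 * v1 + v2) / dt_history^2

  tri <- fine$tri
  a <- v0[tri[, 1], , drop = FALSE]
  b <- v0[tri[, 2], , drop = FALSE]
  cc <- v0[tri[, 3], , drop = FALSE]
  cr <- cross3(b - a, cc - a)
  area2 <- row_norms(cr)
  nrm <- cr / pmax(area2, 1e-300)
  centroid <- (a + b + cc) / 3
  velem <- (vel_v[tri[, 1], , drop = FALSE] + vel_v[tri[, 2], , drop = FALSE] +
              vel_v[tri[, 3], , drop = FALSE]) / 3
  aelem <- (acc_v[tri[, 1], , drop = FALSE] + acc_v[tri[, 2], , drop = FALSE] +
              acc_v[tri[, 3], , drop = FALSE]) / 3

  elements <- tibble(
    centroid_x = centroid[, 1], centroid_y = centroid[, 2],
    centroid_z = centroid[, 3],
    normal_x = nrm[, 1], normal_y = nrm[, 2], normal_z = nrm[, 3],
    area_m2 = area2 / 2,
    vel_x = velem[, 1], vel_y = velem[, 2], vel_z = velem[, 3],
    acc_x = aelem[, 1], acc_y = aelem[, 2], acc_z = aelem[, 3],
    region = fine$tri_region)

  structure(list(time = t, elements = elements, vertices = v0,
                 vertex_velocity = vel_v, tri = tri),
            class = "immersed_surface")
}

#' Build an immersed surface directly from element data
#'
#' Convenience constructor for analytic/toy surfaces (plates, spheres) used
#' by the solver and in tests, bypassing the marker pipeline.
#'
#' @param vertices n x 3 vertex matrix (m).
#' @param tri m x 3 connectivity.
#' @param velocity Either a single length-3 vector applied to all vertices or
#'   an n x 3 matrix (m/s).
#' @param acceleration As `velocity` (m/s^2).
#' @param region Element region tag(s).
#' @param time Surface time stamp (s).
#' @return An `immersed_surface` object.
#' @export
immersed_surface <- function(vertices, tri, velocity = c(0, 0, 0),
                             acceleration = c(0, 0, 0), region = "surface",
                             time = 0) {
  vertices <- as.matrix(vertices)
  tri <- matrix(as.integer(tri), ncol = 3)
  n <- nrow(vertices)
  if (is.null(dim(velocity))) velocity <- matrix(velocity, n, 3, byrow = TRUE)
  if (is.null(dim(acceleration)))
    acceleration <- matrix(acceleration, n, 3, byrow = TRUE)
  a <- vertices[tri[, 1], , drop = FALSE]
  b <- vertices[tri[, 2], , drop = FALSE]
  cc <- vertices[tri[, 3], , drop = FALSE]
  cr <- cross3(b - a, cc - a)
  area2 <- row_norms(cr)
  fw_assert(sum(area2) > 0, "surface has zero total area")
  nrm <- cr / pmax(area2, 1e-300)
  velem <- (velocity[tri[, 1], , drop = FALSE] + velocity[tri[, 2], , drop = FALSE] +
              velocity[tri[, 3], , drop = FALSE]) / 3
  aelem <- (acceleration[tri[, 1], , drop = FALSE] +
              acceleration[tri[, 2], , drop = FALSE] +
              acceleration[tri[, 3], , drop = FALSE]) / 3
  centroid <- (a + b + cc) / 3
  elements <- tibble(
    centroid_x = centroid[, 1], centroid_y = centroid[, 2],
    centroid_z = centroid[, 3],
    normal_x = nrm[, 1], normal_y = nrm[, 2], normal_z = nrm[, 3],
    area_m2 = area2 / 2,
    vel_x = velem[, 1], vel_y = velem[, 2], vel_z = velem[, 3],
    acc_x = aelem[, 1], acc_y = aelem[, 2], acc_z = aelem[, 3],
    region = rep_len(region, nrow(tri)))
  structure(list(time = time, elements = elements, vertices = vertices,
                 vertex_velocity = velocity, tri = tri),
            class = "immersed_surface")
}

#' @export
print.immersed_surface <- function(x, ...) {
  cat(sprintf("<immersed_surface> t = %.5g s, %d elements, total area %.4g m^2\n",
              x$time, nrow(x$elements), sum(x$elements$area_m2)))
  invisible(x)
}

#' Projected (planform) area of an immersed surface
#'
#' Area of the surface projected onto the horizontal x-y plane:
#' `sum(area * |normal_z|)` over the selected elements.
#'
#' @param surface An `immersed_surface`.
#' @param regions Optional character vector of region tags to include (all
#'   elements by default). Prefix matching is used so `"right"` selects
#'   `right_inner` and `right_outer`.
#' @return Projected area (m^2).
#' @export
planform_area <- function(surface, regions = NULL) {
  el <- surface$elements
  if (!is.null(regions)) {
    keep <- Reduce(`|`, lapply(regions, function(r) startsWith(el$region, r)))
    el <- el[keep, , drop = FALSE]
  }
  sum(el$area_m2 * abs(el$normal_z))
}
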