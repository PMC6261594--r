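#' Build the Delaunay control mesh from marker trajectories
#'
#' For each body region group (left wing, right wing, body/tail), projects the
#' markers onto the group's least-squares plane at the reference frame (the
#' most-outstretched instant by default), computes the 2D Delaunay
#' triangulation there, and lifts the connectivity back to 3D. The
#' connectivity is held fixed for all frames; only vertex positions move.
#'
#' @param traj Marker-trajectory tibble (see [generate_wing_motion()]).
#' @param reference_frame Frame index used for triangulation; defaults to the
#'   frame with the largest lateral marker extent (most outstretched wings).
#' @return An object of class `control_mesh`: `control_ids` (marker ids in
#'   vertex order), `tri` (m x 3 vertex-index matrix), `tri_region`,
#'   `ref_frame`, `ref_positions` (n x 3 at the reference frame).
#' @export
build_control_mesh <- function(traj, reference_frame = NULL) {
  if (is.null(reference_frame)) reference_frame <- most_outstretched_frame(traj)
  ref <- traj[traj$frame == reference_frame & traj$valid, , drop = FALSE]
  fw_assert(nrow(ref) > 0, "reference frame %s has no valid markers",
            format(reference_frame))
  ref <- ref[order(ref$marker_id), , drop = FALSE]
  grp <- mesh_group(ref$region)

  tri_all <- list()
  reg_all <- character()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    fw_assert(length(idx) >= 3, "region group '%s' has fewer than 3 markers", g)
    P <- cbind(ref$x_m[idx], ref$y_m[idx], ref$z_m[idx])
    Pc <- sweep(P, 2, colMeans(P))
    sv <- svd(Pc)
    fw_assert(sv$d[2] > 1e-9 * max(sv$d[1], 1e-300),
              "markers of group '%s' are collinear: no valid triangulation", g)
    uv <- Pc %*% sv$v[, 1:2]
    tri2 <- delaunay_triangles(uv[, 1], uv[, 2])
    tri_all[[g]] <- matrix(idx[tri2], ncol = 3)
    # triangle region = most common vertex region
    reg_all <- c(reg_all, apply(tri_all[[g]], 1, function(v) {
      r <- ref$region[v]
      names(sort(table(r), decreasing = TRUE))[1]
    }))
  }
  tri <- do.call(rbind, tri_all)

  # orient wing/body triangle normals consistently +z at the reference frame
  P <- cbind(ref$x_m, ref$y_m, ref$z_m)
  nz <- cross3(P[tri[, 2], , drop = FALSE] - P[tri[, 1], , drop = FALSE],
               P[tri[, 3], , drop = FALSE] - P[tri[, 1], , drop = FALSE])[, 3]
  flip <- nz < 0
  tri[flip, 2:3] <- tri[flip, 3:2]

  structure(list(control_ids = ref$marker_id, tri = tri, tri_region = reg_all,
                 ref_frame = reference_frame, ref_positions = P),
            class = "control_mesh")
}

mesh_group <- function(region) {
  dplyr::case_when(grepl("^left", region) ~ "left_wing",
                   grepl("^right", region) ~ "right_wing",
                   region %in% c("body", "tail") ~ "body",
                   TRUE ~ "all")
}

#' Frame with the most outstretched wings
#'
#' @param traj Marker-trajectory tibble.
#' @return The frame index maximizing the lateral (y) marker extent.
#' @export
most_outstretched_frame <- function(traj) {
  ext <- traj |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(ext = max(.data$y_m) - min(.data$y_m), .groups = "drop")
  ext$frame[which.max(ext$ext)]
}

# 2D Delaunay triangulation (counter-clockwise triangles) via deldir
delaunay_triangles <- function(x, y) {
  dd <- deldir::deldir(x, y, suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  fw_assert(length(tl) > 0, "Delaunay triangulation produced no triangles")
  t(vapply(tl, function(df) as.integer(df$ptNum), integer(3)))
}

#' @export
print.control_mesh <- function(x, ...) {
  cat(sprintf("<control_mesh> %d control points, %d triangles (reference frame %s)\n",
              length(x$control_ids), nrow(x$tri), format(x$ref_frame)))
  invisible(x)
}

#' Refine a control mesh into a barycentric fine mesh
#'
#' Subdivides every control triangle into `k^2` congruent sub-triangles with a
#' single global `k = max(1, ceiling(median_edge / target_edge))`, so shared
#' control edges are split identically and the fine surface stays watertight.
#' Each fine vertex stores its barycentric coordinates (alpha toward the
#' second corner, beta toward the third) within its owning control triangle;
#' these are computed once here and reused unchanged as the wing moves, so
#' interior points keep their relative positions throughout the flap cycles.
#'
#' @param mesh A [build_control_mesh()] result.
#' @param target_edge Target fine-element edge length (m); must be positive
#'   and no larger than the median control edge.
#' @param k Optionally force the subdivision level directly (overrides
#'   `target_edge`).
#' @return An object of class `fine_mesh`: `owner` (control-triangle id per
#'   fine vertex), `alpha`, `beta`, `tri` (fine connectivity), `tri_region`,
#'   `k`, and the originating `control` mesh.
#' @export
refine_mesh <- function(mesh, target_edge = NULL, k = NULL) {
  if (is.null(k)) {
    fw_assert(!is.null(target_edge) && target_edge > 0,
              "target_edge must be positive")
    med <- median_control_edge(mesh)
    fw_assert(target_edge <= med,
              "target_edge (%.4g m) must not exceed the median control edge (%.4g m)",
              target_edge, med)
    k <- max(1L, as.integer(ceiling(med / target_edge)))
  }
  k <- as.integer(k)
  fw_assert(k >= 1, "k must be >= 1")

  key_env <- new.env(hash = TRUE, parent = emptyenv())
  owner <- integer(0); alpha <- numeric(0); beta <- numeric(0)
  nvert <- 0L

  vertex_id <- function(key, tri_id, a, b) {
    id <- key_env[[key]]
    if (is.null(id)) {
      nvert <<- nvert + 1L
      id <- nvert
      key_env[[key]] <- id
      owner[id] <<- tri_id; alpha[id] <<- a; beta[id] <<- b
    }
    id
  }

  edge_key <- function(va, vb, i, k) {
    if (va < vb) sprintf("e%d_%d_%d", va, vb, i) else
      sprintf("e%d_%d_%d", vb, va, k - i)
  }

  ntri <- nrow(mesh$tri)
  fine_tri <- vector("list", ntri)
  for (tt in seq_len(ntri)) {
    v <- mesh$tri[tt, ]
    # vertex ids on the (i, j) barycentric grid, i + j <= k
    ids <- matrix(NA_integer_, k + 1, k + 1)
    for (i in 0:k) for (j in 0:(k - i)) {
      a <- i / k; b <- j / k
      key <- if (i == 0 && j == 0) sprintf("c%d", v[1])
      else if (i == k && j == 0) sprintf("c%d", v[2])
      else if (i == 0 && j == k) sprintf("c%d", v[3])
      else if (j == 0) edge_key(v[1], v[2], i, k)
      else if (i == 0) edge_key(v[1], v[3], j, k)
      else if (i + j == k) edge_key(v[2], v[3], j, k)
      else sprintf("i%d_%d_%d", tt, i, j)
      ids[i + 1, j + 1] <- vertex_id(key, tt, a, b)
    }
    tris <- vector("list", k * k)
    n <- 0L
    for (i in 0:(k - 1)) for (j in 0:(k - 1 - i)) {
      n <- n + 1L
      tris[[n]] <- c(ids[i + 1, j + 1], ids[i + 2, j + 1], ids[i + 1, j + 2])
      if (i + j <= k - 2) {
        n <- n + 1L
        tris[[n]] <- c(ids[i + 2, j + 1], ids[i + 2, j + 2], ids[i + 1, j + 2])
      }
    }
    fine_tri[[tt]] <- do.call(rbind, tris[seq_len(n)])
  }
  tri <- do.call(rbind, fine_tri)
  tri_region <- rep(mesh$tri_region, vapply(fine_tri, nrow, 1L))

  structure(list(owner = owner, alpha = alpha, beta = beta, tri = tri,
                 tri_region = tri_region, k = k, control = mesh),
            class = "fine_mesh")
}

median_control_edge <- function(mesh) {
  P <- mesh$ref_positions
  e <- rbind(mesh$tri[, c(1, 2)], mesh$tri[, c(2, 3)], mesh$tri[, c(1, 3)])
  median(row_norms(P[e[, 1], , drop = FALSE] - P[e[, 2], , drop = FALSE]))
}

#' @export
print.fine_mesh <- function(x, ...) {
  cat(sprintf("<fine_mesh> k = %d: %d vertices, %d elements from %d control triangles\n",
              x$k, length(x$owner), nrow(x$tri), nrow(x$control$tri)))
  invisible(x)
}

# fine vertex positions for given control point positions (n_ctrl x 3)
fine_vertex_positions <- function(fine, ctrl_pos) {
  t1 <- fine$control$tri[fine$owner, 1]
  t2 <- fine$control$tri[fine$owner, 2]
  t3 <- fine$control$tri[fine$owner, 3]
  r1 <- ctrl_pos[t1, , drop = FALSE]
  r1 + fine$alpha * (ctrl_pos[t2, , drop = FALSE] - r1) +
    fine$beta * (ctrl_pos[t3, , drop = FALSE] - r1)
}
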