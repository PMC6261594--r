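# trilinear interpolation of a (possibly degenerate-axis) gridded field
# xs, ys, zs: coordinate vectors of the field's own sampling locations
interp3 <- function(xs, ys, zs, F, P) {
  one <- function(x, q) {
    n <- length(x)
    if (n == 1) return(list(i = rep(1L, length(q)), t = rep(0, length(q))))
    i <- pmin(pmax(findInterval(q, x), 1L), n - 1L)
    t <- (q - x[i]) / (x[i + 1] - x[i])
    list(i = i, t = pmin(pmax(t, 0), 1))
  }
  a <- one(xs, P[, 1]); b <- one(ys, P[, 2]); cc <- one(zs, P[, 3])
  d <- dim(F)
  lin <- function(i, j, k) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
  i2 <- if (d[1] > 1) a$i + 1L else a$i
  j2 <- if (d[2] > 1) b$i + 1L else b$i
  k2 <- if (d[3] > 1) cc$i + 1L else cc$i
  F[lin(a$i, b$i, cc$i)] * (1 - a$t) * (1 - b$t) * (1 - cc$t) +
    F[lin(i2, b$i, cc$i)] * a$t * (1 - b$t) * (1 - cc$t) +
    F[lin(a$i, j2, cc$i)] * (1 - a$t) * b$t * (1 - cc$t) +
    F[lin(i2, j2, cc$i)] * a$t * b$t * (1 - cc$t) +
    F[lin(a$i, b$i, k2)] * (1 - a$t) * (1 - b$t) * cc$t +
    F[lin(i2, b$i, k2)] * a$t * (1 - b$t) * cc$t +
    F[lin(a$i, j2, k2)] * (1 - a$t) * b$t * cc$t +
    F[lin(i2, j2, k2)] * a$t * b$t * cc$t
}

# local grid spacing projected on a unit normal: |n_x| dx + |n_y| dy + ...
# over active axes; the natural band width for classifying nodes around a
# surface of that orientation
normal_spacing_at <- function(grid, P, N) {
  ix <- pmin(pmax(findInterval(P[, 1], grid$xf), 1L), grid$nx)
  iy <- pmin(pmax(findInterval(P[, 2], grid$yf), 1L), grid$ny)
  iz <- pmin(pmax(findInterval(P[, 3], grid$zf), 1L), grid$nz)
  act <- c(grid$nx > 1, grid$ny > 1, grid$nz > 1)
  h <- numeric(nrow(P))
  if (act[1]) h <- h + abs(N[, 1]) * grid$dx[ix]
  if (act[2]) h <- h + abs(N[, 2]) * grid$dy[iy]
  if (act[3]) h <- h + abs(N[, 3]) * grid$dz[iz]
  pmax(h, local_spacing_at(grid, P) * 0.5)
}

# local grid spacing at points (geometric mean over active axes)
local_spacing_at <- function(grid, P) {
  ix <- pmin(pmax(findInterval(P[, 1], grid$xf), 1L), grid$nx)
  iy <- pmin(pmax(findInterval(P[, 2], grid$yf), 1L), grid$ny)
  iz <- pmin(pmax(findInterval(P[, 3], grid$zf), 1L), grid$nz)
  act <- c(grid$nx > 1, grid$ny > 1, grid$nz > 1)
  h <- rep(1, nrow(P))
  if (act[1]) h <- h * grid$dx[ix]
  if (act[2]) h <- h * grid$dy[iy]
  if (act[3]) h <- h * grid$dz[iz]
  h^(1 / max(1, sum(act)))
}

#' Build the immersed-boundary interpolation map for a surface
#'
#' Classifies velocity nodes within `cfg$ib_band` local grid spacings of the
#' thin surface (on each side separately) as IB nodes. For each IB node a
#' linear interpolation profile is built along the local surface normal
#' between the no-slip surface point (value = local surface velocity) and a
#' fluid probe point beyond the node on the same side; the probe value is
#' obtained by trilinear interpolation. Each element's (i, j, k) cell
#' location is found by binary search per axis.
#'
#' @param grid A [build_grid()] result.
#' @param surface An `immersed_surface`.
#' @param cfg A [solver_config()].
#' @param probe_gap Probe distance beyond the surface in local spacings.
#' @return An object of class `ib_map`.
#' @export
build_ib_map <- function(grid, surface, cfg, probe_gap = 1.8) {
  el <- surface$elements
  E <- cbind(el$centroid_x, el$centroid_y, el$centroid_z)
  # every element must live inside the (refined part of the) domain
  box <- list(x = range(grid$xf), y = range(grid$yf), z = range(grid$zf))
  bad <- which(E[, 1] < box$x[1] | E[, 1] > box$x[2] |
                 E[, 2] < box$y[1] | E[, 2] > box$y[2] |
                 E[, 3] < box$z[1] | E[, 3] > box$z[2])
  fw_assert(length(bad) == 0,
            "surface element %s lies outside the fluid domain",
            paste(head(bad, 3), collapse = ", "))
  N <- cbind(el$normal_x, el$normal_y, el$normal_z)
  Vel <- cbind(el$vel_x, el$vel_y, el$vel_z)
  elem_cells <- cbind(
    i = pmin(pmax(findInterval(E[, 1], grid$xf), 1L), grid$nx),
    j = pmin(pmax(findInterval(E[, 2], grid$yf), 1L), grid$ny),
    k = pmin(pmax(findInterval(E[, 3], grid$zf), 1L), grid$nz))

  A <- surface$vertices[surface$tri[, 1], , drop = FALSE]
  B <- surface$vertices[surface$tri[, 2], , drop = FALSE]
  C <- surface$vertices[surface$tri[, 3], , drop = FALSE]
  h_e <- normal_spacing_at(grid, E, N)

  comp_coords <- list(
    u = list(x = grid$xf, y = grid$yc, z = grid$zc),
    v = list(x = grid$xc, y = grid$yf, z = grid$zc),
    w = list(x = grid$xc, y = grid$yc, z = grid$zf))

  maps <- lapply(names(comp_coords), function(comp) {
    co <- comp_coords[[comp]]
    dims <- c(length(co$x), length(co$y), length(co$z))
    node <- integer(0); elem <- integer(0); dist <- numeric(0)
    for (e in seq_len(nrow(E))) {
      band <- cfg$ib_band * h_e[e]
      vx <- range(A[e, 1], B[e, 1], C[e, 1])
      vy <- range(A[e, 2], B[e, 2], C[e, 2])
      vz <- range(A[e, 3], B[e, 3], C[e, 3])
      ir <- idx_in(co$x, vx[1] - band, vx[2] + band)
      jr <- idx_in(co$y, vy[1] - band, vy[2] + band)
      kr <- idx_in(co$z, vz[1] - band, vz[2] + band)
      if (!length(ir) || !length(jr) || !length(kr)) next
      g <- expand.grid(i = ir, j = jr, k = kr)
      X <- cbind(co$x[g$i], co$y[g$j], co$z[g$k])
      r <- X - matrix(A[e, ], nrow(X), 3, byrow = TRUE)
      d <- r %*% N[e, ]
      # nodes exactly on the surface (d = 0) are kept: they receive the
      # surface velocity itself
      keep <- abs(d) <= band
      if (!any(keep)) next
      # lateral containment: barycentric coordinates of the in-plane foot
      q <- r[keep, , drop = FALSE] - d[keep] %*% t(N[e, ])
      e1 <- B[e, ] - A[e, ]; e2 <- C[e, ] - A[e, ]
      d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
      det <- d11 * d22 - d12^2
      q1 <- q %*% e1; q2 <- q %*% e2
      al <- (d22 * q1 - d12 * q2) / det
      be <- (d11 * q2 - d12 * q1) / det
      tol <- 0.25
      inside <- al >= -tol & be >= -tol & (al + be) <= 1 + tol
      if (!any(inside)) next
      sel <- which(keep)[inside]
      node <- c(node, g$i[sel] + (g$j[sel] - 1L) * dims[1] +
                  (g$k[sel] - 1L) * dims[1] * dims[2])
      elem <- c(elem, rep(e, length(sel)))
      dist <- c(dist, d[keep][inside])
    }
    if (!length(node)) {
      return(list(node = integer(0)))
    }
    ord <- order(abs(dist))
    first <- !duplicated(node[ord])
    node <- node[ord][first]; elem <- elem[ord][first]
    dist <- dist[ord][first]

    # probe point beyond the node along the same-side normal
    co_x <- co$x; co_y <- co$y; co_z <- co$z
    k3 <- cbind((node - 1L) %% dims[1] + 1L,
                ((node - 1L) %/% dims[1]) %% dims[2] + 1L,
                (node - 1L) %/% (dims[1] * dims[2]) + 1L)
    X <- cbind(co_x[k3[, 1]], co_y[k3[, 2]], co_z[k3[, 3]])
    n_e <- N[elem, , drop = FALSE]
    foot <- X - dist * n_e
    hloc <- normal_spacing_at(grid, X, n_e)
    L <- abs(dist) + probe_gap * hloc
    probe <- foot + sign(dist) * L * n_e
    # clamp probes into the domain
    probe[, 1] <- pmin(pmax(probe[, 1], box$x[1]), box$x[2])
    probe[, 2] <- pmin(pmax(probe[, 2], box$y[1]), box$y[2])
    probe[, 3] <- pmin(pmax(probe[, 3], box$z[1]), box$z[2])
    list(node = node, elem = elem, dist = abs(dist), L = L, probe = probe,
         comp = comp, cells = k3)
  })
  names(maps) <- names(comp_coords)

  # cells adjacent to IB nodes (divergence there is not a fluid-cell check)
  touched <- integer(0)
  lin_cell <- function(i, j, k) i + (j - 1L) * grid$nx + (k - 1L) * grid$nx * grid$ny
  for (comp in names(maps)) {
    m <- maps[[comp]]
    if (!length(m$node)) next
    k3 <- m$cells
    if (comp == "u") {
      touched <- c(touched,
                   lin_cell(pmax(k3[, 1] - 1L, 1L), k3[, 2], k3[, 3]),
                   lin_cell(pmin(k3[, 1], grid$nx), k3[, 2], k3[, 3]))
    } else if (comp == "v") {
      touched <- c(touched,
                   lin_cell(k3[, 1], pmax(k3[, 2] - 1L, 1L), k3[, 3]),
                   lin_cell(k3[, 1], pmin(k3[, 2], grid$ny), k3[, 3]))
    } else {
      touched <- c(touched,
                   lin_cell(k3[, 1], k3[, 2], pmax(k3[, 3] - 1L, 1L)),
                   lin_cell(k3[, 1], k3[, 2], pmin(k3[, 3], grid$nz)))
    }
  }

  structure(list(maps = maps, elem_cells = elem_cells,
                 elem_velocity = Vel, touched_cells = unique(touched),
                 coords = comp_coords, time = surface$time),
            class = "ib_map")
}

idx_in <- function(x, lo, hi) {
  i1 <- findInterval(lo, x) + 1L
  i2 <- findInterval(hi, x)
  if (i2 < i1) integer(0) else seq(i1, i2)
}

#' @export
print.ib_map <- function(x, ...) {
  n <- vapply(x$maps, function(m) length(m$node), 1L)
  cat(sprintf("<ib_map> IB nodes: u %d, v %d, w %d (%d elements)\n",
              n[["u"]], n[["v"]], n[["w"]], nrow(x$elem_cells)))
  invisible(x)
}

# overwrite IB node velocities with the normal-line interpolated profile
apply_ib_velocity <- function(state, ib) {
  for (comp in c("u", "v", "w")) {
    m <- ib$maps[[comp]]
    if (!length(m$node)) next
    co <- ib$coords[[comp]]
    us <- ib$elem_velocity[m$elem, match(comp, c("u", "v", "w"))]
    uf <- interp3(co$x, co$y, co$z, state[[comp]], m$probe)
    state[[comp]][m$node] <- us + (m$dist / m$L) * (uf - us)
  }
  state
}

#' Sample pressure and viscous traction on both sides of the surface
#'
#' For every element and each side of the thin surface, samples the fluid
#' pressure and velocity at a probe point offset along the (signed) element
#' normal, extrapolates pressure to the wall using the moving-wall normal
#' pressure-gradient correction `dp/dn = -rho (a . n)`, and forms the viscous
#' traction from the one-sided tangential velocity gradient (first-order).
#'
#' @param state A [flow_state()].
#' @param grid The grid.
#' @param surface The `immersed_surface` at the same time instant.
#' @param cfg The [solver_config()].
#' @param probe_factor Sampling offset in local grid spacings.
#' @return A `surface_loads` tibble: one row per (element, side) with the
#'   outward side normal, pressure, traction vector, element area, region and
#'   element velocity; the surface time is attached as an attribute.
#' @export
surface_loads <- function(state, grid, surface, cfg, probe_factor = 1.8) {
  el <- surface$elements
  E <- cbind(el$centroid_x, el$centroid_y, el$centroid_z)
  N <- cbind(el$normal_x, el$normal_y, el$normal_z)
  V <- cbind(el$vel_x, el$vel_y, el$vel_z)
  Acc <- cbind(el$acc_x, el$acc_y, el$acc_z)
  h <- probe_factor * normal_spacing_at(grid, E, N)
  nuc <- cfg$nu + state$nu_t

  clamp_dom <- function(P) {
    P[, 1] <- pmin(pmax(P[, 1], grid$xf[1]), grid$xf[grid$nx + 1])
    P[, 2] <- pmin(pmax(P[, 2], grid$yf[1]), grid$yf[grid$ny + 1])
    P[, 3] <- pmin(pmax(P[, 3], grid$zf[1]), grid$zf[grid$nz + 1])
    P
  }
  out <- lapply(c(1, -1), function(s) {
    n_s <- s * N
    P <- clamp_dom(E + n_s * h)
    P2 <- clamp_dom(E + n_s * (2 * h))
    # two-point linear extrapolation of pressure to the wall, plus the
    # moving-wall normal-gradient correction over the first offset
    p1 <- interp3(grid$xc, grid$yc, grid$zc, state$p, P)
    p2 <- interp3(grid$xc, grid$yc, grid$zc, state$p, P2)
    p_s <- 2 * p1 - p2 + cfg$rho * rowSums(Acc * n_s) * h
    us <- interp3(grid$xf, grid$yc, grid$zc, state$u, P)
    vs <- interp3(grid$xc, grid$yf, grid$zc, state$v, P)
    ws <- interp3(grid$xc, grid$yc, grid$zf, state$w, P)
    rel <- cbind(us, vs, ws) - V
    reln <- rowSums(rel * n_s)
    relt <- rel - reln * n_s
    nu_tot <- interp3(grid$xc, grid$yc, grid$zc, nuc, P)
    tau <- relt * (cfg$rho * nu_tot / h)
    tibble(element = seq_len(nrow(E)), side = s,
           n_x = n_s[, 1], n_y = n_s[, 2], n_z = n_s[, 3],
           p_Pa = p_s, tau_x = tau[, 1], tau_y = tau[, 2], tau_z = tau[, 3],
           area_m2 = el$area_m2, region = el$region,
           vel_x = V[, 1], vel_y = V[, 2], vel_z = V[, 3])
  })
  loads <- dplyr::bind_rows(out)
  attr(loads, "time") <- surface$time
  class(loads) <- c("surface_loads", class(loads))
  loads
}
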