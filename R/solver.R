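#' Solver configuration
#'
#' Numerical settings of the incompressible fractional-step solver: fluid
#' properties, time step (fixed `dt` or CFL-targeted), LES switch, boundary
#' conditions per face, moving-frame velocity, and pressure-solve tolerance.
#'
#' Boundary conditions are a named list with entries `xlo`, `xhi`, `ylo`,
#' `yhi`, `zlo`, `zhi`; each face is one of `bc_dirichlet(u)`, `bc_noslip()`,
#' or `bc_outflow()`. Periodic axes are declared on the grid, not here.
#' [bc_tunnel()] builds the flight-tunnel set: Dirichlet free stream on the
#' inlet and four side walls, zero-gradient outflow (+x) with a uniform flux
#' correction enforcing global mass balance.
#'
#' @param nu Kinematic molecular viscosity (m^2/s).
#' @param rho Density (kg/m^3).
#' @param dt Fixed time step (s); when `NULL` the step is chosen from `cfl`
#'   and the explicit viscous stability bound.
#' @param cfl Target convective CFL number (<= 1).
#' @param les Enable the dynamic Smagorinsky subgrid model.
#' @param test_filter_ratio Test-to-grid filter width ratio (default 2).
#' @param frame_velocity Streamwise speed of the moving reference frame
#'   (m/s); subtracted from wing kinematics by [run_simulation()].
#' @param bc Boundary-condition list (see Details).
#' @param p_tol Pressure-solve residual tolerance (relative).
#' @param ib_band IB classification band in local grid spacings.
#' @param body_force Constant body acceleration (length 3, m/s^2), e.g. a
#'   mean pressure gradient driving a periodic channel.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(nu, rho = 1.225, dt = NULL, cfl = 0.4, les = FALSE,
                          test_filter_ratio = 2, frame_velocity = 0,
                          bc = bc_tunnel(c(0, 0, 0)), p_tol = 1e-8,
                          ib_band = 1.0, body_force = c(0, 0, 0)) {
  fw_assert(nu > 0 && rho > 0, "nu and rho must be positive")
  fw_assert(p_tol > 0, "p_tol must be positive")
  fw_assert(cfl > 0 && cfl <= 1, "cfl must be in (0, 1]")
  structure(list(nu = nu, rho = rho, dt = dt, cfl = cfl, les = les,
                 test_filter_ratio = test_filter_ratio,
                 frame_velocity = frame_velocity, bc = bc, p_tol = p_tol,
                 ib_band = ib_band, body_force = as.numeric(body_force)),
            class = "solver_config")
}

#' @rdname solver_config
#' @param u Length-3 boundary velocity (m/s).
#' @export
bc_dirichlet <- function(u) list(type = "dirichlet", u = as.numeric(u))

#' @rdname solver_config
#' @export
bc_noslip <- function() list(type = "dirichlet", u = c(0, 0, 0))

#' @rdname solver_config
#' @export
bc_outflow <- function() list(type = "outflow")

#' @rdname solver_config
#' @param U_inf Free-stream velocity (m/s), along +x.
#' @export
bc_tunnel <- function(U_inf) {
  if (length(U_inf) == 1) U_inf <- c(U_inf, 0, 0)
  d <- bc_dirichlet(U_inf)
  list(xlo = d, xhi = bc_outflow(), ylo = d, yhi = d, zlo = d, zhi = d)
}

#' Initialize a flow state
#'
#' Staggered (MAC) arrangement: face-normal velocity components on cell
#' faces, pressure and eddy viscosity at cell centers.
#'
#' @param grid A [build_grid()] result.
#' @param u0 Initial uniform velocity (length 3, m/s) or a list with full
#'   arrays `u` (nx+1 x ny x nz), `v`, `w`.
#' @return An object of class `flow_state`.
#' @export
flow_state <- function(grid, u0 = c(0, 0, 0)) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  if (is.list(u0)) {
    u <- u0$u; v <- u0$v; w <- u0$w
  } else {
    u <- array(u0[1], c(nx + 1, ny, nz))
    v <- array(u0[2], c(nx, ny + 1, nz))
    w <- array(u0[3], c(nx, ny, nz + 1))
  }
  structure(list(u = u, v = v, w = w,
                 p = array(0, c(nx, ny, nz)),
                 nu_t = array(0, c(nx, ny, nz)),
                 time = 0, step = 0L, h_old = NULL,
                 max_div = NA_real_),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> t = %.5g s (step %d), max |div u| = %.3g\n",
              x$time, x$step, x$max_div))
  invisible(x)
}

# ---- array helpers (recycling-aware division along a given dim) ----
div1 <- function(A, v) A / v
div2 <- function(A, v) A / rep(v, each = dim(A)[1])
div3 <- function(A, v) A / rep(v, each = dim(A)[1] * dim(A)[2])
mul2 <- function(A, v) A * rep(v, each = dim(A)[1])
mul3 <- function(A, v) A * rep(v, each = dim(A)[1] * dim(A)[2])

# ghost-extend a cell-centered array along one dim (1, 2 or 3)
# mode: "periodic", "copy" (zero-gradient), or "mirror" with value vlo/vhi
# (tangential Dirichlet: ghost = 2*val - interior)
extend_dim <- function(A, dim, lo, hi, vlo = 0, vhi = 0) {
  d <- base::dim(A)
  n <- d[dim]
  pick <- function(i) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[dim]] <- i
    do.call(`[`, c(list(A), idx, list(drop = FALSE)))
  }
  glo <- switch(lo, periodic = pick(n), copy = pick(1),
                mirror = 2 * vlo - pick(1),
                extrap = if (n > 1) 2 * pick(1) - pick(2) else pick(1))
  ghi <- switch(hi, periodic = pick(1), copy = pick(n),
                mirror = 2 * vhi - pick(n),
                extrap = if (n > 1) 2 * pick(n) - pick(n - 1) else pick(n))
  abind_dim(list(glo, A, ghi), dim)
}

# bind 3D arrays along a dimension (tiny abind)
abind_dim <- function(lst, dim) {
  if (dim == 1) {
    do.call(rbind3, lst)
  } else if (dim == 2) {
    aperm(do.call(rbind3, lapply(lst, aperm, c(2, 1, 3))), c(2, 1, 3))
  } else {
    aperm(do.call(rbind3, lapply(lst, aperm, c(3, 2, 1))), c(3, 2, 1))
  }
}

rbind3 <- function(...) {
  lst <- list(...)
  d <- dim(lst[[1]])
  n1 <- vapply(lst, function(a) dim(a)[1], 1L)
  out <- array(0, c(sum(n1), d[2], d[3]))
  at <- 0L
  for (a in lst) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# slice helper along dim1
s1 <- function(A, i) A[i, , , drop = FALSE]

# ---- canonical convection + diffusion for one velocity component ----
# ua: component on its own faces (na+1, nb, nc); ub, uc: the two cross
# components on their faces, already permuted so dims are (a, b, c).
# met: list(da, dac, db, dbc, dc, dcc); bcmodes/bcvals: per face of the
# permuted axes for THIS component (a_lo, a_hi, b_lo, b_hi, c_lo, c_hi).
# nu_c: total kinematic viscosity at cell centers (na, nb, nc), ghost-ready.
# per_a: is the a axis periodic. Returns H at active faces + the index set.
conv_diff_canonical <- function(ua, ub, uc, nu_c, met, per_a,
                                bmode, bval) {
  d <- dim(ua); na <- d[1] - 1L; nb <- d[2]; nc <- d[3]
  ia <- if (per_a) seq_len(na) else seq(2L, na)
  c1 <- ifelse(ia == 1L, na, ia - 1L)  # cell left of face
  c2 <- ia                             # cell right of face

  # --- convection, divergence form ---
  ucc <- (s1(ua, 1:na) + s1(ua, 2:(na + 1))) / 2
  Faa <- ucc * ucc
  conv <- div1((s1(Faa, c2) - s1(Faa, c1)), met$dac[ia])

  uaext_b <- extend_dim(ua, 2, bmode["b_lo"], bmode["b_hi"],
                        bval["b_lo"], bval["b_hi"])
  uab <- (uaext_b[, 1:(nb + 1), , drop = FALSE] +
            uaext_b[, 2:(nb + 2), , drop = FALSE]) / 2  # (na+1, nb+1, nc)
  ubbar <- (s1(ub, c1) + s1(ub, c2)) / 2                # (nact, nb+1, nc)
  Fab <- ubbar * s1(uab, ia)
  conv <- conv + div2(Fab[, 2:(nb + 1), , drop = FALSE] -
                        Fab[, 1:nb, , drop = FALSE], met$db)

  uaext_c <- extend_dim(ua, 3, bmode["c_lo"], bmode["c_hi"],
                        bval["c_lo"], bval["c_hi"])
  uac <- (uaext_c[, , 1:(nc + 1), drop = FALSE] +
            uaext_c[, , 2:(nc + 2), drop = FALSE]) / 2
  ucbar <- (s1(uc, c1) + s1(uc, c2)) / 2
  Fac <- ucbar * s1(uac, ia)
  conv <- conv + div3(Fac[, , 2:(nc + 1), drop = FALSE] -
                        Fac[, , 1:nc, drop = FALSE], met$dc)

  # --- diffusion, conservative flux form with total viscosity ---
  duda <- div1(s1(ua, 2:(na + 1)) - s1(ua, 1:na), met$da)  # at centers
  Ga <- nu_c * duda
  diff <- div1(s1(Ga, c2) - s1(Ga, c1), met$dac[ia])

  # viscosity at b-edges of the active a-faces
  nub <- extend_dim(nu_c, 2, bmode_nu(bmode["b_lo"]), bmode_nu(bmode["b_hi"]))
  nu_be <- (nub[, 1:(nb + 1), , drop = FALSE] + nub[, 2:(nb + 2), , drop = FALSE]) / 2
  nu_be <- (s1(nu_be, c1) + s1(nu_be, c2)) / 2
  duadb <- div2(uaext_b[, 2:(nb + 2), , drop = FALSE] -
                  uaext_b[, 1:(nb + 1), , drop = FALSE], met$dbc)
  Gb <- nu_be * s1(duadb, ia)
  diff <- diff + div2(Gb[, 2:(nb + 1), , drop = FALSE] -
                        Gb[, 1:nb, , drop = FALSE], met$db)

  nuc_ <- extend_dim(nu_c, 3, bmode_nu(bmode["c_lo"]), bmode_nu(bmode["c_hi"]))
  nu_ce <- (nuc_[, , 1:(nc + 1), drop = FALSE] + nuc_[, , 2:(nc + 2), drop = FALSE]) / 2
  nu_ce <- (s1(nu_ce, c1) + s1(nu_ce, c2)) / 2
  duadc <- div3(uaext_c[, , 2:(nc + 2), drop = FALSE] -
                  uaext_c[, , 1:(nc + 1), drop = FALSE], met$dcc)
  Gc <- nu_ce * s1(duadc, ia)
  diff <- diff + div3(Gc[, , 2:(nc + 1), drop = FALSE] -
                        Gc[, , 1:nc, drop = FALSE], met$dc)

  list(H = diff - conv, ia = ia)
}

bmode_nu <- function(mode) if (mode == "periodic") "periodic" else "copy"

# BC mode/value tables for a component along `axis` given the config
component_bc <- function(cfg, grid, comp_axis, b_axis, c_axis) {
  faces <- list(x = c("xlo", "xhi"), y = c("ylo", "yhi"), z = c("zlo", "zhi"))
  axname <- c("x", "y", "z")
  mode_of <- function(axis, side) {
    if (grid$periodic[axis]) return("periodic")
    b <- cfg$bc[[faces[[axname[axis]]][side]]]
    fw_assert(!is.null(b), "missing boundary condition for face %s",
              faces[[axname[axis]]][side])
    if (b$type == "dirichlet") "mirror" else "copy"
  }
  val_of <- function(axis, side) {
    if (grid$periodic[axis]) return(0)
    b <- cfg$bc[[faces[[axname[axis]]][side]]]
    if (b$type == "dirichlet") b$u[comp_axis] else 0
  }
  list(mode = c(b_lo = mode_of(b_axis, 1), b_hi = mode_of(b_axis, 2),
                c_lo = mode_of(c_axis, 1), c_hi = mode_of(c_axis, 2)),
       val = c(b_lo = val_of(b_axis, 1), b_hi = val_of(b_axis, 2),
               c_lo = val_of(c_axis, 1), c_hi = val_of(c_axis, 2)))
}

# H (convection + diffusion) for all three components; returns full-size
# arrays with zeros at non-active faces
compute_rhs <- function(state, grid, cfg) {
  nu_c <- cfg$nu + state$nu_t

  met_u <- list(da = grid$dx, dac = grid$dxc, db = grid$dy, dbc = grid$dyc,
                dc = grid$dz, dcc = grid$dzc)
  bcu <- component_bc(cfg, grid, 1, 2, 3)
  ru <- conv_diff_canonical(state$u, state$v, state$w, nu_c, met_u,
                            grid$periodic[1], bcu$mode, bcu$val)
  Hu <- array(0, dim(state$u)); Hu[ru$ia, , ] <- ru$H

  met_v <- list(da = grid$dy, dac = grid$dyc, db = grid$dx, dbc = grid$dxc,
                dc = grid$dz, dcc = grid$dzc)
  bcv <- component_bc(cfg, grid, 2, 1, 3)
  pv <- c(2, 1, 3)
  rv <- conv_diff_canonical(aperm(state$v, pv), aperm(state$u, pv),
                            aperm(state$w, pv), aperm(nu_c, pv), met_v,
                            grid$periodic[2], bcv$mode, bcv$val)
  Hvp <- array(0, dim(aperm(state$v, pv))); Hvp[rv$ia, , ] <- rv$H
  Hv <- aperm(Hvp, pv)

  met_w <- list(da = grid$dz, dac = grid$dzc, db = grid$dx, dbc = grid$dxc,
                dc = grid$dy, dcc = grid$dyc)
  bcw <- component_bc(cfg, grid, 3, 1, 2)
  pw <- c(3, 1, 2)
  rw <- conv_diff_canonical(aperm(state$w, pw), aperm(state$u, pw),
                            aperm(state$v, pw), aperm(nu_c, pw), met_w,
                            grid$periodic[3], bcw$mode, bcw$val)
  Hwp <- array(0, dim(aperm(state$w, pw))); Hwp[rw$ia, , ] <- rw$H
  Hw <- aperm(Hwp, c(2, 3, 1))

  list(u = Hu, v = Hv, w = Hw)
}

#' Apply boundary conditions to a flow state
#'
#' Sets normal boundary-face velocities from the face conditions: Dirichlet
#' values on inflow/wall faces, zero-gradient on outflow faces followed by a
#' uniform flux correction over all outflow faces enforcing zero net boundary
#' flux, and duplicate-face synchronization on periodic axes.
#'
#' @param state A [flow_state()].
#' @param grid The [build_grid()] result.
#' @param cfg The [solver_config()].
#' @return The updated state.
#' @export
apply_boundary_conditions <- function(state, grid, cfg) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  u <- state$u; v <- state$v; w <- state$w
  bc <- cfg$bc
  # face areas
  Ax <- outer(grid$dy, grid$dz)          # ny x nz
  Ay <- outer(grid$dx, grid$dz)          # nx x nz
  Az <- outer(grid$dx, grid$dy)          # nx x ny

  set_face <- function(arr, axis, side, value) {
    n <- dim(arr)[axis]
    if (axis == 1) { if (side == 1) arr[1, , ] <- value else arr[n, , ] <- value }
    if (axis == 2) { if (side == 1) arr[, 1, ] <- value else arr[, n, ] <- value }
    if (axis == 3) { if (side == 1) arr[, , 1] <- value else arr[, , n] <- value }
    arr
  }

  outflows <- list()
  for (spec in list(list("xlo", 1, 1), list("xhi", 1, 2), list("ylo", 2, 1),
                    list("yhi", 2, 2), list("zlo", 3, 1), list("zhi", 3, 2))) {
    fname <- spec[[1]]; axis <- spec[[2]]; side <- spec[[3]]
    if (grid$periodic[axis]) next
    b <- bc[[fname]]
    arr_name <- c("u", "v", "w")[axis]
    arr <- get(arr_name)
    if (b$type == "dirichlet") {
      arr <- set_face(arr, axis, side, b$u[axis])
    } else if (b$type == "outflow") {
      n <- dim(arr)[axis]
      inner <- if (side == 1) 2L else n - 1L
      edge <- if (side == 1) 1L else n
      val <- switch(axis, arr[inner, , ], arr[, inner, ], arr[, , inner])
      arr <- set_face(arr, axis, side, val)
      outflows[[length(outflows) + 1L]] <- list(arr = arr_name, axis = axis,
                                                side = side, edge = edge)
    }
    assign(arr_name, arr)
  }

  # periodic duplicate faces
  if (grid$periodic[1]) { u[nx + 1, , ] <- u[1, , ] }
  if (grid$periodic[2]) { v[, ny + 1, ] <- v[, 1, ] }
  if (grid$periodic[3]) { w[, , nz + 1] <- w[, , 1] }

  # global mass balance via uniform correction over outflow faces
  if (length(outflows)) {
    net <- boundary_net_flux(u, v, w, grid)
    area <- 0
    for (o in outflows) {
      A <- switch(o$axis, Ax, Ay, Az)
      area <- area + sum(A)
    }
    corr <- net / area
    for (o in outflows) {
      sgn <- if (o$side == 2) 1 else -1   # outward direction
      if (o$axis == 1) u[o$edge, , ] <- u[o$edge, , ] - sgn * corr
      if (o$axis == 2) v[, o$edge, ] <- v[, o$edge, ] - sgn * corr
      if (o$axis == 3) w[, , o$edge] <- w[, , o$edge] - sgn * corr
    }
  }
  state$u <- u; state$v <- v; state$w <- w
  state
}

# net outward boundary volume flux
boundary_net_flux <- function(u, v, w, grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  Ax <- outer(grid$dy, grid$dz); Ay <- outer(grid$dx, grid$dz)
  Az <- outer(grid$dx, grid$dy)
  fx <- if (grid$periodic[1]) 0 else
    sum(u[nx + 1, , ] * Ax) - sum(u[1, , ] * Ax)
  fy <- if (grid$periodic[2]) 0 else
    sum(v[, ny + 1, ] * Ay) - sum(v[, 1, ] * Ay)
  fz <- if (grid$periodic[3]) 0 else
    sum(w[, , nz + 1] * Az) - sum(w[, , 1] * Az)
  fx + fy + fz
}

# cell-wise divergence (nx, ny, nz)
divergence <- function(u, v, w, grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  div1(u[2:(nx + 1), , , drop = FALSE] - u[1:nx, , , drop = FALSE], grid$dx) +
    div2(v[, 2:(ny + 1), , drop = FALSE] - v[, 1:ny, , drop = FALSE], grid$dy) +
    div3(w[, , 2:(nz + 1), drop = FALSE] - w[, , 1:nz, drop = FALSE], grid$dz)
}

# ---- pressure Poisson operator: symmetric FV Laplacian, cached factor ----
poisson_operator <- function(grid, cfg) {
  key <- paste0("poisson_",
                paste(vapply(cfg$bc, function(b) b$type %||% "p", ""),
                      collapse = "_"),
                paste(grid$periodic, collapse = ""))
  hit <- grid$cache[[key]]
  if (!is.null(hit)) return(hit)

  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  N <- nx * ny * nz
  idx <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_v <- numeric(N)
  add_pair <- function(a, b, coef) {
    ii <<- c(ii, a, b); jj <<- c(jj, b, a); vv <<- c(vv, -coef, -coef)
    diag_v[a] <<- diag_v[a] + coef
    diag_v[b] <<- diag_v[b] + coef
  }
  grd <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))

  # x-direction connections
  if (nx > 1) {
    g <- grd[grd$i < nx, ]
    a <- idx(g$i, g$j, g$k); b <- idx(g$i + 1L, g$j, g$k)
    coef <- (grid$dy[g$j] * grid$dz[g$k]) / grid$dxc[g$i + 1L]
    ii <- c(ii, a, b); jj <- c(jj, b, a); vv <- c(vv, -coef, -coef)
    dtab <- tapply(c(coef, coef), c(a, b), sum)
    diag_v[as.integer(names(dtab))] <- diag_v[as.integer(names(dtab))] + dtab
  }
  if (grid$periodic[1] && nx > 1) {
    g <- grd[grd$i == nx, ]
    a <- idx(g$i, g$j, g$k); b <- idx(1L, g$j, g$k)
    coef <- (grid$dy[g$j] * grid$dz[g$k]) / grid$dxc[1L]
    ii <- c(ii, a, b); jj <- c(jj, b, a); vv <- c(vv, -coef, -coef)
    dtab <- tapply(c(coef, coef), c(a, b), sum)
    diag_v[as.integer(names(dtab))] <- diag_v[as.integer(names(dtab))] + dtab
  }
  # y-direction
  if (ny > 1) {
    g <- grd[grd$j < ny, ]
    a <- idx(g$i, g$j, g$k); b <- idx(g$i, g$j + 1L, g$k)
    coef <- (grid$dx[g$i] * grid$dz[g$k]) / grid$dyc[g$j + 1L]
    ii <- c(ii, a, b); jj <- c(jj, b, a); vv <- c(vv, -coef, -coef)
    dtab <- tapply(c(coef, coef), c(a, b), sum)
    diag_v[as.integer(names(dtab))] <- diag_v[as.integer(names(dtab))] + dtab
  }
  if (grid$periodic[2] && ny > 1) {
    g <- grd[grd$j == ny, ]
    a <- idx(g$i, g$j, g$k); b <- idx(g$i, 1L, g$k)
    coef <- (grid$dx[g$i] * grid$dz[g$k]) / grid$dyc[1L]
    ii <- c(ii, a, b); jj <- c(jj, b, a); vv <- c(vv, -coef, -coef)
    dtab <- tapply(c(coef, coef), c(a, b), sum)
    diag_v[as.integer(names(dtab))] <- diag_v[as.integer(names(dtab))] + dtab
  }
  # z-direction
  if (nz > 1) {
    g <- grd[grd$k < nz, ]
    a <- idx(g$i, g$j, g$k); b <- idx(g$i, g$j, g$k + 1L)
    coef <- (grid$dx[g$i] * grid$dy[g$j]) / grid$dzc[g$k + 1L]
    ii <- c(ii, a, b); jj <- c(jj, b, a); vv <- c(vv, -coef, -coef)
    dtab <- tapply(c(coef, coef), c(a, b), sum)
    diag_v[as.integer(names(dtab))] <- diag_v[as.integer(names(dtab))] + dtab
  }
  if (grid$periodic[3] && nz > 1) {
    g <- grd[grd$k == nz, ]
    a <- idx(g$i, g$j, g$k); b <- idx(g$i, g$j, 1L)
    coef <- (grid$dx[g$i] * grid$dy[g$j]) / grid$dzc[1L]
    ii <- c(ii, a, b); jj <- c(jj, b, a); vv <- c(vv, -coef, -coef)
    dtab <- tapply(c(coef, coef), c(a, b), sum)
    diag_v[as.integer(names(dtab))] <- diag_v[as.integer(names(dtab))] + dtab
  }

  # Dirichlet p = 0 at outflow faces (normal direction)
  has_dirichlet <- FALSE
  faces <- list(xlo = c(1, 1), xhi = c(1, 2), ylo = c(2, 1), yhi = c(2, 2),
                zlo = c(3, 1), zhi = c(3, 2))
  for (fname in names(faces)) {
    axis <- faces[[fname]][1]; side <- faces[[fname]][2]
    if (grid$periodic[axis]) next
    b <- cfg$bc[[fname]]
    if (!is.null(b) && b$type == "outflow") {
      has_dirichlet <- TRUE
      if (axis == 1) {
        g <- grd[grd$i == (if (side == 1) 1L else nx), ]
        dist <- if (side == 1) grid$xc[1] - grid$xf[1] else
          grid$xf[nx + 1] - grid$xc[nx]
        coef <- (grid$dy[g$j] * grid$dz[g$k]) / dist
      } else if (axis == 2) {
        g <- grd[grd$j == (if (side == 1) 1L else ny), ]
        dist <- if (side == 1) grid$yc[1] - grid$yf[1] else
          grid$yf[ny + 1] - grid$yc[ny]
        coef <- (grid$dx[g$i] * grid$dz[g$k]) / dist
      } else {
        g <- grd[grd$k == (if (side == 1) 1L else nz), ]
        dist <- if (side == 1) grid$zc[1] - grid$zf[1] else
          grid$zf[nz + 1] - grid$zc[nz]
        coef <- (grid$dx[g$i] * grid$dy[g$j]) / dist
      }
      a <- idx(g$i, g$j, g$k)
      dtab <- tapply(coef, a, sum)
      diag_v[as.integer(names(dtab))] <- diag_v[as.integer(names(dtab))] + dtab
    }
  }

  A <- Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                            x = c(vv, diag_v), dims = c(N, N))
  pinned <- !has_dirichlet
  if (pinned) {
    Ar <- A[-1, -1, drop = FALSE]
  } else {
    Ar <- A
  }
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Ar), LDL = FALSE, perm = TRUE)
  op <- list(A = A, fac = fac, pinned = pinned, N = N)
  grid$cache[[key]] <- op
  op
}

solve_pressure <- function(op, rhs, tol) {
  b <- as.numeric(rhs)
  if (op$pinned) {
    b <- b - mean(b)
    phi <- c(0, as.numeric(Matrix::solve(op$fac, b[-1])))
    phi <- phi - mean(phi)
  } else {
    phi <- as.numeric(Matrix::solve(op$fac, b))
  }
  res <- as.numeric(op$A %*% phi) - b
  denom <- max(sqrt(sum(b^2)), 1e-300)
  attr(phi, "residual") <- sqrt(sum(res^2)) / denom
  phi
}

#' Stable time step for the current state
#'
#' Combined convective CFL and explicit-diffusion stability bound.
#'
#' @param state A [flow_state()].
#' @param grid,cfg Grid and configuration.
#' @return Time step (s).
#' @export
stable_dt <- function(state, grid, cfg) {
  hx <- min(grid$dx); hy <- min(grid$dy); hz <- min(grid$dz)
  umax <- max(abs(state$u)); vmax <- max(abs(state$v)); wmax <- max(abs(state$w))
  conv <- 1 / (umax / hx + vmax / hy + wmax / hz + 1e-12)
  numax <- cfg$nu + max(state$nu_t)
  visc <- 1 / (2 * numax * (1 / hx^2 + 1 / hy^2 + 1 / hz^2))
  min(cfg$cfl * conv, 0.5 * visc)
}

#' Advance the flow one time step
#'
#' Fractional-step advance: explicit second-order Adams-Bashforth for the
#' central-difference convection and diffusion terms (total viscosity =
#' molecular + eddy), immersed-boundary velocity imposition, then a pressure
#' projection solving the variable-coefficient finite-volume Poisson system
#' with a cached sparse Cholesky factorization, restoring the discrete
#' divergence-free constraint. IB node velocities are re-imposed after
#' projection. With LES enabled the eddy viscosity is refreshed from the
#' dynamic Smagorinsky model at the start of the step.
#'
#' @param state A [flow_state()].
#' @param grid The grid.
#' @param cfg The [solver_config()]; `cfg$dt` must be set (use [stable_dt()]).
#' @param ib Optional [build_ib_map()] for an immersed surface.
#' @return The advanced state; `state$max_div` reports the post-projection
#'   maximum absolute divergence over regular fluid cells.
#' @export
step_flow <- function(state, grid, cfg, ib = NULL) {
  dt <- cfg$dt
  fw_assert(!is.null(dt) && dt > 0, "cfg$dt must be set; see stable_dt()")
  if (cfg$les) state$nu_t <- dynamic_smagorinsky(state, grid, cfg)

  state <- apply_boundary_conditions(state, grid, cfg)
  H <- compute_rhs(state, grid, cfg)
  if (is.null(state$h_old)) {
    du <- H$u; dv <- H$v; dw <- H$w
  } else {
    du <- 1.5 * H$u - 0.5 * state$h_old$u
    dv <- 1.5 * H$v - 0.5 * state$h_old$v
    dw <- 1.5 * H$w - 0.5 * state$h_old$w
  }
  state$h_old <- H

  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  iu <- if (grid$periodic[1]) 1:nx else 2:nx
  iv <- if (grid$periodic[2]) 1:ny else 2:ny
  iw <- if (grid$periodic[3]) 1:nz else 2:nz
  bf <- cfg$body_force %||% c(0, 0, 0)
  state$u[iu, , ] <- state$u[iu, , , drop = FALSE] +
    dt * (du[iu, , , drop = FALSE] + bf[1])
  state$v[, iv, ] <- state$v[, iv, , drop = FALSE] +
    dt * (dv[, iv, , drop = FALSE] + bf[2])
  state$w[, , iw] <- state$w[, , iw, drop = FALSE] +
    dt * (dw[, , iw, drop = FALSE] + bf[3])
  state <- apply_boundary_conditions(state, grid, cfg)
  if (!is.null(ib)) state <- apply_ib_velocity(state, ib)

  for (f in c("u", "v", "w")) {
    if (!all(is.finite(state[[f]]))) {
      fw_stop("NaN/Inf detected in field '%s' at step %d (t = %.5g s)",
              f, state$step + 1L, state$time + dt)
    }
  }
  op <- poisson_operator(grid, cfg)
  vol <- outer(grid$dx, outer(grid$dy, grid$dz))
  div <- divergence(state$u, state$v, state$w, grid)
  # the assembled operator is -Laplacian (SPD), hence the sign
  rhs <- -vol * div / dt
  phi <- solve_pressure(op, rhs, cfg$p_tol)
  if (attr(phi, "residual") > cfg$p_tol) {
    fw_stop("pressure solve did not reach tolerance (residual %.3g > %.3g)",
            attr(phi, "residual"), cfg$p_tol)
  }
  phi <- array(phi, c(nx, ny, nz))

  # velocity correction on interior/periodic faces
  c1u <- ifelse(iu == 1L, nx, iu - 1L)
  state$u[iu, , ] <- state$u[iu, , , drop = FALSE] -
    dt * div1(phi[iu, , , drop = FALSE] - phi[c1u, , , drop = FALSE],
              grid$dxc[iu])
  c1v <- ifelse(iv == 1L, ny, iv - 1L)
  state$v[, iv, ] <- state$v[, iv, , drop = FALSE] -
    dt * div2(phi[, iv, , drop = FALSE] - phi[, c1v, , drop = FALSE],
              grid$dyc[iv])
  c1w <- ifelse(iw == 1L, nz, iw - 1L)
  state$w[, , iw] <- state$w[, , iw, drop = FALSE] -
    dt * div3(phi[, , iw, drop = FALSE] - phi[, , c1w, drop = FALSE],
              grid$dzc[iw])
  # outflow faces carry the phi = 0 face condition
  for (spec in list(list("xhi", 1, 2), list("xlo", 1, 1), list("yhi", 2, 2),
                    list("ylo", 2, 1), list("zhi", 3, 2), list("zlo", 3, 1))) {
    b <- cfg$bc[[spec[[1]]]]
    if (grid$periodic[spec[[2]]] || is.null(b) || b$type != "outflow") next
    axis <- spec[[2]]; side <- spec[[3]]
    if (axis == 1) {
      if (side == 2) {
        d <- grid$xf[nx + 1] - grid$xc[nx]
        state$u[nx + 1, , ] <- state$u[nx + 1, , ] - dt * (0 - phi[nx, , ]) / d
      } else {
        d <- grid$xc[1] - grid$xf[1]
        state$u[1, , ] <- state$u[1, , ] - dt * (phi[1, , ] - 0) / d
      }
    }
  }
  if (grid$periodic[1]) state$u[nx + 1, , ] <- state$u[1, , ]
  if (grid$periodic[2]) state$v[, ny + 1, ] <- state$v[, 1, ]
  if (grid$periodic[3]) state$w[, , nz + 1] <- state$w[, , 1]

  state$p <- phi * cfg$rho
  if (!is.null(ib)) state <- apply_ib_velocity(state, ib)

  div_post <- divergence(state$u, state$v, state$w, grid)
  if (!is.null(ib)) div_post[ib$touched_cells] <- 0
  state$max_div <- max(abs(div_post))

  for (f in c("u", "v", "w", "p")) {
    if (!all(is.finite(state[[f]]))) {
      fw_stop("NaN/Inf detected in field '%s' at step %d (t = %.5g s)",
              f, state$step + 1L, state$time + dt)
    }
  }
  state$time <- state$time + dt
  state$step <- state$step + 1L
  state
}
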