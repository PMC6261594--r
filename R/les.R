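# cell-centered velocity components from face values
center_velocity <- function(state, grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  list(
    u = (state$u[1:nx, , , drop = FALSE] + state$u[2:(nx + 1), , , drop = FALSE]) / 2,
    v = (state$v[, 1:ny, , drop = FALSE] + state$v[, 2:(ny + 1), , drop = FALSE]) / 2,
    w = (state$w[, , 1:nz, drop = FALSE] + state$w[, , 2:(nz + 1), drop = FALSE]) / 2)
}

# ghosts for gradients/filters: wrap on periodic axes, linear extrapolation
# otherwise (exact for linear fields, so rigid motions have zero strain
# everywhere including the boundary layer of cells)
axis_modes <- function(grid) {
  ifelse(grid$periodic, "periodic", "extrap")
}

# extended center coordinates (ghost centers mirrored / wrapped)
ext_centers <- function(grid, axis) {
  xc <- switch(axis, grid$xc, grid$yc, grid$zc)
  xf <- switch(axis, grid$xf, grid$yf, grid$zf)
  n <- length(xc)
  if (grid$periodic[axis]) {
    wrap <- switch(axis, grid$dxc, grid$dyc, grid$dzc)[1]
    c(xc[1] - wrap, xc, xc[n] + wrap)
  } else {
    c(2 * xf[1] - xc[1], xc, 2 * xf[n + 1] - xc[n])
  }
}

# central-difference gradient of a cell-centered field along an axis
grad_center <- function(A, grid, axis) {
  modes <- axis_modes(grid)
  n <- dim(A)[axis]
  if (n == 1) return(array(0, dim(A)))
  Ae <- extend_dim(A, axis, modes[axis], modes[axis])
  xe <- ext_centers(grid, axis)
  span <- xe[3:(n + 2)] - xe[1:n]
  if (axis == 1) {
    div1(Ae[3:(n + 2), , , drop = FALSE] - Ae[1:n, , , drop = FALSE], span)
  } else if (axis == 2) {
    div2(Ae[, 3:(n + 2), , drop = FALSE] - Ae[, 1:n, , drop = FALSE], span)
  } else {
    div3(Ae[, , 3:(n + 2), drop = FALSE] - Ae[, , 1:n, drop = FALSE], span)
  }
}

# discrete box filter: (1/4, 1/2, 1/4) along each active axis
test_filter <- function(A, grid) {
  modes <- axis_modes(grid)
  for (axis in 1:3) {
    n <- dim(A)[axis]
    if (n == 1) next
    Ae <- extend_dim(A, axis, modes[axis], modes[axis])
    A <- if (axis == 1) {
      0.25 * Ae[1:n, , , drop = FALSE] + 0.5 * Ae[2:(n + 1), , , drop = FALSE] +
        0.25 * Ae[3:(n + 2), , , drop = FALSE]
    } else if (axis == 2) {
      0.25 * Ae[, 1:n, , drop = FALSE] + 0.5 * Ae[, 2:(n + 1), , drop = FALSE] +
        0.25 * Ae[, 3:(n + 2), , drop = FALSE]
    } else {
      0.25 * Ae[, , 1:n, drop = FALSE] + 0.5 * Ae[, , 2:(n + 1), drop = FALSE] +
        0.25 * Ae[, , 3:(n + 2), drop = FALSE]
    }
  }
  A
}

strain_and_mag <- function(uc, grid) {
  g <- list(
    ux = grad_center(uc$u, grid, 1), uy = grad_center(uc$u, grid, 2),
    uz = grad_center(uc$u, grid, 3),
    vx = grad_center(uc$v, grid, 1), vy = grad_center(uc$v, grid, 2),
    vz = grad_center(uc$v, grid, 3),
    wx = grad_center(uc$w, grid, 1), wy = grad_center(uc$w, grid, 2),
    wz = grad_center(uc$w, grid, 3))
  s <- list(s11 = g$ux, s22 = g$vy, s33 = g$wz,
            s12 = (g$uy + g$vx) / 2, s13 = (g$uz + g$wx) / 2,
            s23 = (g$vz + g$wy) / 2)
  s$mag <- sqrt(2 * (s$s11^2 + s$s22^2 + s$s33^2 +
                       2 * (s$s12^2 + s$s13^2 + s$s23^2)))
  s
}

# local filter width: geometric mean of the active-axis spacings
local_delta <- function(grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  act <- c(nx > 1, ny > 1, nz > 1)
  lx <- array(rep(grid$dx, times = ny * nz), c(nx, ny, nz))
  ly <- array(rep(rep(grid$dy, each = nx), times = nz), c(nx, ny, nz))
  lz <- array(rep(grid$dz, each = nx * ny), c(nx, ny, nz))
  prod_l <- array(1, c(nx, ny, nz))
  if (act[1]) prod_l <- prod_l * lx
  if (act[2]) prod_l <- prod_l * ly
  if (act[3]) prod_l <- prod_l * lz
  prod_l^(1 / max(1, sum(act)))
}

#' Dynamic Smagorinsky eddy viscosity
#'
#' Germano-identity least-squares (Lilly) closure with the model coefficient
#' computed locally at each cell from a discrete box test filter at twice the
#' grid width: `nu_t = C Delta^2 |S|` with
#' `C = (L_ij M_ij) / (M_ij M_ij)` clipped at zero, `L_ij` the resolved
#' Leonard stresses and `M_ij = 2 Delta^2 (G(|S|S_ij) - alpha^2 |S~| S~_ij)`.
#' Uniform flow and solid-body rotation have zero strain, hence zero eddy
#' viscosity.
#'
#' @param state A [flow_state()].
#' @param grid The grid.
#' @param cfg The [solver_config()] (`test_filter_ratio` = alpha).
#' @return Cell-centered eddy viscosity array (m^2/s), non-negative.
#' @export
dynamic_smagorinsky <- function(state, grid, cfg = solver_config(nu = 1e-5)) {
  uc <- center_velocity(state, grid)
  s <- strain_and_mag(uc, grid)
  delta <- local_delta(grid)
  alpha2 <- cfg$test_filter_ratio^2

  uf <- list(u = test_filter(uc$u, grid), v = test_filter(uc$v, grid),
             w = test_filter(uc$w, grid))
  sf <- strain_and_mag(uf, grid)

  lij <- function(a, b, fa, fb) test_filter(a * b, grid) - fa * fb
  L11 <- lij(uc$u, uc$u, uf$u, uf$u); L22 <- lij(uc$v, uc$v, uf$v, uf$v)
  L33 <- lij(uc$w, uc$w, uf$w, uf$w); L12 <- lij(uc$u, uc$v, uf$u, uf$v)
  L13 <- lij(uc$u, uc$w, uf$u, uf$w); L23 <- lij(uc$v, uc$w, uf$v, uf$w)

  mij <- function(sij, sfij) {
    2 * delta^2 * (test_filter(s$mag * sij, grid) - alpha2 * sf$mag * sfij)
  }
  M11 <- mij(s$s11, sf$s11); M22 <- mij(s$s22, sf$s22)
  M33 <- mij(s$s33, sf$s33); M12 <- mij(s$s12, sf$s12)
  M13 <- mij(s$s13, sf$s13); M23 <- mij(s$s23, sf$s23)

  num <- L11 * M11 + L22 * M22 + L33 * M33 +
    2 * (L12 * M12 + L13 * M13 + L23 * M23)
  den <- M11^2 + M22^2 + M33^2 + 2 * (M12^2 + M13^2 + M23^2)
  C <- ifelse(den > 1e-30, num / den, 0)
  C[C < 0] <- 0
  C * delta^2 * s$mag
}

#' Delta-criterion vortex-identification field
#'
#' `Delta = (Q/3)^3 + (R/2)^2` from the second and third invariants of the
#' cell-centered velocity-gradient tensor (`Q = -tr(A^2)/2`, `R = -det(A)`
#' for incompressible flow). `Delta > 0` marks coherent vortices.
#'
#' @param state A [flow_state()].
#' @param grid The grid.
#' @return Cell-centered scalar array.
#' @export
delta_criterion <- function(state, grid) {
  uc <- center_velocity(state, grid)
  a11 <- grad_center(uc$u, grid, 1); a12 <- grad_center(uc$u, grid, 2)
  a13 <- grad_center(uc$u, grid, 3)
  a21 <- grad_center(uc$v, grid, 1); a22 <- grad_center(uc$v, grid, 2)
  a23 <- grad_center(uc$v, grid, 3)
  a31 <- grad_center(uc$w, grid, 1); a32 <- grad_center(uc$w, grid, 2)
  a33 <- grad_center(uc$w, grid, 3)
  trA2 <- a11^2 + a22^2 + a33^2 +
    2 * (a12 * a21 + a13 * a31 + a23 * a32)
  Q <- -trA2 / 2
  detA <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  R <- -detA
  (Q / 3)^3 + (R / 2)^2
}
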