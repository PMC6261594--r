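# shared fixtures: toy surfaces, canonical flows, synthetic series

# thin rectangular plate spanning the (periodic) y extent of a 2D grid,
# normal +/- x, centred at x0
make_plate_x <- function(g, x0 = 0, zlo = -0.125, zhi = 0.125, nseg = 12,
                         velocity = c(0, 0, 0)) {
  y0 <- g$yf[1]; y1 <- g$yf[length(g$yf)]
  zs <- seq(zlo, zhi, length.out = nseg + 1)
  V <- NULL; Tr <- NULL
  for (i in seq_len(nseg)) {
    b <- if (is.null(V)) 0L else nrow(V)
    V <- rbind(V, c(x0, y0, zs[i]), c(x0, y1, zs[i]),
               c(x0, y0, zs[i + 1]), c(x0, y1, zs[i + 1]))
    Tr <- rbind(Tr, c(b + 1, b + 2, b + 3), c(b + 3, b + 2, b + 4))
  }
  immersed_surface(V, Tr, velocity = velocity)
}

# horizontal plate (normal +/- z) for heaving tests
make_plate_z <- function(g, z0 = 0, xlo = -0.125, xhi = 0.125, nseg = 12,
                         velocity = c(0, 0, 0)) {
  y0 <- g$yf[1]; y1 <- g$yf[length(g$yf)]
  xs <- seq(xlo, xhi, length.out = nseg + 1)
  V <- NULL; Tr <- NULL
  for (i in seq_len(nseg)) {
    b <- if (is.null(V)) 0L else nrow(V)
    V <- rbind(V, c(xs[i], y0, z0), c(xs[i], y1, z0),
               c(xs[i + 1], y0, z0), c(xs[i + 1], y1, z0))
    Tr <- rbind(Tr, c(b + 1, b + 2, b + 3), c(b + 3, b + 2, b + 4))
  }
  immersed_surface(V, Tr, velocity = velocity)
}

# 2D Taylor-Green vortex on [0, 2pi]^2 (x-z plane, one periodic y cell)
tg_setup <- function(n, nu = 0.01, dt = 1e-3) {
  g <- build_grid(c(0, 2 * pi), c(0, 1), c(0, 2 * pi),
                  spacing = c(x = 2 * pi / n, y = 1, z = 2 * pi / n),
                  periodic = c(TRUE, TRUE, TRUE))
  cfg <- solver_config(nu = nu, dt = dt, bc = list())
  u0 <- array(0, c(g$nx + 1, 1, g$nz))
  w0 <- array(0, c(g$nx, 1, g$nz + 1))
  for (k in seq_len(g$nz)) u0[, 1, k] <- sin(g$xf) * cos(g$zc[k])
  for (k in seq_len(g$nz + 1)) w0[, 1, k] <- -cos(g$xc) * sin(g$zf[k])
  st <- flow_state(g, list(u = u0, v = array(0, c(g$nx, 2, g$nz)), w = w0))
  list(grid = g, cfg = cfg, state = st, u0 = u0, w0 = w0)
}

tg_error <- function(n, nu = 0.01, dt = 1e-3, t_end = 0.2) {
  s <- tg_setup(n, nu, dt)
  st <- s$state
  for (i in seq_len(round(t_end / dt))) st <- step_flow(st, s$grid, s$cfg)
  dec <- exp(-2 * nu * st$time)
  nx <- s$grid$nx
  sqrt(mean((st$u[1:nx, , ] - s$u0[1:nx, , ] * dec)^2))
}

# synthetic two-flap force/power series with exact per-cycle means,
# emulating the structure of the deposited flight-simulation series
# (period 138 ms, per-flap mean powers 1.00 / 1.10 W, mean Fz 0.525 N)
synthetic_s1_series <- function(period = 0.138, dt = 0.001,
                                p_means = c(1.00, 1.10), fz_mean = 0.525) {
  tt <- seq(0, 2 * period, by = dt)
  cyc <- pmin(floor(tt / period) + 1, 2)
  ph <- 2 * pi * (tt %% period) / period
  # harmonics integrate to zero over each complete cycle; the per-cycle mean
  # shift rides on (1 - cos), which vanishes at the cycle boundaries so the
  # series is continuous there
  dm <- p_means - mean(p_means)
  P <- mean(p_means) + dm[cyc] * (1 - cos(ph)) - 1.1 * cos(ph) +
    0.45 * sin(2 * ph)
  Fz <- fz_mean - 0.55 * cos(ph) + 0.2 * sin(2 * ph)
  Fx <- 0.005 - 0.1 * sin(ph)
  Fy <- -0.050 + 0.08 * sin(ph)
  tibble::tibble(time_s = tt, Fx_N = Fx, Fy_N = Fy, Fz_N = Fz, P_W = P)
}

# simple calibrated camera for undistortion/triangulation tests
toy_camera <- function(id = 1L, eye = c(0, -2, 0), target = c(0, 0, 0),
                       k = c(-0.2, 0.05)) {
  R <- flapwing:::look_at_rotation(eye, target)
  camera_model(id = id, fx = 900, fy = 880, cx = 640, cy = 360, k = k,
               R = R, t = -as.numeric(R %*% eye))
}
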