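icosphere <- function(r = 0.2, center = c(0, 0, 0), nsub = 8) {
  # UV sphere triangulation, adequate for classification tests
  th <- seq(0, pi, length.out = nsub + 1)
  ph <- seq(0, 2 * pi, length.out = 2 * nsub + 1)[-1]
  V <- rbind(c(0, 0, r), c(0, 0, -r))
  idx <- function(i, j) 2 + (i - 1) * length(ph) + j
  for (i in seq_len(nsub - 1)) {
    for (j in seq_along(ph)) {
      V <- rbind(V, r * c(sin(th[i + 1]) * cos(ph[j]),
                          sin(th[i + 1]) * sin(ph[j]), cos(th[i + 1])))
    }
  }
  Tr <- NULL
  np <- length(ph)
  for (j in seq_len(np)) {
    jn <- j %% np + 1
    Tr <- rbind(Tr, c(1, idx(1, j), idx(1, jn)),
                c(2, idx(nsub - 1, jn), idx(nsub - 1, j)))
  }
  for (i in seq_len(nsub - 2)) for (j in seq_len(np)) {
    jn <- j %% np + 1
    Tr <- rbind(Tr, c(idx(i, j), idx(i + 1, j), idx(i, jn)),
                c(idx(i, jn), idx(i + 1, j), idx(i + 1, jn)))
  }
  V <- sweep(V, 2, center, "+")
  immersed_surface(V, Tr)
}

test_that("IB nodes of a static plate at rest receive zero velocity", {
  g <- build_grid(c(-0.5, 0.5), c(0, 0.05), c(-0.5, 0.5),
                  spacing = c(x = 1 / 24, y = 0.05, z = 1 / 24),
                  growth = 1, periodic = c(FALSE, TRUE, FALSE))
  cfg <- solver_config(nu = 0.01, dt = 1e-3, bc = bc_tunnel(0))
  pl <- make_plate_x(g)
  ib <- build_ib_map(g, pl, cfg)
  expect_gt(length(ib$maps$u$node), 0)
  st <- flow_state(g)  # quiescent
  st2 <- apply_ib_velocity(st, ib)
  expect_identical(max(abs(st2$u)), 0)
})

test_that("IB node velocity approaches the wall velocity as distance shrinks", {
  g <- build_grid(c(-0.5, 0.5), c(0, 0.05), c(-0.5, 0.5),
                  spacing = c(x = 1 / 32, y = 0.05, z = 1 / 32),
                  growth = 1, periodic = c(FALSE, TRUE, FALSE))
  cfg <- solver_config(nu = 0.01, dt = 1e-3, bc = bc_tunnel(0))
  v_wall <- c(0.7, 0, 0)
  # plate slightly off the grid planes so IB nodes sit at varied distances
  pl <- make_plate_x(g, x0 = 0.011, velocity = v_wall)
  ib <- build_ib_map(g, pl, cfg)
  st <- flow_state(g)  # fluid at rest
  st2 <- apply_ib_velocity(st, ib)
  m <- ib$maps$u
  vals <- st2$u[m$node]
  # linear profile: u = v_wall * (1 - d/L); closest nodes closest to v_wall
  expect_equal(vals, v_wall[1] * (1 - m$dist / m$L), tolerance = 1e-12)
  near <- which(m$dist < 0.25 * min(g$dx))
  if (length(near)) expect_gt(min(vals[near]), 0.9 * v_wall[1])
})

test_that("sphere IB classification matches a brute-force signed-distance scan", {
  g <- build_grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5),
                  spacing = 1 / 16, growth = 1)
  cfg <- solver_config(nu = 0.01, dt = 1e-3, bc = bc_tunnel(0))
  sp <- icosphere(r = 0.27, nsub = 10)
  ib <- build_ib_map(g, sp, cfg)

  el <- sp$elements
  E <- cbind(el$centroid_x, el$centroid_y, el$centroid_z)
  N <- cbind(el$normal_x, el$normal_y, el$normal_z)
  A <- sp$vertices[sp$tri[, 1], ]; B <- sp$vertices[sp$tri[, 2], ]
  C <- sp$vertices[sp$tri[, 3], ]
  brute_count <- function(xs, ys, zs) {
    cnt <- 0L
    band_h <- function(n) sum(abs(n) * c(g$dx[1], g$dy[1], g$dz[1]))
    for (i in seq_along(xs)) for (j in seq_along(ys)) for (k in seq_along(zs)) {
      X <- c(xs[i], ys[j], zs[k])
      hit <- FALSE
      for (e in seq_len(nrow(E))) {
        d <- sum((X - A[e, ]) * N[e, ])
        if (abs(d) > cfg$ib_band * band_h(N[e, ])) next
        q <- X - A[e, ] - d * N[e, ]
        e1 <- B[e, ] - A[e, ]; e2 <- C[e, ] - A[e, ]
        d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
        dt <- d11 * d22 - d12^2
        al <- (d22 * sum(q * e1) - d12 * sum(q * e2)) / dt
        be <- (d11 * sum(q * e2) - d12 * sum(q * e1)) / dt
        if (al >= -0.25 && be >= -0.25 && al + be <= 1.25) { hit <- TRUE; break }
      }
      if (hit) cnt <- cnt + 1L
    }
    cnt
  }
  expect_identical(length(ib$maps$u$node), brute_count(g$xf, g$yc, g$zc))
  expect_identical(length(ib$maps$w$node), brute_count(g$xc, g$yc, g$zf))
})

test_that("restart reproduces an uninterrupted run bit-for-bit", {
  g <- build_grid(c(-0.5, 1), c(0, 0.05), c(-0.5, 0.5),
                  spacing = c(x = 1 / 20, y = 0.05, z = 1 / 20),
                  growth = 1, periodic = c(FALSE, TRUE, FALSE))
  cfg <- solver_config(nu = 0.01, dt = 5e-3, bc = bc_tunnel(1))
  pl <- make_plate_x(g)
  full <- run_simulation(g, cfg, n_steps = 10, surface = pl)
  part <- run_simulation(g, cfg, n_steps = 5, surface = pl)
  resumed <- run_simulation(g, cfg, n_steps = 5, surface = pl,
                            state = part$state)
  expect_equal(resumed$state$u, full$state$u, tolerance = 1e-12)
  expect_equal(resumed$state$p, full$state$p, tolerance = 1e-12)
  expect_identical(resumed$state$step, full$state$step)
})

test_that("a gently heaving plate produces near-zero cycle-mean streamwise force", {
  g <- build_grid(c(-0.6, 0.6), c(0, 0.06), c(-0.6, 0.6),
                  spacing = c(x = 1 / 24, y = 0.06, z = 1 / 24),
                  growth = 1, periodic = c(FALSE, TRUE, FALSE))
  cfg <- solver_config(nu = 0.02, dt = NULL, cfl = 0.3,
                       bc = bc_tunnel(c(0, 0, 0)))
  amp <- 0.04; om <- 2 * pi * 1.0
  surf_fn <- function(t, dt) {
    make_plate_z(g, z0 = amp * sin(om * t), nseg = 10,
                 velocity = c(0, 0, amp * om * cos(om * t)))
  }
  st <- flow_state(g)
  cfg$dt <- 2.5e-3
  n <- round(1 / cfg$dt)  # one full heave cycle
  res <- run_simulation(g, cfg, n_steps = n, surface = surf_fn, state = st,
                        loads_every = 4)
  expect_lt(abs(mean(res$series$Fx_N)), 0.02 * max(abs(res$series$Fz_N)))
})
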