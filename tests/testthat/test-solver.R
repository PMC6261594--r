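test_that("grid construction honors uniform and stretched requests", {
  g <- build_grid(c(0, 1), c(0, 1), c(0, 1), spacing = 0.1, growth = 1)
  expect_equal(g$dx, rep(0.1, 10), tolerance = 1e-12)
  expect_identical(g$n_cells, 1000L)

  # fine spacing of 0.020 chords puts 50 cells across one chord
  c_m <- 0.074
  g2 <- build_grid(c(0, 10 * c_m), c(0, 1), c(0, 1),
                   refined = list(x = c(4 * c_m, 6 * c_m)),
                   spacing = c(x = 0.020 * c_m, y = 1, z = 1), growth = 1.15)
  core <- g2$dx[abs(g2$dx - 0.020 * c_m) < 1e-12]
  expect_identical(length(core), 100L)  # 2 chords x 50 cells
  # smooth stretching outside the refined box
  ratios <- g2$dx[-1] / g2$dx[-length(g2$dx)]
  expect_lt(max(ratios), 1.151)

  # stretched cell count matches the geometric-series oracle
  h <- 0.02; gr <- 1.1; len <- 1 - 0.6
  m_oracle <- ceiling(log(1 + len * (gr - 1) / (h * gr)) / log(gr))
  g3 <- build_grid(c(0, 1), c(0, 1), c(0, 1),
                   refined = list(x = c(0, 0.6)),
                   spacing = c(x = h, y = 1, z = 1), growth = gr)
  expect_identical(g3$nx, as.integer(0.6 / h + m_oracle))
  expect_error(build_grid(c(0, 1), c(0, 1), c(0, 1), spacing = 0.1,
                          growth = 0.9), "growth")
})

test_that("a uniform free stream is an exact steady state of the tunnel", {
  g <- build_grid(c(0, 1), c(0, 0.5), c(0, 0.5), spacing = 0.1, growth = 1)
  cfg <- solver_config(nu = 1e-5, dt = 0.01, bc = bc_tunnel(1))
  st <- flow_state(g, c(1, 0, 0))
  for (i in 1:5) st <- step_flow(st, g, cfg)
  expect_lt(max(abs(st$u - 1)), 1e-12)
  expect_lt(max(abs(st$v)), 1e-12)
  expect_lt(st$max_div, 1e-12)
})

test_that("boundary conditions conserve global mass", {
  g <- build_grid(c(0, 1), c(0, 0.5), c(0, 0.5), spacing = 0.1, growth = 1)
  cfg <- solver_config(nu = 1e-5, dt = 0.01, bc = bc_tunnel(1))
  set.seed(8)
  st <- flow_state(g, c(1, 0, 0))
  st$u <- st$u + array(rnorm(length(st$u), sd = 0.2), dim(st$u))
  st$v <- st$v + array(rnorm(length(st$v), sd = 0.2), dim(st$v))
  st$w <- st$w + array(rnorm(length(st$w), sd = 0.2), dim(st$w))
  st <- apply_boundary_conditions(st, g, cfg)
  net <- flapwing:::boundary_net_flux(st$u, st$v, st$w, g)
  expect_lt(abs(net), 1e-12)
  # outlet carries exactly the inlet flux for a blocked-velocity test
  inflow <- sum(st$u[1, , ] * outer(g$dy, g$dz))
  outflow <- sum(st$u[g$nx + 1, , ] * outer(g$dy, g$dz))
  expect_equal(outflow, inflow, tolerance = 1e-12)
})

test_that("every step leaves the interior divergence-free to tolerance", {
  s <- tg_setup(16, nu = 0.02, dt = 2e-3)
  st <- s$state
  for (i in 1:20) {
    st <- step_flow(st, s$grid, s$cfg)
    expect_lt(st$max_div, 1e-10)
  }
})

test_that("kinetic energy decays monotonically in unforced periodic flow", {
  s <- tg_setup(16, nu = 0.02, dt = 2e-3)
  st <- s$state
  ke <- numeric(30)
  for (i in seq_along(ke)) {
    st <- step_flow(st, s$grid, s$cfg)
    ke[i] <- sum(st$u^2) + sum(st$w^2)
  }
  expect_true(all(diff(ke) < 0))
})

test_that("Poiseuille startup converges to the parabolic profile", {
  nu <- 0.1; G <- 1; H <- 1
  g <- build_grid(c(0, 1), c(0, 1), c(0, H),
                  spacing = c(x = 0.25, y = 1, z = H / 16),
                  periodic = c(TRUE, TRUE, FALSE))
  cfg <- solver_config(nu = nu, dt = 0.004, body_force = c(G, 0, 0),
                       bc = list(zlo = bc_noslip(), zhi = bc_noslip()))
  st <- flow_state(g)
  for (i in 1:4000) st <- step_flow(st, g, cfg)
  prof <- st$u[1, 1, ]
  exact <- G / (2 * nu) * g$zc * (H - g$zc)
  expect_lt(abs(max(prof) - G * H^2 / (8 * nu)) / (G * H^2 / (8 * nu)), 0.01)
  expect_lt(max(abs(prof - exact)) / max(exact), 0.01)
})

test_that("NaN injection is caught with a named field", {
  g <- build_grid(c(0, 1), c(0, 0.5), c(0, 0.5), spacing = 0.25, growth = 1)
  cfg <- solver_config(nu = 1e-5, dt = 1e5, bc = bc_tunnel(100))
  st <- flow_state(g, c(100, 0, 0))
  st$u[3, 1, 1] <- NA
  expect_error(step_flow(st, g, cfg), "field 'u'")
})
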