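# hand-built loads for a toy thin surface
toy_loads <- function(n = 10, p_top = NULL, p_bot = NULL, tau = 0,
                      vel = c(0, 0, 0), normal = c(0, 0, 1), area = 0.001,
                      time = 0) {
  if (is.null(p_top)) p_top <- rep(0, n)
  if (is.null(p_bot)) p_bot <- rep(0, n)
  one_side <- function(s, p) {
    tibble::tibble(element = seq_len(n), side = s,
                   n_x = s * normal[1], n_y = s * normal[2],
                   n_z = s * normal[3],
                   p_Pa = p, tau_x = tau, tau_y = tau, tau_z = tau,
                   area_m2 = area, region = "surface",
                   vel_x = vel[1], vel_y = vel[2], vel_z = vel[3])
  }
  loads <- dplyr::bind_rows(one_side(1, p_top), one_side(-1, p_bot))
  attr(loads, "time") <- time
  class(loads) <- c("surface_loads", class(loads))
  loads
}

test_that("force integration obeys pressure-difference identities", {
  # equal pressure on both sides cancels exactly
  l0 <- toy_loads(n = 7, p_top = rep(3.3, 7), p_bot = rep(3.3, 7))
  expect_equal(unname(integrate_forces(l0)$force), c(0, 0, 0),
               tolerance = 1e-15)
  # flat horizontal plate, dp = 10 Pa over 0.01 m^2 -> 0.1 N up
  n <- 10
  l1 <- toy_loads(n = n, p_top = rep(-5, n), p_bot = rep(5, n),
                  area = 0.01 / n)
  expect_equal(unname(integrate_forces(l1)$force), c(0, 0, 0.1),
               tolerance = 1e-12)
  # missing side is an error naming the element
  broken <- l1[l1$side == 1 | l1$element != 4, ]
  expect_error(integrate_forces(broken), "element 4")
})

test_that("random toy loads match an element-by-element summation oracle", {
  set.seed(12)
  n <- 10
  loads <- toy_loads(n)
  loads$p_Pa <- rnorm(2 * n)
  loads$tau_x <- rnorm(2 * n); loads$tau_y <- rnorm(2 * n)
  loads$tau_z <- rnorm(2 * n)
  loads$area_m2 <- runif(2 * n, 1e-4, 1e-3)
  fr <- integrate_forces(loads)
  oracle <- c(0, 0, 0)
  for (r in seq_len(nrow(loads))) {
    nvec <- c(loads$n_x[r], loads$n_y[r], loads$n_z[r])
    tvec <- c(loads$tau_x[r], loads$tau_y[r], loads$tau_z[r])
    oracle <- oracle + (tvec - loads$p_Pa[r] * nvec) * loads$area_m2[r]
  }
  expect_equal(unname(fr$force), oracle, tolerance = 1e-14)
  # region breakdown sums to the total
  expect_equal(sum(fr$by_region$Fz_N), unname(fr$force[3]), tolerance = 1e-14)
})

test_that("the lift coefficient normalization is the textbook identity", {
  pars <- flight_params()
  ref <- 0.5 * pars$rho * pars$U_inf^2 * pars$S_ref
  expect_equal(lift_coefficient(ref, pars), 1, tolerance = 1e-14)
  expect_identical(lift_coefficient(0, pars), 0)
  expect_equal(lift_coefficient(0.525, pars, S_max = 0.04),
               0.525 / (0.5 * pars$rho * pars$U_inf^2 * 0.04),
               tolerance = 1e-14)
})

test_that("aerodynamic power follows the rigid-motion sign convention", {
  n <- 6
  # static surface: no power
  l0 <- toy_loads(n, p_top = rnorm(n), p_bot = rnorm(n))
  expect_identical(aerodynamic_power(l0), 0)
  # plate moving down at 1 m/s carrying +1 N net upward force: P = +1 W
  l1 <- toy_loads(n, p_top = rep(-50, n), p_bot = rep(50, n),
                  area = 0.01 / n, vel = c(0, 0, -1))
  expect_equal(aerodynamic_power(l1), 1, tolerance = 1e-12)
  # energy consistency: P = -(F . v) for any rigid motion, to round-off
  set.seed(4)
  v <- c(0.3, -1.2, 0.8)
  lr <- toy_loads(n, p_top = rnorm(n, sd = 20), p_bot = rnorm(n, sd = 20),
                  vel = v)
  lr$tau_x <- rnorm(2 * n); lr$tau_y <- rnorm(2 * n); lr$tau_z <- rnorm(2 * n)
  F <- integrate_forces(lr)$force
  P <- aerodynamic_power(lr)
  expect_equal(P, -sum(F * v), tolerance = 1e-12)
  # per-element brute-force oracle for a deforming surface
  lr$vel_x <- rnorm(2 * n); lr$vel_y <- rnorm(2 * n); lr$vel_z <- rnorm(2 * n)
  oracle <- 0
  for (r in seq_len(nrow(lr))) {
    nvec <- c(lr$n_x[r], lr$n_y[r], lr$n_z[r])
    tvec <- c(lr$tau_x[r], lr$tau_y[r], lr$tau_z[r])
    vvec <- c(lr$vel_x[r], lr$vel_y[r], lr$vel_z[r])
    oracle <- oracle + sum((lr$p_Pa[r] * nvec - tvec) * vvec) * lr$area_m2[r]
  }
  expect_equal(aerodynamic_power(lr), oracle, tolerance = 1e-14)
  # time mismatch with a surface is rejected
  s <- make_plate_z(build_grid(c(-1, 1), c(0, 0.05), c(-1, 1),
                               spacing = c(x = 0.1, y = 0.05, z = 0.1),
                               growth = 1, periodic = c(FALSE, TRUE, FALSE)))
  s$time <- 0.5
  expect_error(aerodynamic_power(l0, s), "different times")
})

test_that("cycle averages reproduce closed-form means", {
  t <- seq(0, 1, by = 0.005)
  const <- tibble::tibble(time_s = t, Fx_N = 2, Fy_N = -1, Fz_N = 0.5,
                          P_W = 3)
  cyc <- tibble::tibble(start_s = c(0, 0.5), end_s = c(0.5, 1),
                        period_s = 0.5)
  cs <- cycle_average(const, cyc)
  expect_equal(cs$overall$P_W, 3, tolerance = 1e-12)
  expect_equal(cs$per_cycle$Fz_N, c(0.5, 0.5), tolerance = 1e-12)
  # pure sinusoid over integer periods averages to zero
  sine <- tibble::tibble(time_s = t, Fx_N = sin(2 * pi * 2 * t),
                         Fy_N = 0, Fz_N = 0, P_W = cos(2 * pi * 2 * t))
  cs2 <- cycle_average(sine, tibble::tibble(start_s = 0, end_s = 1,
                                            period_s = 1))
  expect_lt(abs(cs2$overall$Fx_N), 1e-12)
  expect_lt(abs(cs2$overall$P_W), 1e-12)
  # two equal-duration cycles with means 1.00 and 1.10 average to 1.05
  two <- synthetic_s1_series()
  cyc2 <- cycles_from_period(two, 0.138)
  cs3 <- cycle_average(two, cyc2)
  expect_equal(cs3$per_cycle$P_W, c(1.00, 1.10), tolerance = 1e-6)
  expect_equal(cs3$overall$P_W, 1.05, tolerance = 1e-6)
  expect_error(cycle_average(const, cyc[0, ]), "empty cycle")
})

test_that("cycle means are invariant to uniform resampling", {
  s <- synthetic_s1_series(dt = 0.001)
  cyc <- cycles_from_period(s, 0.138)
  coarse <- s[seq(1, nrow(s), by = 3), ]
  m1 <- cycle_average(s, cyc)$overall$P_W
  m2 <- cycle_average(coarse, cyc)$overall$P_W
  expect_equal(m1, m2, tolerance = 1e-3)
})

test_that("autocorrelation period estimation finds the flap period", {
  s <- synthetic_s1_series(period = 0.138)
  per <- estimate_flap_period(s, nominal_period_s = 0.138)
  expect_lt(abs(per - 0.138), 0.002)
  # robust to a biased seed
  per2 <- estimate_flap_period(s, nominal_period_s = 0.150)
  expect_lt(abs(per2 - 0.138), 0.002)
})
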