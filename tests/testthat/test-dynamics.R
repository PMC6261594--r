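const_series <- function(F, t_end = 1, dt = 0.01) {
  t <- seq(0, t_end, by = dt)
  tibble::tibble(time_s = t, Fx_N = F[1], Fy_N = F[2], Fz_N = F[3], P_W = 0)
}

test_that("equilibrium hover stays fixed to round-off", {
  M <- 0.055; g <- 9.81
  s <- const_series(c(0, 0, M * g))
  tr <- predict_trajectory(s, M = M, g = g, x0 = c(1, 2, 3))
  expect_lt(max(abs(tr$x_m - 1)), 1e-14)
  expect_lt(max(abs(tr$z_m - 3)), 1e-14)
  expect_lt(max(abs(tr$vz_m_s)), 1e-14)
})

test_that("free fall matches the closed form", {
  M <- 0.055
  s <- const_series(c(0, 0, 0))
  tr <- predict_trajectory(s, M = M, g = 9.81, x0 = c(0, 0, 10))
  expect_equal(tr$z_m, 10 - 0.5 * 9.81 * tr$time_s^2, tolerance = 1e-12)
})

test_that("constant net force reproduces x = F t^2 / (2 M) to 1e-10", {
  M <- 0.5; F <- c(0.7, -0.2, 0.4 + M * 9.81)
  s <- const_series(F)
  tr <- predict_trajectory(s, M = M, g = 9.81)
  T <- max(tr$time_s)
  xf <- c(tail(tr$x_m, 1), tail(tr$y_m, 1), tail(tr$z_m, 1))
  expect_equal(xf, (F / M - c(0, 0, 9.81)) * T^2 / 2, tolerance = 1e-10)
  # interval outside the series is rejected
  expect_error(predict_trajectory(s, M = M, t_range = c(0, 2)),
               "outside the force series")
})

test_that("RK4 shows fourth-order endpoint convergence on smooth forcing", {
  M <- 0.1
  t <- seq(0, 1, by = 1e-4)
  s <- tibble::tibble(time_s = t, Fx_N = sin(2 * pi * t),
                      Fy_N = 0, Fz_N = M * 9.81, P_W = 0)
  # closed form for this forcing: x(1) = 1 / (2 pi M) from rest
  x_exact <- 1 / (2 * pi * M)
  e <- vapply(c(1 / 8, 1 / 16), function(h) {
    tr <- predict_trajectory(s, M = M, dt = h)
    abs(tail(tr$x_m, 1) - x_exact)
  }, numeric(1))
  # coarse steps keep the RK4 truncation error far above the force-table
  # interpolation floor; halving the step cuts the error ~16x
  expect_lt(e[2], e[1] / 12)
})

test_that("trajectory comparison recovers known offsets", {
  t <- seq(0, 1, by = 0.02)
  pred <- tibble::tibble(time_s = t, x_m = t^2, y_m = sin(t), z_m = cos(t),
                         vx_m_s = 2 * t, vy_m_s = cos(t), vz_m_s = -sin(t))
  same <- compare_trajectory(pred, pred)
  expect_equal(unname(same$rms_m), c(0, 0, 0), tolerance = 1e-12)
  obs <- pred
  obs$x_m <- obs$x_m - 0.15
  cmp <- compare_trajectory(pred, obs)
  expect_equal(unname(cmp$final_offset_m[1]), 0.15, tolerance = 1e-9)
  expect_equal(unname(cmp$rms_m[1]), 0.15, tolerance = 1e-9)
  # hand-computed RMS for an analytic pair
  obs2 <- pred
  obs2$z_m <- obs2$z_m + 0.01 * t
  cmp2 <- compare_trajectory(pred, obs2)
  expect_equal(unname(cmp2$rms_m[3]), sqrt(mean((0.01 * t)^2)),
               tolerance = 1e-6)
  expect_error(compare_trajectory(pred, obs[1, ]), "overlapping")
})
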