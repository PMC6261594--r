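square_traj <- function() {
  tibble::tibble(frame = 1L, time_s = 0, marker_id = 1:4, region = "body",
                 x_m = c(0, 1, 0, 1), y_m = c(0, 0, 1, 1), z_m = 0,
                 valid = TRUE)
}

test_that("Delaunay control meshing handles canonical configurations", {
  m <- build_control_mesh(square_traj(), reference_frame = 1L)
  expect_identical(nrow(m$tri), 2L)
  areas <- vapply(seq_len(2), function(i) {
    P <- m$ref_positions[m$tri[i, ], ]
    norm(flapwing:::cross3(rbind(P[2, ] - P[1, ]), rbind(P[3, ] - P[1, ])),
         "2") / 2
  }, numeric(1))
  expect_equal(sum(areas), 1, tolerance = 1e-12)

  # regular n-gon plus center -> n triangles
  n <- 9
  ang <- 2 * pi * (0:(n - 1)) / n
  tr <- tibble::tibble(frame = 1L, time_s = 0, marker_id = 1:(n + 1),
                       region = "body",
                       x_m = c(cos(ang), 0), y_m = c(sin(ang), 0), z_m = 0,
                       valid = TRUE)
  m2 <- build_control_mesh(tr, reference_frame = 1L)
  expect_identical(nrow(m2$tri), as.integer(n))

  # a regular grid triangulates into 2 * (rows-1) * (cols-1) triangles
  g <- expand.grid(x = seq(0, 0.1, by = 0.02), y = seq(0, 0.08, by = 0.02))
  trg <- tibble::tibble(frame = 1L, time_s = 0, marker_id = seq_len(nrow(g)),
                        region = "body", x_m = g$x, y_m = g$y, z_m = 0,
                        valid = TRUE)
  mg <- build_control_mesh(trg, reference_frame = 1L)
  expect_identical(nrow(mg$tri), as.integer(2 * 5 * 4))

  # collinear markers cannot be triangulated
  bad <- tibble::tibble(frame = 1L, time_s = 0, marker_id = 1:5,
                        region = "body", x_m = 1:5, y_m = 2 * (1:5),
                        z_m = 3 * (1:5), valid = TRUE)
  expect_error(build_control_mesh(bad, reference_frame = 1L), "collinear")
})

test_that("refinement at k = 1 and k = 2 produces the documented barycentric layout", {
  m <- build_control_mesh(square_traj(), reference_frame = 1L)
  f1 <- refine_mesh(m, k = 1)
  expect_identical(nrow(f1$tri), nrow(m$tri))
  expect_setequal(round(f1$alpha + f1$beta, 12), c(0, 1))
  f2 <- refine_mesh(m, k = 2)
  expect_identical(nrow(f2$tri), 4L * nrow(m$tri))
  expect_true(any(f2$alpha == 0.5 & f2$beta == 0))
})

test_that("the fine mesh is watertight and area-exact at every k", {
  p <- wing_motion_params(n_frames = 6)
  tr <- generate_wing_motion(p)
  m <- build_control_mesh(tr)
  ctrl_area <- sum(vapply(seq_len(nrow(m$tri)), function(i) {
    P <- m$ref_positions[m$tri[i, ], ]
    norm(flapwing:::cross3(rbind(P[2, ] - P[1, ]), rbind(P[3, ] - P[1, ])),
         "2") / 2
  }, numeric(1)))
  for (k in c(1, 3)) {
    f <- refine_mesh(m, k = k)
    e <- rbind(f$tri[, c(1, 2)], f$tri[, c(2, 3)], f$tri[, c(1, 3)])
    ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    counts <- table(table(ek))
    expect_true(all(names(counts) %in% c("1", "2")))
    V <- flapwing:::fine_vertex_positions(f, m$ref_positions)
    a <- V[f$tri[, 1], ]; b <- V[f$tri[, 2], ]; cc <- V[f$tri[, 3], ]
    fine_area <- sum(flapwing:::row_norms(flapwing:::cross3(b - a, cc - a))) / 2
    expect_equal(fine_area, ctrl_area, tolerance = 1e-12)
  }
})

test_that("a paper-scale 182-triangle control mesh refines to ~42,839 elements", {
  # 8 x 14 grid of 2 cm spacing: 182 Delaunay triangles, the production
  # control-mesh size; target edge = the fine fluid spacing 0.020 chords
  g <- expand.grid(x = seq(0, 0.26, by = 0.02), y = seq(0, 0.14, by = 0.02))
  tr <- tibble::tibble(frame = 1L, time_s = 0, marker_id = seq_len(nrow(g)),
                       region = "right_inner", x_m = g$x, y_m = g$y, z_m = 0,
                       valid = TRUE)
  m <- build_control_mesh(tr, reference_frame = 1L)
  expect_identical(nrow(m$tri), 182L)
  f <- refine_mesh(m, target_edge = 0.020 * 0.074)
  expect_lt(abs(nrow(f$tri) - 42839) / 42839, 0.20)
})

test_that("spline kinematics interpolate samples exactly and move fine vertices affinely", {
  p <- wing_motion_params(n_frames = 10)
  tr <- generate_wing_motion(p)
  m <- build_control_mesh(tr)
  spl <- spline_kinematics(tr, m)
  # reproduces the samples
  t3 <- tr$time_s[tr$frame == 3][1]
  pos <- flapwing:::control_positions(spl, t3)
  ref <- tr[tr$frame == 3, ]
  ref <- ref[match(m$control_ids, ref$marker_id), ]
  expect_lt(max(abs(pos - cbind(ref$x_m, ref$y_m, ref$z_m))), 1e-12)

  # barycentric placement: alpha = beta = 0 vertices ride on control point 1
  f <- refine_mesh(m, k = 2)
  V <- flapwing:::fine_vertex_positions(f, pos)
  at_origin <- which(f$alpha == 0 & f$beta == 0)
  own <- f$control$tri[f$owner[at_origin], 1]
  expect_lt(max(abs(V[at_origin, ] - pos[own, ])), 1e-12)

  # rigid translation of control points translates every fine vertex
  d <- c(0.1, -0.2, 0.05)
  V2 <- flapwing:::fine_vertex_positions(f, sweep(pos, 2, -d))
  expect_equal(V2, sweep(V, 2, -d), tolerance = 1e-12)
})

test_that("backward-difference surface velocity is exact for linear motion", {
  # control points translating at constant velocity v
  v <- c(0.3, -0.1, 0.2)
  base <- square_traj()
  frames <- purrr::map(1:8, function(k) {
    out <- base
    out$frame <- as.integer(k)
    out$time_s <- (k - 1) / 100
    out$x_m <- out$x_m + v[1] * out$time_s
    out$y_m <- out$y_m + v[2] * out$time_s
    out$z_m <- out$z_m + v[3] * out$time_s
    out
  })
  tr <- dplyr::bind_rows(frames)
  m <- build_control_mesh(tr, reference_frame = 1L)
  spl <- spline_kinematics(tr, m)
  f <- refine_mesh(m, k = 2)
  s <- evaluate_surface(spl, f, t = 0.05, dt_history = 0.004)
  expect_equal(unname(colMeans(cbind(s$elements$vel_x, s$elements$vel_y,
                                     s$elements$vel_z))), v,
               tolerance = 1e-9)
  expect_lt(max(abs(cbind(s$elements$acc_x, s$elements$acc_y,
                          s$elements$acc_z))), 1e-6)
  expect_error(evaluate_surface(spl, f, t = 0.2, dt_history = 0.004),
               "outside the spline interval")
})

test_that("planform area projects correctly for tilted rectangles", {
  b <- 0.5; ch <- 0.2
  V <- rbind(c(0, 0, 0), c(ch, 0, 0), c(0, b, 0), c(ch, b, 0))
  s <- immersed_surface(V, rbind(c(1, 2, 3), c(3, 2, 4)))
  expect_equal(planform_area(s), b * ch, tolerance = 1e-12)
  roll <- pi / 3
  Vr <- V %*% t(rbind(c(1, 0, 0), c(0, cos(roll), -sin(roll)),
                      c(0, sin(roll), cos(roll))))
  s60 <- immersed_surface(Vr, rbind(c(1, 2, 3), c(3, 2, 4)))
  expect_equal(planform_area(s60), b * ch * cos(roll), tolerance = 1e-12)
})
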