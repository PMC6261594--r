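test_that("undistortion is exact for zero distortion and at the principal point", {
  cam0 <- toy_camera(k = c(0, 0))
  obs <- tibble::tibble(u_px = c(100, 640, 900), v_px = c(50, 360, 700))
  un <- undistort(obs, cam0)
  expect_equal(un$xn, (obs$u_px - cam0$cx) / cam0$fx, tolerance = 1e-14)
  expect_true(all(un$undistort_ok))
  camd <- toy_camera(k = c(-0.3, 0.08))
  pp <- undistort(tibble::tibble(u_px = camd$cx, v_px = camd$cy), camd)
  expect_identical(c(pp$xn, pp$yn), c(0, 0))
})

test_that("distort-then-undistort round trip is identity to 1e-8", {
  cam <- toy_camera(k = c(-0.25, 0.07))
  set.seed(42)
  xn <- runif(200, -0.4, 0.4)
  yn <- runif(200, -0.3, 0.3)
  d <- flapwing:::distortion_factor(xn^2 + yn^2, cam$k)
  obs <- tibble::tibble(u_px = cam$fx * xn * d + cam$cx,
                        v_px = cam$fy * yn * d + cam$cy)
  un <- undistort(obs, cam)
  expect_lt(max(abs(un$xn - xn)), 1e-8)
  expect_lt(max(abs(un$yn - yn)), 1e-8)
})

test_that("pair triangulation recovers noise-free points and flags degeneracy", {
  cams <- list(toy_camera(1L, eye = c(-1.5, -1.5, 0.3)),
               toy_camera(2L, eye = c(1.5, -1.5, -0.2)))
  set.seed(3)
  X <- cbind(runif(50, -0.3, 0.3), runif(50, -0.3, 0.3), runif(50, -0.3, 0.3))
  truth <- tibble::tibble(frame = 1L, time_s = 0, marker_id = seq_len(50),
                          region = "body", x_m = X[, 1], y_m = X[, 2],
                          z_m = X[, 3], valid = TRUE)
  obs <- project_to_cameras(truth, cams, seed = 1)
  oa <- obs[obs$camera_id == 1, ]; ob <- obs[obs$camera_id == 2, ]
  tr <- triangulate_pair(oa, ob, cams[[1]], cams[[2]])
  m <- match(tr$marker_id, truth$marker_id)
  err <- sqrt((tr$x_m - truth$x_m[m])^2 + (tr$y_m - truth$y_m[m])^2 +
                (tr$z_m - truth$z_m[m])^2)
  expect_lt(max(err), 1e-9)
  expect_lt(max(tr$residual_px), 1e-6)
  # identical camera centers: no parallax
  expect_error(triangulate_pair(oa, ob, cams[[1]], cams[[1]]), "degenerate")
})

test_that("1 px noise at tunnel scale keeps median pair error below a pinned bound", {
  cams <- list(toy_camera(1L, eye = c(-1.5, -1.5, 0.3)),
               toy_camera(2L, eye = c(1.5, -1.5, -0.2)))
  set.seed(9)
  X <- cbind(runif(300, -0.3, 0.3), runif(300, -0.3, 0.3), runif(300, -0.3, 0.3))
  truth <- tibble::tibble(frame = 1L, time_s = 0, marker_id = seq_len(300),
                          region = "body", x_m = X[, 1], y_m = X[, 2],
                          z_m = X[, 3], valid = TRUE)
  obs <- project_to_cameras(truth, cams, pixel_noise_sd = 1, seed = 5)
  tr <- triangulate_pair(obs[obs$camera_id == 1, ], obs[obs$camera_id == 2, ],
                         cams[[1]], cams[[2]])
  m <- match(tr$marker_id, truth$marker_id)
  err <- sqrt((tr$x_m - truth$x_m[m])^2 + (tr$y_m - truth$y_m[m])^2 +
                (tr$z_m - truth$z_m[m])^2)
  # regression pin: two ~900 px cameras 2.3 m away, 1 px noise ~ few mm
  expect_lt(median(err), 5e-3)
})

test_that("median fusion is robust and exact on clean candidates", {
  expect_equal(fuse_multiview(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  cand <- rbind(c(0, 0, 0), c(0, 0, 0), c(9, 9, 9))
  expect_equal(fuse_multiview(cand), c(0, 0, 0))
})

test_that("fusing all camera pairs of a noise-free scene recovers truth", {
  p <- wing_motion_params(n_frames = 4)
  sc <- synthetic_scene(p, pixel_noise_sd = 0, occlusion_rate = 0)
  rec <- reconstruct_markers(sc$observations, sc$cameras,
                             frame_rate = p$frame_rate)
  m <- dplyr::inner_join(sc$truth, rec, by = c("frame", "marker_id"),
                         suffix = c("", ".r"))
  expect_true(all(m$valid.r))
  err <- sqrt((m$x_m - m$x_m.r)^2 + (m$y_m - m$y_m.r)^2 + (m$z_m - m$z_m.r)^2)
  expect_lt(max(err), 1e-6)
})

test_that("fusion error does not grow as more cameras observe", {
  p <- wing_motion_params(n_frames = 4)
  truth <- generate_wing_motion(p)
  cams <- camera_ring_array()
  errs <- vapply(c(2, 4, 8), function(ncam) {
    obs <- project_to_cameras(truth, cams[seq_len(ncam)],
                              pixel_noise_sd = 1, seed = 21)
    rec <- reconstruct_markers(obs, cams[seq_len(ncam)],
                               frame_rate = p$frame_rate)
    m <- dplyr::inner_join(truth, rec[rec$valid, ],
                           by = c("frame", "marker_id"), suffix = c("", ".r"))
    median(sqrt((m$x_m - m$x_m.r)^2 + (m$y_m - m$y_m.r)^2 +
                  (m$z_m - m$z_m.r)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
})

test_that("pca_clean flags an injected spike, fills it, and touches nothing else", {
  p <- wing_motion_params(n_frames = 24)
  tr <- generate_wing_motion(p)
  spiked <- tr
  i <- which(spiked$marker_id == 5 & spiked$frame == 11)
  spiked$z_m[i] <- spiked$z_m[i] + 0.10
  cleaned <- pca_clean(spiked)
  rep <- attr(cleaned, "cleaning_report")
  expect_true(any(rep$marker_id == 5 & rep$frame == 11))
  # only the spiked marker is modified
  expect_true(all(rep$marker_id == 5))
  other <- cleaned$marker_id != 5
  expect_identical(cleaned$z_m[other], spiked$z_m[other])
  # the infilled value lands near the true motion
  j <- which(cleaned$marker_id == 5 & cleaned$frame == 11)
  expect_lt(abs(cleaned$z_m[j] - tr$z_m[i]), 5e-3)
})

test_that("pca_clean leaves exactly low-rank records untouched", {
  p <- wing_motion_params(n_frames = 16, area_modulation_fraction = 0,
                          pitch_amplitude = 0)
  tr <- generate_wing_motion(p)
  out <- pca_clean(tr)
  expect_identical(out$x_m, tr$x_m)
  expect_identical(nrow(attr(out, "cleaning_report")), 0L)
  # full-rank projection cannot flag anything either
  out2 <- pca_clean(tr, variance_fraction = 1)
  expect_identical(nrow(attr(out2, "cleaning_report")), 0L)
})

test_that("markers with too few valid frames are reported, not invented", {
  p <- wing_motion_params(n_frames = 12)
  tr <- generate_wing_motion(p)
  tr$valid[tr$marker_id == 3 & tr$frame > 2] <- FALSE
  out <- pca_clean(tr)
  rep <- attr(out, "cleaning_report")
  expect_true(any(rep$marker_id == 3 & rep$action == "too_few_valid_frames"))
  expect_false(any(out$valid[out$marker_id == 3 & out$frame > 2]))
})
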