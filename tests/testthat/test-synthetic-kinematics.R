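test_that("wingtip vertical excursion matches the configured plunge amplitude", {
  p <- wing_motion_params()
  tr <- generate_wing_motion(p)
  ref <- tr[tr$frame == 1 & startsWith(tr$region, "right"), ]
  tip <- ref$marker_id[which.max(abs(ref$y_m))]
  zz <- tr$z_m[tr$marker_id == tip]
  # 52 frames at 120 fps discretize the flap; peaks are interior samples
  expect_equal(max(zz) - min(zz), 2 * p$plunge_amplitude, tolerance = 0.01)
})

test_that("zero modulation and zero pitch leave the material wing area constant", {
  p <- wing_motion_params(area_modulation_fraction = 0, pitch_amplitude = 0,
                          n_frames = 12)
  tr <- generate_wing_motion(p)
  mesh <- build_control_mesh(tr)
  # rigid flapping: the 3D (material) surface area never changes
  area3d <- vapply(sort(unique(tr$frame)), function(fr) {
    sub <- tr[tr$frame == fr, ]
    P <- as.matrix(sub[match(mesh$control_ids, sub$marker_id),
                       c("x_m", "y_m", "z_m")])
    sum(flapwing:::row_norms(flapwing:::cross3(
      P[mesh$tri[, 2], ] - P[mesh$tri[, 1], ],
      P[mesh$tri[, 3], ] - P[mesh$tri[, 1], ]))) / 2
  }, numeric(1))
  expect_lt(max(area3d) - min(area3d), 1e-10 * max(area3d))
  # and the projected planform's shape in time follows the closed-form tilt
  # factor (absolute scale differs slightly: discrete markers vs idealized
  # trapezoid)
  am <- analytic_motion_metrics(p)
  areas <- planform_area_series(tr, mesh)
  wing <- grepl("inner|outer", areas$region)
  wa <- areas[wing, ] |>
    dplyr::group_by(frame, time_s) |>
    dplyr::summarise(a = sum(area_m2), .groups = "drop")
  truth <- am$wing_area_fun(wa$time_s)
  expect_equal(wa$a / mean(wa$a), truth / mean(truth), tolerance = 0.01)
})

test_that("a 1 Hz flap sampled past two crests shows exactly two interior tip maxima", {
  # the closed-form motion starts at a crest (downstroke start), so crests
  # sit at integer seconds; a 2.3 s record holds exactly two interior ones
  p <- wing_motion_params(flap_frequency = 1, frame_rate = 100,
                          n_frames = 231, forward_speed_start = 1,
                          forward_speed_end = 1)
  tr <- generate_wing_motion(p)
  ref <- tr[tr$frame == 1 & startsWith(tr$region, "right"), ]
  tip <- ref$marker_id[which.max(abs(ref$y_m))]
  tp <- tr[tr$marker_id == tip, ]
  pk <- flapwing:::interp_extrema(tp$time_s, tp$z_m, "max")
  expect_identical(nrow(pk), 2L)
  expect_equal(diff(pk$t), 1, tolerance = 1e-3)
})

test_that("generation is byte-identical under the same seed", {
  p <- wing_motion_params(n_frames = 8)
  expect_identical(generate_wing_motion(p), generate_wing_motion(p))
  sc1 <- synthetic_scene(p, pixel_noise_sd = 0.5, occlusion_rate = 0.05,
                         seed = 11)
  sc2 <- synthetic_scene(p, pixel_noise_sd = 0.5, occlusion_rate = 0.05,
                         seed = 11)
  expect_identical(sc1$observations, sc2$observations)
})

test_that("non-physical plunge amplitudes are rejected", {
  expect_error(wing_motion_params(plunge_amplitude = 0.3, span_max = 0.52),
               "fold over")
  expect_error(wing_motion_params(area_modulation_fraction = 1), "area_modulation")
  expect_error(wing_motion_params(n_frames = 3), "n_frames")
})

test_that("analytic St matches the metrics pipeline on noiseless markers", {
  p <- wing_motion_params(forward_speed_start = 2.57, forward_speed_end = 2.57)
  tr <- generate_wing_motion(p)
  am <- analytic_motion_metrics(p)
  met <- kinematic_metrics(tr, flight_params())
  expect_lt(abs(met$strouhal - am$strouhal) / am$strouhal, 0.01)
})

test_that("area modulation amplitude is recovered from noiseless meshes", {
  p <- wing_motion_params()
  tr <- generate_wing_motion(p)
  areas <- planform_area_series(tr)
  wing <- grepl("inner|outer", areas$region)
  wa <- areas[wing, ] |>
    dplyr::group_by(frame) |>
    dplyr::summarise(a = sum(area_m2))
  r <- max(wa$a) / min(wa$a)
  a_rec <- (r - 1) / (r + 1)
  expect_lt(abs(a_rec - p$area_modulation_fraction) /
              p$area_modulation_fraction, 0.02)
})

test_that("projection honors noise, occlusion and visibility geometry", {
  p <- wing_motion_params(n_frames = 6)
  tr <- generate_wing_motion(p)
  cams <- camera_ring_array()
  clean <- project_to_cameras(tr, cams, pixel_noise_sd = 0,
                              occlusion_rate = 0, seed = 1)
  # occlusion thins observations binomially
  occ <- project_to_cameras(tr, cams, pixel_noise_sd = 0,
                            occlusion_rate = 0.9, seed = 2)
  frac <- nrow(occ) / nrow(clean)
  se <- sqrt(0.9 * 0.1 / nrow(clean))
  expect_lt(abs(frac - 0.1), 5 * se)
  # a marker on the optical axis projects to the principal point
  cam <- toy_camera()
  eye <- flapwing:::camera_center(cam)
  axis_pt <- tibble::tibble(frame = 1L, time_s = 0, marker_id = 1L,
                            region = "body",
                            x_m = 0, y_m = 0, z_m = 0, valid = TRUE)
  ob <- project_to_cameras(axis_pt, list(cam), seed = 1)
  expect_equal(unname(ob$u_px), cam$cx, tolerance = 1e-9)
  expect_equal(unname(ob$v_px), cam$cy, tolerance = 1e-9)
})
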