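#' Pinhole camera model with radial distortion
#'
#' A calibrated camera: intrinsics (focal lengths and principal point in
#' pixels), polynomial radial distortion on the normalized image radius, and
#' extrinsics mapping world to camera coordinates as `X_cam = R %*% X + t`.
#'
#' @param id Camera identifier (integer or string).
#' @param fx,fy Focal lengths (px).
#' @param cx,cy Principal point (px).
#' @param k Numeric vector of radial distortion coefficients (k1, k2, ...);
#'   the distortion factor is `1 + k1 r^2 + k2 r^4 + ...` on the normalized
#'   radius r.
#' @param R 3x3 rotation matrix (orthonormal, det +1), world to camera.
#' @param t Length-3 translation (m), world to camera.
#' @param width,height Sensor size (px), used for visibility checks.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(id, fx, fy, cx, cy, k = c(0, 0), R = diag(3),
                         t = c(0, 0, 0), width = 1280, height = 720) {
  fw_assert(fx > 0 && fy > 0, "focal lengths must be positive")
  R <- as.matrix(R)
  fw_assert(all(dim(R) == c(3, 3)) &&
              max(abs(crossprod(R) - diag(3))) < 1e-8 &&
              abs(det(R) - 1) < 1e-8,
            "R must be orthonormal with determinant +1")
  structure(list(id = id, fx = fx, fy = fy, cx = cx, cy = cy,
                 k = as.numeric(k), R = R, t = as.numeric(t),
                 width = width, height = height),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model %s> f = (%.4g, %.4g) px, pp = (%.4g, %.4g), k = [%s]\n",
              x$id, x$fx, x$fy, x$cx, x$cy, paste(signif(x$k, 3), collapse = ", ")))
  invisible(x)
}

# camera center in world coordinates
camera_center <- function(cam) as.numeric(-crossprod(cam$R, cam$t))

# look-at rotation: camera +z axis points from eye to target, +x roughly
# along world up x cross; world -> camera rows
look_at_rotation <- function(eye, target, up = c(0, 0, 1)) {
  z <- target - eye
  z <- z / sqrt(sum(z^2))
  if (abs(sum(z * up)) > 0.99) up <- c(0, 1, 0)
  x <- c(z[2] * up[3] - z[3] * up[2],
         z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  rbind(x, y, z)
}

#' Synthetic multi-camera tunnel array
#'
#' Places cameras in rings around a rectangular flight-tunnel cross-section,
#' emulating a motion-capture array: `n_rings` streamwise stations, each with
#' `per_ring` cameras spread over the tunnel walls, all aimed at the middle of
#' the flight volume.
#'
#' @param n_rings Number of streamwise rings.
#' @param per_ring Cameras per ring.
#' @param tunnel_halfwidth Half the tunnel cross-section side (m).
#' @param ring_x Streamwise ring stations (m); defaults to three stations
#'   bracketing a ~1 m flight starting at x = 0.
#' @param target Aim point of every camera (m).
#' @param fx Focal length (px) used for all cameras.
#' @param k Radial distortion coefficients shared by all cameras.
#' @return A list of [camera_model()] objects.
#' @export
camera_ring_array <- function(n_rings = 3, per_ring = 7,
                              tunnel_halfwidth = 0.6,
                              ring_x = c(-0.9, 0.55, 2.0),
                              target = c(0.55, 0, 0),
                              fx = 880, k = c(-0.25, 0.07)) {
  fw_assert(length(ring_x) == n_rings, "ring_x must have n_rings entries")
  cams <- list()
  idx <- 1L
  for (r in seq_len(n_rings)) {
    ang <- 2 * pi * (seq_len(per_ring) - 1) / per_ring + 0.3 * r
    for (j in seq_len(per_ring)) {
      # point on the square tunnel perimeter in the (y, z) plane
      cy <- cos(ang[j]); sz <- sin(ang[j])
      sc <- tunnel_halfwidth / max(abs(cy), abs(sz))
      eye <- c(ring_x[r], sc * cy, sc * sz)
      R <- look_at_rotation(eye, target)
      t <- -as.numeric(R %*% eye)
      cams[[idx]] <- camera_model(id = idx, fx = fx, fy = fx,
                                  cx = 640, cy = 360, k = k, R = R, t = t)
      idx <- idx + 1L
    }
  }
  cams
}

#' Project marker trajectories into camera observations
#'
#' Projects every valid 3D marker position through each camera's pinhole +
#' radial-distortion model, adds Gaussian pixel noise, and drops each
#' (camera, frame, marker) independently with probability `occlusion_rate`.
#' Markers behind a camera or projecting outside the sensor are simply not
#' observed (not an error).
#'
#' @param truth Marker-trajectory tibble (see [generate_wing_motion()]).
#' @param cameras List of [camera_model()] objects.
#' @param pixel_noise_sd Gaussian noise SD (px).
#' @param occlusion_rate Drop probability in `[0, 1)`.
#' @param seed Integer seed; the output is reproducible given the seed.
#' @return Observation tibble with columns `camera_id`, `frame`, `marker_id`,
#'   `u_px`, `v_px`.
#' @export
project_to_cameras <- function(truth, cameras, pixel_noise_sd = 0,
                               occlusion_rate = 0, seed = 1L) {
  fw_assert(occlusion_rate >= 0 && occlusion_rate < 1,
            "occlusion_rate must be in [0, 1)")
  fw_assert(pixel_noise_sd >= 0, "pixel_noise_sd must be >= 0")
  set.seed(as.integer(seed))
  pts <- truth[truth$valid, c("frame", "marker_id", "x_m", "y_m", "z_m")]
  X <- cbind(pts$x_m, pts$y_m, pts$z_m)

  out <- purrr::map(cameras, function(cam) {
    Xc <- X %*% t(cam$R) + matrix(cam$t, nrow(X), 3, byrow = TRUE)
    vis <- Xc[, 3] > 0.05
    xn <- Xc[vis, 1] / Xc[vis, 3]
    yn <- Xc[vis, 2] / Xc[vis, 3]
    d <- distortion_factor(xn^2 + yn^2, cam$k)
    u <- cam$fx * xn * d + cam$cx
    v <- cam$fy * yn * d + cam$cy
    inb <- u >= 0 & u <= cam$width & v >= 0 & v <= cam$height
    tibble(camera_id = cam$id,
           frame = pts$frame[vis][inb], marker_id = pts$marker_id[vis][inb],
           u_px = u[inb], v_px = v[inb])
  })
  obs <- dplyr::bind_rows(out)
  if (pixel_noise_sd > 0) {
    obs$u_px <- obs$u_px + stats::rnorm(nrow(obs), 0, pixel_noise_sd)
    obs$v_px <- obs$v_px + stats::rnorm(nrow(obs), 0, pixel_noise_sd)
  }
  if (occlusion_rate > 0) {
    keep <- stats::runif(nrow(obs)) >= occlusion_rate
    obs <- obs[keep, , drop = FALSE]
  }
  obs
}

distortion_factor <- function(r2, k) {
  d <- rep(1, length(r2))
  rp <- r2
  for (ki in k) {
    d <- d + ki * rp
    rp <- rp * r2
  }
  d
}

#' Undistort pixel observations to normalized image coordinates
#'
#' Inverts the radial distortion map iteratively (fixed-point on the
#' normalized coordinates) to a tolerance of 1e-10 in normalized units, with
#' at most 50 iterations. Non-converged points are flagged invalid.
#'
#' @param obs Observation tibble (columns `u_px`, `v_px`, ...).
#' @param cam The [camera_model()] that produced the observations.
#' @param tol Convergence tolerance in normalized units.
#' @param max_iter Maximum fixed-point iterations.
#' @return The input tibble with added columns `xn`, `yn` (ideal normalized
#'   coordinates) and `undistort_ok`.
#' @export
undistort <- function(obs, cam, tol = 1e-10, max_iter = 50L) {
  xd <- (obs$u_px - cam$cx) / cam$fx
  yd <- (obs$v_px - cam$cy) / cam$fy
  xu <- xd; yu <- yd
  ok <- rep(FALSE, length(xd))
  for (i in seq_len(max_iter)) {
    d <- distortion_factor(xu^2 + yu^2, cam$k)
    x_new <- xd / d
    y_new <- yd / d
    conv <- abs(x_new - xu) < tol & abs(y_new - yu) < tol
    xu <- x_new; yu <- y_new
    ok <- ok | conv
    if (all(conv)) break
  }
  obs$xn <- xu
  obs$yn <- yu
  obs$undistort_ok <- ok
  obs
}
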