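#' Triangulate matched observations from a camera pair
#'
#' Linear least-squares (DLT) solution of the two projection constraints per
#' matched observation. Both observation tibbles must contain the same
#' (frame, marker) pairs' pixel coordinates; they are joined on
#' `frame` and `marker_id`, undistorted, and triangulated in one vectorized
#' pass.
#'
#' Pairs whose viewing rays are nearly parallel (intersection angle below
#' `min_ray_angle_deg`) are flagged `low_confidence` so callers can exclude
#' them from fusion.
#'
#' @param obs_a,obs_b Observation tibbles (columns `frame`, `marker_id`,
#'   `u_px`, `v_px`) from camera a and b.
#' @param cam_a,cam_b The corresponding [camera_model()] objects.
#' @param min_ray_angle_deg Rays meeting at less than this angle are flagged.
#' @return A tibble with `frame`, `marker_id`, `x_m`, `y_m`, `z_m`,
#'   `residual_px` (RMS reprojection error over both views) and
#'   `low_confidence`.
#' @export
triangulate_pair <- function(obs_a, obs_b, cam_a, cam_b,
                             min_ray_angle_deg = 1) {
  ca <- camera_center(cam_a)
  cb <- camera_center(cam_b)
  fw_assert(sqrt(sum((ca - cb)^2)) > 1e-9,
            "degenerate camera pair: identical camera centers give no parallax")

  m <- dplyr::inner_join(
    undistort(obs_a, cam_a)[c("frame", "marker_id", "xn", "yn")],
    undistort(obs_b, cam_b)[c("frame", "marker_id", "xn", "yn")],
    by = c("frame", "marker_id"), suffix = c("_a", "_b"))
  if (nrow(m) == 0) {
    return(tibble(frame = integer(), marker_id = integer(), x_m = numeric(),
                  y_m = numeric(), z_m = numeric(), residual_px = numeric(),
                  low_confidence = logical()))
  }

  # Constraint rows (r1 - x r3) . X = x t3 - t1 etc., two rows per camera.
  rows <- function(cam, xn, yn) {
    R <- cam$R; t <- cam$t
    a1 <- cbind(R[1, 1] - xn * R[3, 1], R[1, 2] - xn * R[3, 2], R[1, 3] - xn * R[3, 3])
    a2 <- cbind(R[2, 1] - yn * R[3, 1], R[2, 2] - yn * R[3, 2], R[2, 3] - yn * R[3, 3])
    b1 <- xn * t[3] - t[1]
    b2 <- yn * t[3] - t[2]
    list(a1 = a1, a2 = a2, b1 = b1, b2 = b2)
  }
  ra <- rows(cam_a, m$xn_a, m$yn_a)
  rb <- rows(cam_b, m$xn_b, m$yn_b)

  # accumulate 3x3 normal equations per point, vectorized over points
  n11 <- n12 <- n13 <- n22 <- n23 <- n33 <- 0
  c1 <- c2 <- c3 <- 0
  for (r in list(ra$a1, ra$a2, rb$a1, rb$a2)) {
    n11 <- n11 + r[, 1]^2; n12 <- n12 + r[, 1] * r[, 2]
    n13 <- n13 + r[, 1] * r[, 3]; n22 <- n22 + r[, 2]^2
    n23 <- n23 + r[, 2] * r[, 3]; n33 <- n33 + r[, 3]^2
  }
  for (rb_ in list(list(ra$a1, ra$b1), list(ra$a2, ra$b2),
                   list(rb$a1, rb$b1), list(rb$a2, rb$b2))) {
    c1 <- c1 + rb_[[1]][, 1] * rb_[[2]]
    c2 <- c2 + rb_[[1]][, 2] * rb_[[2]]
    c3 <- c3 + rb_[[1]][, 3] * rb_[[2]]
  }
  # closed-form inverse of the symmetric 3x3 via adjugate
  d11 <- n22 * n33 - n23^2
  d12 <- n13 * n23 - n12 * n33
  d13 <- n12 * n23 - n13 * n22
  det <- n11 * d11 + n12 * d12 + n13 * d13
  d22 <- n11 * n33 - n13^2
  d23 <- n12 * n13 - n11 * n23
  d33 <- n11 * n22 - n12^2
  X <- cbind((d11 * c1 + d12 * c2 + d13 * c3) / det,
             (d12 * c1 + d22 * c2 + d23 * c3) / det,
             (d13 * c1 + d23 * c2 + d33 * c3) / det)

  # ray angle for confidence flag
  dir_a <- cbind(m$xn_a, m$yn_a, 1) %*% cam_a$R
  dir_b <- cbind(m$xn_b, m$yn_b, 1) %*% cam_b$R
  cosang <- abs(rowSums(dir_a * dir_b)) / (row_norms(dir_a) * row_norms(dir_b))
  low_conf <- cosang > cos(min_ray_angle_deg * pi / 180)

  # RMS reprojection residual in pixels over both views
  reproj <- function(cam, X) {
    Xc <- X %*% t(cam$R) + matrix(cam$t, nrow(X), 3, byrow = TRUE)
    xn <- Xc[, 1] / Xc[, 3]; yn <- Xc[, 2] / Xc[, 3]
    d <- distortion_factor(xn^2 + yn^2, cam$k)
    cbind(cam$fx * xn * d + cam$cx, cam$fy * yn * d + cam$cy)
  }
  oa <- dplyr::inner_join(m[c("frame", "marker_id")], obs_a,
                          by = c("frame", "marker_id"))
  ob <- dplyr::inner_join(m[c("frame", "marker_id")], obs_b,
                          by = c("frame", "marker_id"))
  pa <- reproj(cam_a, X); pb <- reproj(cam_b, X)
  res <- sqrt(((pa[, 1] - oa$u_px)^2 + (pa[, 2] - oa$v_px)^2 +
                 (pb[, 1] - ob$u_px)^2 + (pb[, 2] - ob$v_px)^2) / 2)

  tibble(frame = m$frame, marker_id = m$marker_id,
         x_m = X[, 1], y_m = X[, 2], z_m = X[, 3],
         residual_px = res, low_confidence = low_conf)
}

#' Fuse multi-view candidate reconstructions by the coordinate-wise median
#'
#' @param points A numeric matrix (n x 3) or data frame with columns
#'   `x_m`, `y_m`, `z_m` of candidate 3D reconstructions of one point.
#' @return Length-3 numeric vector: the coordinate-wise median.
#' @export
fuse_multiview <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x_m", "y_m", "z_m")])
  fw_assert(nrow(points) >= 1, "fuse_multiview needs at least one candidate")
  apply(points, 2, median)
}

#' Reconstruct 3D marker trajectories from all camera pairs
#'
#' For every camera pair, triangulates all matched observations; candidates
#' with reprojection residual above `max_residual_px` or near-parallel rays
#' are excluded, and each (frame, marker) position is the coordinate-wise
#' median of the surviving candidates. Markers with no candidate in a frame
#' are marked invalid there.
#'
#' @param observations Observation tibble over all cameras (columns
#'   `camera_id`, `frame`, `marker_id`, `u_px`, `v_px`).
#' @param cameras List of [camera_model()] objects whose `id`s appear in the
#'   observations.
#' @param frame_rate Capture frame rate (Hz) used to reconstruct the time
#'   axis.
#' @param max_residual_px Candidate rejection threshold (px).
#' @param min_ray_angle_deg Minimum ray intersection angle (deg).
#' @param regions Optional tibble `marker_id`, `region` to carry region tags
#'   through (defaults to `"unknown"`).
#' @return A marker-trajectory tibble (`frame`, `time_s`, `marker_id`,
#'   `region`, `x_m`, `y_m`, `z_m`, `valid`) covering every frame/marker in
#'   the observations.
#' @export
reconstruct_markers <- function(observations, cameras, frame_rate = 120,
                                max_residual_px = 5, min_ray_angle_deg = 1,
                                regions = NULL) {
  ids <- vapply(cameras, function(cm) cm$id, FUN.VALUE = observations$camera_id[1])
  by_cam <- split(observations, observations$camera_id)
  present <- names(by_cam)

  cand <- list()
  n <- length(present)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      cam_i <- cameras[[match(present[i], as.character(ids))]]
      cam_j <- cameras[[match(present[j], as.character(ids))]]
      tr <- triangulate_pair(by_cam[[i]], by_cam[[j]], cam_i, cam_j,
                             min_ray_angle_deg = min_ray_angle_deg)
      tr <- tr[!tr$low_confidence & tr$residual_px <= max_residual_px, ,
               drop = FALSE]
      if (nrow(tr)) cand[[length(cand) + 1L]] <- tr
    }
  }
  cand <- dplyr::bind_rows(cand)

  fused <- cand |>
    dplyr::group_by(.data$frame, .data$marker_id) |>
    dplyr::summarise(x_m = median(.data$x_m), y_m = median(.data$y_m),
                     z_m = median(.data$z_m), n_candidates = dplyr::n(),
                     .groups = "drop")

  grid <- tidyr::expand_grid(frame = sort(unique(observations$frame)),
                             marker_id = sort(unique(observations$marker_id)))
  out <- dplyr::left_join(grid, fused, by = c("frame", "marker_id"))
  out$valid <- !is.na(out$x_m)
  out$time_s <- (out$frame - min(out$frame)) / frame_rate
  if (is.null(regions)) {
    out$region <- "unknown"
  } else {
    out <- dplyr::left_join(out, regions, by = "marker_id")
  }
  out[, c("frame", "time_s", "marker_id", "region",
          "x_m", "y_m", "z_m", "valid")]
}

#' PCA-based trajectory cleaning
#'
#' Stacks per-frame marker coordinates into a frames x (3 * markers) matrix
#' (mean-imputing gaps), projects onto the leading principal components
#' capturing at least `variance_fraction` of the variance, flags
#' (frame, marker) entries whose 3D residual norm exceeds
#' `outlier_k * MAD` of all residual norms, and replaces flagged and missing
#' entries by natural cubic-spline interpolation in time. Entries that are
#' not flagged are returned bit-identical. Markers valid in fewer than 4
#' frames are left invalid and reported.
#'
#' @param traj Marker-trajectory tibble.
#' @param variance_fraction Fraction of variance the kept leading subspace
#'   must capture (default 0.99).
#' @param outlier_k MAD multiplier for flagging (default 5).
#' @return The cleaned trajectory tibble, with a `"cleaning_report"`
#'   attribute: a tibble of modified entries (`marker_id`, `frame`, `action`,
#'   `residual_m`).
#' @export
pca_clean <- function(traj, variance_fraction = 0.99, outlier_k = 5) {
  fw_assert(variance_fraction > 0 && variance_fraction <= 1,
            "variance_fraction must be in (0, 1]")
  frames <- sort(unique(traj$frame))
  nfr <- length(frames)
  valid_counts <- traj |>
    dplyr::filter(.data$valid) |>
    dplyr::count(.data$marker_id)
  usable <- valid_counts$marker_id[valid_counts$n >= 4]
  skipped <- setdiff(unique(traj$marker_id), usable)

  sub <- traj[traj$marker_id %in% usable, , drop = FALSE]
  markers <- sort(unique(sub$marker_id))
  nmk <- length(markers)

  # frames x (3 * markers) matrix; NA where invalid
  M <- matrix(NA_real_, nfr, 3 * nmk)
  fi <- match(sub$frame, frames)
  mi <- match(sub$marker_id, markers)
  ok <- sub$valid
  M[cbind(fi[ok], 3 * (mi[ok] - 1) + 1)] <- sub$x_m[ok]
  M[cbind(fi[ok], 3 * (mi[ok] - 1) + 2)] <- sub$y_m[ok]
  M[cbind(fi[ok], 3 * (mi[ok] - 1) + 3)] <- sub$z_m[ok]
  miss <- is.na(M)
  colmean <- colMeans(M, na.rm = TRUE)
  for (jj in which(colSums(miss) > 0)) M[miss[, jj], jj] <- colmean[jj]

  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  q <- which(cumvar >= variance_fraction - 1e-12)[1]
  recon <- pc$x[, seq_len(q), drop = FALSE] %*%
    t(pc$rotation[, seq_len(q), drop = FALSE])
  recon <- sweep(recon, 2, pc$center, "+")
  E <- M - recon

  # 3D residual norm per (frame, marker)
  rnorm2 <- sqrt(E[, seq(1, 3 * nmk, 3)]^2 +
                   E[, seq(2, 3 * nmk, 3)]^2 +
                   E[, seq(3, 3 * nmk, 3)]^2)
  observed <- !(miss[, seq(1, 3 * nmk, 3)] |
                  miss[, seq(2, 3 * nmk, 3)] |
                  miss[, seq(3, 3 * nmk, 3)])
  scale_mad <- mad(rnorm2[observed], center = 0)
  # an (almost) exactly low-rank record has no meaningful residual scale:
  # nothing can be flagged
  flagged <- if (scale_mad < 1e-12) observed & FALSE else
    observed & (rnorm2 > outlier_k * scale_mad)

  out <- traj
  tvec <- sort(unique(traj$time_s))
  report <- list()
  for (im in seq_len(nmk)) {
    bad <- flagged[, im]
    gap <- !observed[, im]
    if (!any(bad) && !any(gap)) next
    keep <- which(!bad & !gap)
    rows <- match(paste(frames, markers[im]), paste(out$frame, out$marker_id))
    if (length(keep) >= 4) {
      for (d in 1:3) {
        coords <- M[, 3 * (im - 1) + d]
        fitted <- spline(tvec[keep], coords[keep], xout = tvec,
                         method = "natural")$y
        repl <- which(bad | gap)
        out[[c("x_m", "y_m", "z_m")[d]]][rows[repl]] <- fitted[repl]
      }
      out$valid[rows[bad | gap]] <- TRUE
      act <- ifelse(bad[bad | gap], "outlier_replaced", "gap_filled")
    } else {
      out$valid[rows[bad]] <- FALSE
      act <- rep("invalidated", sum(bad | gap))
    }
    report[[length(report) + 1L]] <-
      tibble(marker_id = markers[im], frame = frames[bad | gap],
             action = act, residual_m = rnorm2[bad | gap, im])
  }
  if (length(skipped)) {
    report[[length(report) + 1L]] <-
      tibble(marker_id = skipped, frame = NA_integer_,
             action = "too_few_valid_frames", residual_m = NA_real_)
  }
  attr(out, "cleaning_report") <-
    if (length(report)) dplyr::bind_rows(report) else
      tibble(marker_id = integer(), frame = integer(),
             action = character(), residual_m = numeric())
  out
}
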