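#' Build a non-uniform Cartesian fluid grid
#'
#' Uniform spacing inside a refined box (sized to contain the swept wing
#' volume), geometric stretching outward to the domain boundaries. Mirrors
#' the production protocol of a 32c x 16c x 16c domain refined to
#' 0.020 chords in the wing region, at desk scale.
#'
#' @param xlim,ylim,zlim Domain extents (m), length-2 each.
#' @param refined Named list with optional `x`, `y`, `z` length-2 intervals
#'   (m) of the uniformly refined box; axes omitted are uniform throughout.
#' @param spacing Fine grid spacing (m) inside the refined box (scalar or
#'   per-axis named vector).
#' @param growth Geometric stretching ratio (> 1) outside the refined box;
#'   `1` requests uniform spacing everywhere.
#' @param periodic Logical length-3: periodic axes (refined box ignored
#'   there; spacing uniform).
#' @return An object of class `fluid_grid` with per-axis face/center/spacing
#'   arrays and the total cell count.
#' @export
build_grid <- function(xlim, ylim, zlim, refined = list(), spacing,
                       growth = 1.15, periodic = c(FALSE, FALSE, FALSE)) {
  fw_assert(growth >= 1, "growth ratio must be >= 1 (got %.3g)", growth)
  if (length(spacing) == 1) spacing <- c(x = spacing, y = spacing, z = spacing)
  lims <- list(x = xlim, y = ylim, z = zlim)
  ax <- lapply(c(x = "x", y = "y", z = "z"), function(a) {
    axis_faces(lims[[a]], refined[[a]], spacing[[a]], growth,
               periodic[[match(a, c("x", "y", "z"))]])
  })
  g <- list(xf = ax$x, yf = ax$y, zf = ax$z,
            xc = midpts(ax$x), yc = midpts(ax$y), zc = midpts(ax$z),
            dx = diff(ax$x), dy = diff(ax$y), dz = diff(ax$z),
            nx = length(ax$x) - 1L, ny = length(ax$y) - 1L,
            nz = length(ax$z) - 1L,
            periodic = periodic, refined = refined,
            cache = new.env(parent = emptyenv()))
  g$n_cells <- g$nx * g$ny * g$nz
  # distance across each face between adjacent cell centers (ghosts mirrored)
  g$dxc <- face_center_dist(g$xc, g$xf, periodic[1])
  g$dyc <- face_center_dist(g$yc, g$yf, periodic[2])
  g$dzc <- face_center_dist(g$zc, g$zf, periodic[3])
  structure(g, class = "fluid_grid")
}

midpts <- function(f) (f[-1] + f[-length(f)]) / 2

face_center_dist <- function(xc, xf, per) {
  n <- length(xc)
  if (n == 1) {
    d <- xf[2] - xf[1]
    return(c(d, d))
  }
  inner <- diff(xc)
  if (per) {
    wrap <- (xc[1] - xf[1]) + (xf[n + 1] - xc[n])
    c(wrap, inner, wrap)
  } else {
    c(2 * (xc[1] - xf[1]), inner, 2 * (xf[n + 1] - xc[n]))
  }
}

axis_faces <- function(lim, refined, h, growth, periodic) {
  fw_assert(lim[2] > lim[1], "axis limits must be increasing")
  if (is.null(refined) || periodic || growth == 1) {
    n <- max(1L, round((lim[2] - lim[1]) / h))
    return(seq(lim[1], lim[2], length.out = n + 1))
  }
  fw_assert(refined[1] >= lim[1] && refined[2] <= lim[2],
            "refined box must lie inside the domain")
  n_core <- max(1L, round((refined[2] - refined[1]) / h))
  h_adj <- (refined[2] - refined[1]) / n_core
  core <- seq(refined[1], refined[2], length.out = n_core + 1)
  # geometric widths h0*g, h0*g^2, ..., rescaled as a block to fill [from, to]
  # exactly: adjacent ratio stays g, the core-to-first ratio is at most g
  stretch <- function(from, to, h0, dir) {
    len <- abs(to - from)
    if (len < 1e-12) return(numeric(0))
    g <- growth
    m <- max(1L, ceiling(log(1 + len * (g - 1) / (h0 * g)) / log(g)))
    widths <- h0 * g^seq_len(m)
    widths <- widths * (len / sum(widths))
    pos <- from + dir * cumsum(widths)
    pos[m] <- to
    pos
  }
  left <- rev(stretch(refined[1], lim[1], h_adj, -1))
  right <- stretch(refined[2], lim[2], h_adj, +1)
  c(left, core, right)
}

#' @export
print.fluid_grid <- function(x, ...) {
  cat(sprintf("<fluid_grid> %d x %d x %d = %s cells\n", x$nx, x$ny, x$nz,
              format(x$n_cells, big.mark = ",")))
  cat(sprintf("  x: [%.3g, %.3g] m, dx %.3g..%.3g | y: [%.3g, %.3g], dy %.3g..%.3g | z: [%.3g, %.3g], dz %.3g..%.3g\n",
              min(x$xf), max(x$xf), min(x$dx), max(x$dx),
              min(x$yf), max(x$yf), min(x$dy), max(x$dy),
              min(x$zf), max(x$zf), min(x$dz), max(x$dz)))
  if (any(x$periodic)) cat("  periodic:", paste(c("x", "y", "z")[x$periodic], collapse = ", "), "\n")
  invisible(x)
}
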