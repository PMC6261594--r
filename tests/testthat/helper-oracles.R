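# independent loop-based implementation of the dynamic model on a periodic
# grid: plain nested loops, no shared code with the vectorized version
brute_force_smagorinsky <- function(st, g, alpha = 2) {
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  hx <- g$dx[1]; hy <- g$dy[1]; hz <- g$dz[1]
  uc <- array(0, c(nx, ny, nz)); vc <- uc; wc <- uc
  for (i in 1:nx) uc[i, , ] <- (st$u[i, , ] + st$u[i + 1, , ]) / 2
  for (j in 1:ny) vc[, j, ] <- (st$v[, j, ] + st$v[, j + 1, ]) / 2
  for (k in 1:nz) wc[, , k] <- (st$w[, , k] + st$w[, , k + 1] ) / 2
  wrap <- function(i, n) ((i - 1) %% n) + 1
  gradc <- function(A, axis) {
    out <- array(0, dim(A))
    for (i in 1:nx) for (j in 1:ny) for (k in 1:nz) {
      if (axis == 1) out[i, j, k] <-
          (A[wrap(i + 1, nx), j, k] - A[wrap(i - 1, nx), j, k]) / (2 * hx)
      if (axis == 2) out[i, j, k] <-
          (A[i, wrap(j + 1, ny), k] - A[i, wrap(j - 1, ny), k]) / (2 * hy)
      if (axis == 3) out[i, j, k] <-
          (A[i, j, wrap(k + 1, nz)] - A[i, j, wrap(k - 1, nz)]) / (2 * hz)
    }
    out
  }
  filt <- function(A) {
    out <- array(0, dim(A))
    w1 <- c(0.25, 0.5, 0.25)
    for (i in 1:nx) for (j in 1:ny) for (k in 1:nz) {
      acc <- 0
      for (a in -1:1) for (b in -1:1) for (cc in -1:1) {
        acc <- acc + w1[a + 2] * w1[b + 2] * w1[cc + 2] *
          A[wrap(i + a, nx), wrap(j + b, ny), wrap(k + cc, nz)]
      }
      out[i, j, k] <- acc
    }
    out
  }
  strain <- function(u, v, w) {
    gx <- list(gradc(u, 1), gradc(u, 2), gradc(u, 3),
               gradc(v, 1), gradc(v, 2), gradc(v, 3),
               gradc(w, 1), gradc(w, 2), gradc(w, 3))
    s <- list(s11 = gx[[1]], s22 = gx[[5]], s33 = gx[[9]],
              s12 = (gx[[2]] + gx[[4]]) / 2, s13 = (gx[[3]] + gx[[7]]) / 2,
              s23 = (gx[[6]] + gx[[8]]) / 2)
    s$mag <- sqrt(2 * (s$s11^2 + s$s22^2 + s$s33^2 +
                         2 * (s$s12^2 + s$s13^2 + s$s23^2)))
    s
  }
  s <- strain(uc, vc, wc)
  uf <- filt(uc); vf <- filt(vc); wf <- filt(wc)
  sf <- strain(uf, vf, wf)
  delta2 <- (hx * hy * hz)^(2 / 3)
  L <- list(filt(uc * uc) - uf * uf, filt(vc * vc) - vf * vf,
            filt(wc * wc) - wf * wf, filt(uc * vc) - uf * vf,
            filt(uc * wc) - uf * wf, filt(vc * wc) - vf * wf)
  M <- list()
  nms <- c("s11", "s22", "s33", "s12", "s13", "s23")
  for (q in seq_along(nms)) {
    M[[q]] <- 2 * delta2 * (filt(s$mag * s[[nms[q]]]) -
                              alpha^2 * sf$mag * sf[[nms[q]]])
  }
  num <- L[[1]] * M[[1]] + L[[2]] * M[[2]] + L[[3]] * M[[3]] +
    2 * (L[[4]] * M[[4]] + L[[5]] * M[[5]] + L[[6]] * M[[6]])
  den <- M[[1]]^2 + M[[2]]^2 + M[[3]]^2 +
    2 * (M[[4]]^2 + M[[5]]^2 + M[[6]]^2)
  C <- ifelse(den > 1e-30, num / den, 0)
  C[C < 0] <- 0
  C * delta2 * s$mag
}
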