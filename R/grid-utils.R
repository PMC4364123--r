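# Regular-grid helpers shared by the edge-map / GVF / FFD machinery.
# Grids are 3D arrays with an origin (mm, coordinates of node [1,1,1]) and an
# isotropic spacing (mm); arrays are indexed [x, y, z].

# shift an array by one node along axis, replicating the boundary (Neumann)
.shift3 <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]] - by
  i[i < 1L] <- 1L
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  do.call(`[`, c(list(a), idx))
}

# central-difference gradient (one-sided at the boundary), per-axis list
.gradient3 <- function(a, h) {
  g <- lapply(1:3, function(ax) {
    (.shift3(a, ax, -1L) - .shift3(a, ax, 1L)) / (2 * h)
  })
  # one-sided at the two boundary slabs of each axis
  d <- dim(a)
  for (ax in 1:3) {
    lo <- hi <- lapply(d, seq_len)
    lo[[ax]] <- 1L; hi[[ax]] <- d[ax]
    lo2 <- lo; lo2[[ax]] <- 2L
    hi2 <- hi; hi2[[ax]] <- d[ax] - 1L
    g[[ax]][matrix_index(lo, d)] <-
      (do.call(`[`, c(list(a), lo2)) - do.call(`[`, c(list(a), lo))) / h
    g[[ax]][matrix_index(hi, d)] <-
      (do.call(`[`, c(list(a), hi)) - do.call(`[`, c(list(a), hi2))) / h
  }
  g
}

# linear index set for a sub-slab given per-axis index lists
matrix_index <- function(idx, d) {
  as.vector(outer(outer(idx[[1]], (idx[[2]] - 1L) * d[1], "+"),
                  (idx[[3]] - 1L) * d[1] * d[2], "+"))
}

# 6-neighbour Laplacian with replicated boundary
.laplacian3 <- function(a, h) {
  (.shift3(a, 1, 1L) + .shift3(a, 1, -1L) +
     .shift3(a, 2, 1L) + .shift3(a, 2, -1L) +
     .shift3(a, 3, 1L) + .shift3(a, 3, -1L) - 6 * a) / h^2
}

# trilinear interpolation of a 3D array at arbitrary points (n x 3, mm);
# points outside the grid are clamped to the boundary
.interp3 <- function(a, origin, spacing, points) {
  d <- dim(a)
  u <- sweep(points, 2L, origin) / spacing  # 0-based continuous index
  for (ax in 1:3) u[, ax] <- pmin(pmax(u[, ax], 0), d[ax] - 1 - 1e-9)
  i0 <- floor(u)
  t <- u - i0
  i0 <- i0 + 1L  # 1-based lower corner
  i1 <- pmin(i0 + 1L, matrix(rep(d, each = nrow(u)), ncol = 3L))
  lin <- function(ix, iy, iz) a[cbind(ix, iy, iz)]
  c000 <- lin(i0[,1], i0[,2], i0[,3]); c100 <- lin(i1[,1], i0[,2], i0[,3])
  c010 <- lin(i0[,1], i1[,2], i0[,3]); c110 <- lin(i1[,1], i1[,2], i0[,3])
  c001 <- lin(i0[,1], i0[,2], i1[,3]); c101 <- lin(i1[,1], i0[,2], i1[,3])
  c011 <- lin(i0[,1], i1[,2], i1[,3]); c111 <- lin(i1[,1], i1[,2], i1[,3])
  tx <- t[,1]; ty <- t[,2]; tz <- t[,3]
  (c000 * (1-tx) + c100 * tx) * (1-ty) * (1-tz) +
    (c010 * (1-tx) + c110 * tx) * ty * (1-tz) +
    (c001 * (1-tx) + c101 * tx) * (1-ty) * tz +
    (c011 * (1-tx) + c111 * tx) * ty * tz
}
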