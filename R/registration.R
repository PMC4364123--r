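#' Registration configuration
#'
#' Parameters of the GVF-driven free-form surface registration. The GVF
#' diffusion uses the generalized Xu-Prince update
#' `v <- v + dt * (mu * lap(v) - |grad f|^2 (v - grad f))`; the explicit
#' scheme is stable only when `dt * mu / h^2 <= 1/6` (3D diffusion bound),
#' and `dt` additionally has to keep the reaction term contractive, so the
#' default `dt` is 0.9 times the joint bound and is recomputed per edge map.
#'
#' @param n_iterations free-form deformation update cycles (default 15).
#' @param gvf_mu GVF smoothness weight (mm^2, default 0.1).
#' @param gvf_dt explicit time step; `NULL` picks 0.9x the stability bound.
#' @param gvf_sweeps diffusion sweeps used to converge the GVF field.
#' @param membrane_weight overall regularization weight of the lattice fit.
#' @param thinplate_fraction blend p in `(1-p)*membrane + p*thin-plate`
#'   (first- vs second-difference penalty on control displacements).
#' @param step fraction of the estimated surface distance advanced per cycle.
#' @return list of class `registration_config`.
#' @export
registration_config <- function(n_iterations = 15L, gvf_mu = 0.1,
                                gvf_dt = NULL, gvf_sweeps = 100L,
                                membrane_weight = 1e-2,
                                thinplate_fraction = 0.5, step = 0.9) {
  stopifnot(n_iterations >= 1L, gvf_mu > 0,
            thinplate_fraction >= 0, thinplate_fraction <= 1, step > 0)
  structure(list(n_iterations = as.integer(n_iterations), gvf_mu = gvf_mu,
                 gvf_dt = gvf_dt, gvf_sweeps = as.integer(gvf_sweeps),
                 membrane_weight = membrane_weight,
                 thinplate_fraction = thinplate_fraction, step = step),
            class = "registration_config")
}

#' Average surfaces sharing a common connectivity
#'
#' Vertex-wise arithmetic mean of coordinates over meshes whose face arrays
#' are identical (within-pipeline vertex correspondence); used to build each
#' pipeline's average template.
#'
#' @param meshes list of [triangle_mesh()] with identical `faces`.
#' @return a [triangle_mesh()] with the same connectivity.
#' @export
average_surface <- function(meshes) {
  if (!length(meshes)) stop("no meshes to average")
  f0 <- meshes[[1]]$faces
  acc <- matrix(0, nrow(meshes[[1]]$vertices), 3L)
  for (m in meshes) {
    if (!identical(m$faces, f0)) stop("meshes do not share connectivity")
    acc <- acc + m$vertices
  }
  triangle_mesh(acc / length(meshes), f0, hemisphere = meshes[[1]]$hemisphere)
}

#' Volumetric edge map of a target surface
#'
#' Rasterizes the target surface into an isotropic scalar volume
#' `f = exp(-|d| / sigma)` where `d` is the signed Euclidean distance from
#' each grid node to the surface: `f = 1` on the surface and decays with
#' distance, providing the edge strength that the gradient vector flow
#' diffuses. Within a shell of half-width `refine_band` around the surface,
#' `d` is the exact point-to-triangle distance (signed by the outward
#' normal, negative inside); beyond the shell `|d|` saturates at
#' `refine_band`, with the inside/outside sign resolved by a flood fill
#' from the grid boundary. The shell therefore has to be wider than the
#' decay length (`refine_band > sigma` is enforced) so that the edge
#' profile is exact wherever the field carries useful attraction.
#'
#' @param target a closed [triangle_mesh()].
#' @param spacing grid spacing (mm); the grid must stay within 256^3 nodes.
#' @param sigma edge decay length (mm); default twice the spacing.
#' @param padding margin added around the target bounding box (mm).
#' @param refine_band half-width (mm) of the exact-distance shell.
#' @return object of class `edge_map`: list with arrays `f` (edge strength
#'   in `[0,1]`) and `d` (signed distance, mm, saturated at
#'   `+/- refine_band`), plus `origin`, `spacing`, `dims`, `sigma`.
#' @export
voxelize_and_edge_map <- function(target, spacing, sigma = 2 * spacing,
                                  padding = 6 * spacing,
                                  refine_band = 3 * spacing) {
  if (refine_band <= sigma) stop("refine_band must exceed sigma")
  bb <- apply(target$vertices, 2L, range)
  origin <- bb[1L, ] - padding
  dims <- as.integer(ceiling((bb[2L, ] - bb[1L, ] + 2 * padding) / spacing)) + 1L
  if (prod(dims) > 256^3) stop("resolution error: grid exceeds 256^3 nodes")

  # near-surface band: all nodes in Chebyshev blocks around the vertices,
  # wide enough to cover every node within refine_band of the surface
  e <- mesh_edges(target)
  emax <- sqrt(max(rowSums((target$vertices[e[, 1L], , drop = FALSE] -
                              target$vertices[e[, 2L], , drop = FALSE])^2)))
  B <- ceiling((0.6 * emax + refine_band) / spacing)
  vi <- round(sweep(target$vertices, 2L, origin) / spacing) + 1L
  off <- as.matrix(expand.grid(x = -B:B, y = -B:B, z = -B:B))
  # spherical trim: only offsets that can reach a node within the band
  off <- off[sqrt(rowSums(off^2)) <= (0.6 * emax + refine_band) / spacing + 1, ,
             drop = FALSE]
  noff <- nrow(off)
  mask <- logical(prod(dims))
  for (lo in seq(1L, nrow(vi), by = 2000L)) {
    hi <- min(lo + 1999L, nrow(vi))
    vc <- vi[lo:hi, , drop = FALSE]
    nv <- nrow(vc)
    bx <- rep(vc[, 1L], each = noff) + rep.int(off[, 1L], nv)
    by <- rep(vc[, 2L], each = noff) + rep.int(off[, 2L], nv)
    bz <- rep(vc[, 3L], each = noff) + rep.int(off[, 3L], nv)
    ok <- bx >= 1L & bx <= dims[1] & by >= 1L & by <= dims[2] &
      bz >= 1L & bz <= dims[3]
    mask[(bx[ok] - 1L) + (by[ok] - 1L) * dims[1] +
           (bz[ok] - 1L) * dims[1] * dims[2] + 1L] <- TRUE
  }
  band <- which(mask)
  bi <- arrayInd(band, dims)
  band_pts <- sweep((bi - 1L) * spacing, 2L, origin, "+")
  # nearest-vertex pre-filter: a node within refine_band of the surface is
  # within refine_band + 0.6*emax of some vertex
  pre <- closest_point_search(band_pts, target$vertices)
  keep <- pre$match_distance <= refine_band + 0.6 * emax
  band <- band[keep]; band_pts <- band_pts[keep, , drop = FALSE]
  pre <- list(match_index = pre$match_index[keep],
              match_distance = pre$match_distance[keep])
  dband <- point_surface_distance(band_pts, target, signed = TRUE, cps = pre)
  inband <- abs(dband) <= refine_band
  band <- band[inband]; dband <- dband[inband]

  darr <- array(NA_real_, dim = dims)
  darr[band] <- dband
  # inside/outside for the remaining nodes: flood fill from the corner
  isband <- array(FALSE, dim = dims)
  isband[band] <- TRUE
  outside <- array(FALSE, dim = dims)
  outside[1L, 1L, 1L] <- TRUE
  repeat {
    grown <- outside |
      .shift3(outside, 1, 1L) | .shift3(outside, 1, -1L) |
      .shift3(outside, 2, 1L) | .shift3(outside, 2, -1L) |
      .shift3(outside, 3, 1L) | .shift3(outside, 3, -1L)
    grown <- grown & !isband
    if (sum(grown) == sum(outside)) break
    outside <- grown
  }
  far <- !isband
  darr[far & outside] <- refine_band
  darr[far & !outside] <- -refine_band
  structure(list(f = exp(-abs(darr) / sigma), d = darr,
                 origin = origin, spacing = spacing, dims = dims,
                 sigma = sigma, refine_band = refine_band),
            class = "edge_map")
}

# discrete GVF energy: integral of mu*|grad v|^2 + |grad f|^2 |v - grad f|^2.
# The smoothness term uses forward differences with replicated boundary --
# the discretization whose gradient flow is exactly the 6-neighbour Laplacian
# used in the update, so the energy is a Lyapunov function of the iteration.
.gvf_energy <- function(v, g, b, mu, h) {
  e <- 0
  for (k in 1:3) {
    for (ax in 1:3) {
      e <- e + mu * sum((.shift3(v[[k]], ax, -1L) - v[[k]])^2) / h^2
    }
    e <- e + sum(b * (v[[k]] - g[[k]])^2)
  }
  e * h^3
}

#' Gradient vector flow of an edge map
#'
#' Diffuses the edge-map gradient into homogeneous regions by the
#' generalized Xu-Prince iteration; near strong edges the converged field
#' approximates the edge gradient itself, while far from edges it is a
#' smooth extension giving every surface vertex a direction of attraction.
#' The discrete GVF energy is tracked every sweep and is non-increasing
#' under the stability bound (checked on every run).
#'
#' @param edge an [voxelize_and_edge_map()] result.
#' @param cfg a [registration_config()].
#' @return object of class `vector_field3d`: list of arrays `vx`, `vy`,
#'   `vz`, the grid metadata, the signed-distance volume (carried along for
#'   the deformation step), `iterations` and the per-sweep `energy` trace.
#' @export
compute_gvf <- function(edge, cfg = registration_config()) {
  h <- edge$spacing
  g <- .gradient3(edge$f, h)
  b <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2
  bmax <- max(b)
  dt <- cfg$gvf_dt %||% (0.9 / (6 * cfg$gvf_mu / h^2 + bmax))
  if (dt * cfg$gvf_mu / h^2 > 1 / 6 + 1e-12) {
    stop("unstable GVF configuration: dt * mu / h^2 > 1/6")
  }
  v <- g  # initialize at the edge gradient
  energy <- numeric(cfg$gvf_sweeps)
  for (it in seq_len(cfg$gvf_sweeps)) {
    for (k in 1:3) {
      v[[k]] <- v[[k]] + dt * (cfg$gvf_mu * .laplacian3(v[[k]], h) -
                                 b * (v[[k]] - g[[k]]))
    }
    energy[it] <- .gvf_energy(v, g, b, cfg$gvf_mu, h)
    if (it > 1L && energy[it] > energy[it - 1L] * (1 + 1e-9)) {
      stop("GVF energy increased: diffusion is unstable")
    }
  }
  structure(list(vx = v[[1]], vy = v[[2]], vz = v[[3]],
                 d = edge$d, f = edge$f,
                 origin = edge$origin, spacing = edge$spacing,
                 dims = edge$dims, sigma = edge$sigma,
                 iterations = cfg$gvf_sweeps, energy = energy),
            class = "vector_field3d")
}

#' Uniform cubic B-spline control lattice
#'
#' A free-form deformation parameterized by displacements of a regular
#' control-point grid, interpolated by tensor-product uniform cubic
#' B-splines (C2-continuous). The lattice is laid out with a one-cell
#' margin so every point of the stated domain has full 4x4x4 support.
#'
#' @param domain_lo,domain_hi numeric length-3 corners of the domain (mm).
#' @param dims integer length-1 or -3 control counts per axis (>= 5).
#' @return object of class `control_lattice` with zero displacements.
#' @export
control_lattice <- function(domain_lo, domain_hi, dims = 8L) {
  dims <- rep(as.integer(dims), length.out = 3L)
  if (any(dims < 5L)) stop("lattice needs >= 5 controls per axis")
  spacing <- (domain_hi - domain_lo) / (dims - 3)
  origin <- domain_lo - spacing
  structure(list(dims = dims, origin = origin, spacing = spacing,
                 domain_lo = domain_lo, domain_hi = domain_hi,
                 disp = matrix(0, prod(dims), 3L)),
            class = "control_lattice")
}

# cubic uniform B-spline basis values for fractional offsets t in [0,1)
.bspline_w <- function(t) {
  list((1 - t)^3 / 6,
       (3 * t^3 - 6 * t^2 + 4) / 6,
       (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
       t^3 / 6)
}

# per-point 64 (weight, control-index) pairs; clamps points to the domain.
# returns list(i = point ids, j = control ids, w = weights, clamped count)
.ffd_weights <- function(lattice, points) {
  dm <- lattice$dims
  u <- sweep(as.matrix(points), 2L, lattice$origin)
  u <- sweep(u, 2L, lattice$spacing, "/")
  clamped <- 0L
  for (ax in 1:3) {
    bad <- u[, ax] < 1 | u[, ax] > dm[ax] - 2
    clamped <- clamped + sum(bad)
    u[, ax] <- pmin(pmax(u[, ax], 1), dm[ax] - 2 - 1e-9)
  }
  i0 <- floor(u)              # 0-based cell index per axis
  t <- u - i0
  wx <- .bspline_w(t[, 1]); wy <- .bspline_w(t[, 2]); wz <- .bspline_w(t[, 3])
  n <- nrow(u)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  ii <- vector("list", 64L); jj <- vector("list", 64L); ww <- vector("list", 64L)
  q <- 1L
  for (a in 0:3) for (bb in 0:3) for (cc in 0:3) {
    cx <- i0[, 1] - 1 + a; cy <- i0[, 2] - 1 + bb; cz <- i0[, 3] - 1 + cc
    jj[[q]] <- as.integer(cx + cy * dm[1] + cz * dm[1] * dm[2] + 1)
    ww[[q]] <- wx[[a + 1]] * wy[[bb + 1]] * wz[[cc + 1]]
    ii[[q]] <- seq_len(n)
    q <- q + 1L
  }
  list(i = unlist(ii), j = unlist(jj), w = unlist(ww), clamped = clamped,
       n = n, K = prod(dm))
}

#' Apply a free-form deformation to points
#'
#' Tensor-product cubic B-spline interpolation of the control-point
#' displacements; by the partition-of-unity property a uniform control
#' displacement translates all points rigidly. Points outside the lattice
#' domain are clamped with a warning.
#'
#' @param lattice a [control_lattice()].
#' @param points n x 3 matrix (mm).
#' @return n x 3 matrix of transformed points.
#' @export
apply_ffd <- function(lattice, points) {
  fw <- .ffd_weights(lattice, points)
  if (fw$clamped > 0L) warning(fw$clamped, " point coordinate(s) clamped to the lattice domain")
  B <- Matrix::sparseMatrix(i = fw$i, j = fw$j, x = fw$w,
                            dims = c(fw$n, fw$K))
  as.matrix(points) + as.matrix(B %*% lattice$disp)
}

# first- and second-difference penalty matrices over the lattice graph
.lattice_penalty <- function(dims, thinplate_fraction) {
  K <- prod(dims)
  idx <- array(seq_len(K), dim = dims)
  rows1 <- list(); q <- 1L
  D1 <- list(); D2 <- list()
  for (ax in 1:3) {
    n <- dims[ax]
    sl <- function(k) {
      pick <- lapply(dims, seq_len)
      pick[[ax]] <- k
      as.vector(do.call(`[`, c(list(idx), pick)))
    }
    a <- sl(1:(n - 1)); b2 <- sl(2:n)
    m <- length(a)
    D1[[ax]] <- Matrix::sparseMatrix(i = rep(seq_len(m), 2L), j = c(a, b2),
                                     x = c(rep(-1, m), rep(1, m)),
                                     dims = c(m, K))
    a <- sl(1:(n - 2)); b2 <- sl(2:(n - 1)); c2 <- sl(3:n)
    m <- length(a)
    D2[[ax]] <- Matrix::sparseMatrix(i = rep(seq_len(m), 3L),
                                     j = c(a, b2, c2),
                                     x = c(rep(1, m), rep(-2, m), rep(1, m)),
                                     dims = c(m, K))
  }
  P1 <- Reduce(`+`, lapply(D1, Matrix::crossprod))
  P2 <- Reduce(`+`, lapply(D2, Matrix::crossprod))
  (1 - thinplate_fraction) * P1 + thinplate_fraction * P2
}

# regularized least-squares fit of control increments to desired point
# displacements: min |B c - d|^2 + lambda * c' P c, solved per component
.fit_lattice_increment <- function(lattice, points, desired, lambda,
                                   thinplate_fraction) {
  fw <- .ffd_weights(lattice, points)
  B <- Matrix::sparseMatrix(i = fw$i, j = fw$j, x = fw$w,
                            dims = c(fw$n, fw$K))
  BtB <- Matrix::crossprod(B)
  P <- .lattice_penalty(lattice$dims, thinplate_fraction)
  scale <- mean(Matrix::diag(BtB)) + 1e-12
  A <- BtB + (lambda * scale) * P +
    Matrix::Diagonal(fw$K, 1e-10 * scale)  # keep unsupported controls at 0
  rhs <- Matrix::crossprod(B, desired)
  as.matrix(Matrix::solve(A, rhs))
}

#' GVF-driven free-form registration of a source surface onto a target
#'
#' Deforms the source mesh toward the surface encoded by a gradient vector
#' flow field. Each cycle samples the GVF at the current vertex positions
#' to obtain the direction of attraction, estimates the remaining distance
#' to the target surface from the signed-distance volume, fits the implied
#' vertex displacements by a regularized least-squares update of the
#' control lattice (membrane/thin-plate blend), and re-interpolates all
#' vertices through the cubic B-spline transform. Connectivity never
#' changes; mesh validity is re-checked after every cycle.
#'
#' @param source a [triangle_mesh()] inside the lattice domain.
#' @param gvf a [compute_gvf()] field of the target's edge map.
#' @param lattice a [control_lattice()] covering the source.
#' @param cfg a [registration_config()].
#' @param validate re-validate mesh topology after each cycle.
#' @return list with `mesh` (deformed source), `lattice` (cumulative
#'   control displacements) and `trace` (per-cycle mean estimated distance,
#'   mm).
#' @export
ffd_register <- function(source, gvf, lattice, cfg = registration_config(),
                         validate = TRUE) {
  pos0 <- source$vertices
  cap <- 2 * gvf$sigma
  trace <- numeric(cfg$n_iterations)
  for (it in seq_len(cfg$n_iterations)) {
    pos <- apply_ffd(lattice, pos0)
    vx <- .interp3(gvf$vx, gvf$origin, gvf$spacing, pos)
    vy <- .interp3(gvf$vy, gvf$origin, gvf$spacing, pos)
    vz <- .interp3(gvf$vz, gvf$origin, gvf$spacing, pos)
    dhat <- .interp3(gvf$d, gvf$origin, gvf$spacing, pos)
    if (any(!is.finite(c(vx, vy, vz, dhat)))) stop("non-finite displacement")
    vn2 <- sqrt(vx^2 + vy^2 + vz^2)
    vmax <- max(vn2)
    gate <- if (vmax > 0) pmin(1, vn2 / (0.2 * vmax)) else rep(0, length(vn2))
    mag <- pmin(abs(dhat), cap) * gate * cfg$step
    mag[mag < 0.1 * gvf$spacing] <- 0  # dead band: already on the surface
    trace[it] <- mean(abs(dhat))
    den <- pmax(vn2, 1e-12)
    desired <- cbind(vx / den, vy / den, vz / den) * mag
    inc <- .fit_lattice_increment(lattice, pos0, (pos - pos0) + desired,
                                  cfg$membrane_weight, cfg$thinplate_fraction)
    lattice$disp <- inc  # refit of the cumulative displacement field
    if (validate) {
      validate_mesh(triangle_mesh(apply_ffd(lattice, pos0), source$faces,
                                  hemisphere = source$hemisphere))
    }
  }
  out <- triangle_mesh(apply_ffd(lattice, pos0), source$faces,
                       hemisphere = source$hemisphere)
  list(mesh = out, lattice = lattice, trace = trace)
}

#' Write/read a control lattice as CSV
#'
#' Serialized as one row per control point `(i,j,k,dx,dy,dz)` plus a header
#' comment carrying the grid geometry.
#'
#' @param lattice a [control_lattice()].
#' @param path CSV path.
#' @return [read_lattice()] returns a [control_lattice()].
#' @export
write_lattice <- function(lattice, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims %d %d %d origin %.9g %.9g %.9g spacing %.9g %.9g %.9g lo %.9g %.9g %.9g hi %.9g %.9g %.9g",
                     lattice$dims[1], lattice$dims[2], lattice$dims[3],
                     lattice$origin[1], lattice$origin[2], lattice$origin[3],
                     lattice$spacing[1], lattice$spacing[2], lattice$spacing[3],
                     lattice$domain_lo[1], lattice$domain_lo[2], lattice$domain_lo[3],
                     lattice$domain_hi[1], lattice$domain_hi[2], lattice$domain_hi[3]), con)
  g <- expand.grid(i = seq_len(lattice$dims[1]), j = seq_len(lattice$dims[2]),
                   k = seq_len(lattice$dims[3]))
  utils::write.csv(cbind(g, dx = lattice$disp[, 1], dy = lattice$disp[, 2],
                         dz = lattice$disp[, 3]),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lattice
#' @export
read_lattice <- function(path) {
  hdr <- readLines(path, n = 1L)
  num <- as.numeric(strsplit(hdr, "\\s+")[[1]][c(3:5, 7:9, 11:13, 15:17, 19:21)])
  lat <- control_lattice(num[10:12], num[13:15], dims = as.integer(num[1:3]))
  d <- utils::read.csv(path, skip = 1L)
  lat$disp <- unname(as.matrix(d[, c("dx", "dy", "dz")]))
  lat
}
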