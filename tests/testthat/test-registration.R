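test_that("edge map is exact near the surface and saturates beyond the band", {
  h <- reg_harness()
  em <- h$em
  ax <- lapply(1:3, function(k) em$origin[k] + (seq_len(em$dims[k]) - 1) * em$spacing)
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  dtrue <- r - 10  # analytic signed distance to the radius-10 sphere
  band <- abs(dtrue) <= 0.8 * em$refine_band
  expect_lt(max(abs(em$d[band] - dtrue[band])), 0.05)
  expect_true(all(abs(em$d) <= em$refine_band + 1e-9))
  # f = exp(-|d|/sigma): 1 on the surface, e^-1 at d = sigma, monotone
  expect_equal(em$f, exp(-abs(em$d) / em$sigma))
  on_surface <- abs(dtrue) < 0.05
  expect_gt(min(em$f[on_surface]), exp(-0.11 / em$sigma))
  at_sigma <- abs(abs(dtrue) - em$sigma) < 0.05
  expect_lt(max(abs(em$f[at_sigma] - exp(-1))), 0.06)
  # anti-monotone in the true distance, up to the 0.05 mm distance accuracy
  ord <- order(abs(dtrue[band]))
  expect_true(all(diff(em$f[band][ord]) <= 1 - exp(-0.1 / em$sigma)))
})

test_that("GVF of a constant edge map is identically zero", {
  h <- reg_harness()
  em0 <- h$em
  em0$f[] <- 0.5
  g <- compute_gvf(em0, registration_config(gvf_sweeps = 5))
  expect_equal(max(abs(c(g$vx, g$vy, g$vz))), 0)
})

test_that("GVF energy is non-increasing over 100 sweeps on a sphere edge map", {
  h <- reg_harness()
  g <- compute_gvf(h$em, registration_config(gvf_sweeps = 100))
  expect_true(all(diff(g$energy) <= 1e-9 * g$energy[1]))
})

test_that("converged GVF approximates the edge gradient at strong edges", {
  h <- reg_harness()
  g <- compute_gvf(h$em, registration_config(gvf_mu = 1e-4, gvf_sweeps = 400))
  gr <- corticompare:::.gradient3(h$em$f, h$em$spacing)
  b <- gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2
  strong <- b > 0.5 * max(b)
  relerr <- sqrt((g$vx - gr[[1]])^2 + (g$vy - gr[[2]])^2 +
                   (g$vz - gr[[3]])^2) / sqrt(b)
  expect_lt(max(relerr[strong]), 0.01)
})

test_that("an unstable GVF time step is refused", {
  h <- reg_harness()
  cfg <- registration_config(gvf_dt = 1, gvf_mu = 1)  # dt*mu/h^2 = 4 > 1/6
  expect_error(compute_gvf(h$em, cfg), "unstable")
})

test_that("FFD interpolation: identity, rigid translation, brute-force basis oracle", {
  lat <- control_lattice(c(-13, -13, -13), c(13, 13, 13), dims = 7L)
  p <- matrix(runif(30, -10, 10), 10)
  expect_equal(apply_ffd(lat, p), p)  # zero lattice
  lat$disp <- matrix(rep(c(1, -2, 0.5), each = nrow(lat$disp)), ncol = 3)
  expect_equal(apply_ffd(lat, p), sweep(p, 2, c(1, -2, 0.5), "+"),
               tolerance = 1e-12)  # partition of unity
  # random lattice vs direct tensor-product basis summation
  set.seed(8)
  lat$disp <- matrix(rnorm(nrow(lat$disp) * 3), ncol = 3)
  bs <- function(t) c((1 - t)^3, 3 * t^3 - 6 * t^2 + 4,
                      -3 * t^3 + 3 * t^2 + 3 * t + 1, t^3) / 6
  oracle_one <- function(x) {
    u <- (x - lat$origin) / lat$spacing
    i0 <- floor(u); tt <- u - i0
    out <- x
    for (a in 0:3) for (b in 0:3) for (cc in 0:3) {
      w <- bs(tt[1])[a + 1] * bs(tt[2])[b + 1] * bs(tt[3])[cc + 1]
      j <- (i0[1] - 1 + a) + (i0[2] - 1 + b) * lat$dims[1] +
        (i0[3] - 1 + cc) * lat$dims[1] * lat$dims[2] + 1
      out <- out + w * lat$disp[j, ]
    }
    out
  }
  q <- matrix(runif(30, -9, 9), 10)
  expect_equal(apply_ffd(lat, q), t(apply(q, 1, oracle_one)),
               tolerance = 1e-10)
  expect_warning(apply_ffd(lat, matrix(c(100, 0, 0), 1)), "clamped")
})

test_that("synthetic warps: identity at zero amplitude, positive Jacobian, determinism", {
  h <- reg_harness()
  probe <- h$target$vertices
  w0 <- make_synthetic_warp(1, 0, h$domain_lo, h$domain_hi, probe_points = probe)
  expect_equal(apply_ffd(w0, probe), probe)
  w <- make_synthetic_warp(1, 1.5, h$domain_lo, h$domain_hi, probe_points = probe)
  w2 <- make_synthetic_warp(1, 1.5, h$domain_lo, h$domain_hi, probe_points = probe)
  expect_identical(w$disp, w2$disp)
  expect_equal(max(sqrt(rowSums((apply_ffd(w, probe) - probe)^2))), 1.5)
  set.seed(4)
  dense <- matrix(runif(3000, -10, 10), ncol = 3)
  expect_true(all(ffd_jacobian(w, dense) > 0))
  expect_warning(
    make_synthetic_warp(1, 10, h$domain_lo, h$domain_hi, probe_points = probe),
    "fold")
})

test_that("registration with a zero field returns the source unchanged", {
  h <- reg_harness()
  em0 <- h$em; em0$f[] <- 0.5; em0$d[] <- 0
  gvf0 <- compute_gvf(em0, registration_config(gvf_sweeps = 2))
  w <- make_synthetic_warp(2, 1, h$domain_lo, h$domain_hi,
                           probe_points = h$target$vertices)
  src <- triangle_mesh(apply_ffd(w, h$target$vertices), h$target$faces)
  lat <- control_lattice(h$domain_lo, h$domain_hi, dims = 8L)
  res <- ffd_register(src, gvf0, lat, registration_config(n_iterations = 3),
                      validate = FALSE)
  expect_equal(res$mesh$vertices, src$vertices)
})

test_that("known-warp recovery: median post/pre distance ratio is at most 0.2", {
  h <- reg_harness()
  ratios <- vapply(1:5, function(seed) {
    w <- make_synthetic_warp(seed, 1.5, h$domain_lo, h$domain_hi,
                             probe_points = h$target$vertices)
    src <- triangle_mesh(apply_ffd(w, h$target$vertices), h$target$faces)
    pre <- surface_distance(src, h$target)$mean_distance
    lat <- control_lattice(h$domain_lo, h$domain_hi, dims = 10L)
    res <- ffd_register(src, h$gvf, lat, registration_config(),
                        validate = FALSE)
    surface_distance(res$mesh, h$target)$mean_distance / pre
  }, 0)
  expect_lte(median(ratios), 0.2)
  .harness$recovery_ratios <- ratios
})

test_that("deformation preserves topology and self-registration stays put", {
  h <- reg_harness()
  w <- make_synthetic_warp(3, 1.5, h$domain_lo, h$domain_hi,
                           probe_points = h$target$vertices)
  src <- triangle_mesh(apply_ffd(w, h$target$vertices), h$target$faces)
  lat <- control_lattice(h$domain_lo, h$domain_hi, dims = 10L)
  res <- ffd_register(src, h$gvf, lat,
                      registration_config(n_iterations = 5), validate = TRUE)
  expect_identical(res$mesh$faces, src$faces)
  expect_true(validate_mesh(res$mesh))
  # mesh registered to itself: mean displacement below spacing / 10
  self <- ffd_register(h$target, h$gvf,
                       control_lattice(h$domain_lo, h$domain_hi, dims = 10L),
                       registration_config(), validate = FALSE)
  disp <- sqrt(rowSums((self$mesh$vertices - h$target$vertices)^2))
  expect_lt(mean(disp), h$em$spacing / 10)
})

test_that("control lattices round-trip through CSV", {
  lat <- control_lattice(c(-5, -5, -5), c(5, 5, 5), dims = 6L)
  set.seed(1)
  lat$disp <- matrix(rnorm(nrow(lat$disp) * 3), ncol = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_lattice(lat, p)
  lat2 <- read_lattice(p)
  expect_equal(lat2$disp, lat$disp, tolerance = 1e-12)
  expect_equal(lat2$origin, lat$origin)
  q <- matrix(runif(15, -4, 4), 5)
  expect_equal(apply_ffd(lat2, q), apply_ffd(lat, q))
})

test_that("averaging surfaces is the vertexwise mean and demands shared connectivity", {
  m <- build_icosphere(2, 10)
  expect_equal(average_surface(list(m))$vertices, m$vertices)
  shift <- triangle_mesh(sweep(m$vertices, 2, c(2, 0, 0), "+"), m$faces)
  avg <- average_surface(list(m, shift))
  expect_equal(avg$vertices, sweep(m$vertices, 2, c(1, 0, 0), "+"))
  expect_identical(avg$faces, m$faces)
  other <- build_icosphere(1, 10)
  expect_error(average_surface(list(m, other)), "connectivity")
  # 30 deformed copies keep the vertex count
  set.seed(6)
  many <- lapply(1:30, function(i) {
    triangle_mesh(m$vertices + matrix(rnorm(n_vertices(m) * 3, 0, 0.1),
                                      ncol = 3), m$faces)
  })
  expect_equal(n_vertices(average_surface(many)), n_vertices(m))
})
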