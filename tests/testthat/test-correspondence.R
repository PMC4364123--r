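test_that("closest point search equals the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(10:1000, 1)
    m <- sample(10:1000, 1)
    s <- matrix(rnorm(n * 3), ncol = 3)
    t <- matrix(rnorm(m * 3), ncol = 3)
    cc <- closest_point_search(s, t)
    expect_identical(cc$match_index, unname(cps_oracle(s, t)))
  }
})

test_that("exact ties resolve to the lowest target index", {
  # duplicated target points: identical distances by construction
  t <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(0, 1, 0))
  s <- rbind(c(1, 0, 0), c(0, 1, 0))
  cc <- closest_point_search(s, t)
  expect_identical(cc$match_index, c(1L, 2L))
  # symmetric equidistant pair
  t2 <- rbind(c(0, 0, 1), c(0, 0, -1))
  cc2 <- closest_point_search(matrix(c(5, 0, 0), 1), t2)
  expect_identical(cc2$match_index, 1L)
})

test_that("hierarchical search is exact on large surface-like instances", {
  m <- build_icosphere(4, 30)
  set.seed(5)
  q <- m$vertices + matrix(rnorm(n_vertices(m) * 3, 0, 1), ncol = 3)
  a <- closest_point_search(q, m$vertices, method = "bruteforce")
  b <- closest_point_search(q, m$vertices, method = "hierarchical")
  expect_identical(a$match_index, b$match_index)
  expect_equal(a$match_distance, b$match_distance, tolerance = 1e-12)
})

test_that("empty inputs are rejected", {
  expect_error(closest_point_search(matrix(0, 0, 3), matrix(0, 1, 3)), "empty")
  expect_error(closest_point_search(matrix(0, 1, 3), matrix(0, 0, 3)), "empty")
})

test_that("thickness transfer is an index lookup and idempotent under identity", {
  set.seed(2)
  t <- matrix(rnorm(90), ncol = 3)
  map <- scalar_map(rnorm(30), "target")
  id_corr <- closest_point_search(t, t)
  expect_identical(id_corr$match_index, 1:30)
  expect_equal(transfer_thickness(map, id_corr)$values, map$values)
  # constant map stays constant through any correspondence
  s <- matrix(rnorm(45), ncol = 3)
  corr <- closest_point_search(s, t)
  expect_equal(transfer_thickness(scalar_map(rep(1.5, 30)), corr)$values,
               rep(1.5, 15))
  # values equal oracle lookup on a tie-free instance
  expect_equal(transfer_thickness(map, corr)$values,
               map$values[cps_oracle(s, t)])
  expect_error(transfer_thickness(scalar_map(1:5), corr, n_target = 30),
               "length")
})

test_that("hybrid dataset bookkeeping: one record per subject x timepoint", {
  set.seed(3)
  src <- matrix(rnorm(60), ncol = 3)
  tgt <- matrix(rnorm(90), ncol = 3)
  corr <- closest_point_search(src, tgt)
  keys <- c("S1|BSL", "S1|M24", "S2|BSL", "S2|M24")
  mcv <- setNames(lapply(keys, function(k) scalar_map(rnorm(20))), keys)
  mfs <- setNames(lapply(keys, function(k) scalar_map(rnorm(30))), keys)
  h <- build_hybrid_dataset(mcv, mfs, corr)
  expect_equal(nrow(h$records), 4)
  expect_equal(dim(h$thickness_cv), c(20, 4))
  expect_equal(dim(h$thickness_fs), c(20, 4))
  # a record missing in one pipeline is skipped with a warning
  expect_warning(h2 <- build_hybrid_dataset(mcv, mfs[-2], corr), "skipping")
  expect_equal(nrow(h2$records), 3)
})

test_that("noise-free equal-scale pipelines agree on the hybrid template", {
  # same truth observed on two templates of different resolution: after
  # closest-point transfer the per-vertex difference is far below the
  # truth's between-ROI contrast scale
  coh <- small_cohort()
  r <- 20
  tcv <- combine_hemispheres(build_icosphere(2, r, c(-r - 2, 0, 0), "left"),
                             build_icosphere(2, r, c(r + 2, 0, 0), "right"))
  tfs <- combine_hemispheres(build_icosphere(3, r, c(-r - 2, 0, 0), "left"),
                             build_icosphere(3, r, c(r + 2, 0, 0), "right"))
  acv <- build_synthetic_atlas(tcv, seed = 9)
  afs <- build_synthetic_atlas(tfs, seed = 9)
  noiseless <- pipeline_profile("P", 2, measurement_noise_sd = 0)
  ocv <- render_pipeline_observation(coh, noiseless, acv, tcv,
                                     subjects = "S001", timepoints = "BSL")
  ofs <- render_pipeline_observation(coh, noiseless, afs, tfs,
                                     subjects = "S001", timepoints = "BSL")
  corr <- closest_point_search(tcv$vertices, tfs$vertices)
  h <- build_hybrid_dataset(ocv$maps, ofs$maps, corr)
  dif <- abs(h$thickness_cv[, 1] - h$thickness_fs[, 1])
  expect_lt(median(dif), 0.05)  # most vertices land in the same ROI patch
})
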