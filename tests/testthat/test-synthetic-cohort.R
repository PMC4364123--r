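test_that("cohorts are seed-deterministic", {
  a <- make_cohort(cohort_design(seed = 42))
  b <- make_cohort(cohort_design(seed = 42))
  expect_identical(a$truth, b$truth)
  expect_identical(a$covariates, b$covariates)
  c_ <- make_cohort(cohort_design(seed = 43))
  expect_false(identical(a$truth, c_$truth))
})

test_that("group sizes, MMSE range and thinning ordering match the design", {
  coh <- small_cohort()
  expect_equal(as.vector(table(coh$subjects$group)[c("CTR", "sMCI", "pMCI", "AD")]),
               c(69L, 37L, 27L, 52L))
  expect_true(all(coh$covariates$mmse_bsl >= 0 & coh$covariates$mmse_bsl <= 30))
  expect_true(all(coh$covariates$mmse_bsl == round(coh$covariates$mmse_bsl)))
  expect_true(all(coh$truth > 0))
  # AD-signature ROIs: mean two-year decline magnitude ordered over groups
  tsel <- as.character(coh$config$temporal_rois)
  dec <- coh$truth[, tsel, "M24"] - coh$truth[, tsel, "BSL"]
  bym <- tapply(rowMeans(dec), coh$subjects$group, mean)
  expect_true(bym["CTR"] >= bym["sMCI"] && bym["sMCI"] >= bym["pMCI"] &&
                bym["pMCI"] >= bym["AD"])
})

test_that("an all-zero effect config yields null group differences", {
  coh <- make_cohort(cohort_design(seed = 5),
                     default_effect_config(zero_effects = TRUE))
  g <- coh$subjects$group
  ps <- apply(coh$truth[, , "BSL"], 2, function(v) {
    stats::t.test(v[g == "CTR"], v[g == "AD"])$p.value
  })
  expect_gt(min(ps), 1e-4)            # nothing wildly significant
  expect_lt(mean(ps < 0.01), 0.15)    # about alpha-level rejections
})

test_that("unknown ROIs in the effect config are rejected", {
  cfg <- default_effect_config()
  cfg$roi_ids[1] <- 999L
  expect_error(make_cohort(config = cfg), "unknown ROI")
})

test_that("the injected parahippocampal AD decline is recovered", {
  # average over several cohorts to separate the injected mean (-0.27 mm,
  # anterior parahippocampal, AD group) from per-cohort sampling error
  dec <- vapply(1:6, function(s) {
    coh <- make_cohort(cohort_design(seed = s))
    d <- coh$truth[, "34", "M24"] - coh$truth[, "34", "BSL"]
    mean(d[coh$subjects$group == "AD"])
  }, 0)
  expect_lt(abs(mean(dec) - (-0.27)), 3 * 0.27 / sqrt(52 * 6))
})

test_that("ROI observation applies scale, offset and noise shrinkage", {
  coh <- small_cohort()
  noiseless <- pipeline_profile("CV", 4, thickness_scale = 1,
                                roi_noise_sd = 0)
  t0 <- observe_roi_table(coh, noiseless)
  truth_bsl <- as.vector(coh$truth[, , "BSL"])
  expect_equal(sort(t0$thickness[t0$timepoint == "BSL"]), sort(truth_bsl))
  half <- pipeline_profile("FS", 5, thickness_scale = 0.5,
                           additive_offset = 0.1, roi_noise_sd = 0)
  t1 <- observe_roi_table(coh, half)
  expect_equal(sort(t1$thickness[t1$timepoint == "BSL"]),
               sort(0.5 * truth_bsl + 0.1))
  # follow-up noise shrinkage: FS profile noise smaller at M24 than BSL
  fsnoisy <- fs_profile()
  tt <- observe_roi_table(coh, fsnoisy)
  res <- tt$thickness - 0.7 * as.vector(coh$truth)
  expect_lt(stats::sd(res[tt$timepoint == "M24"]),
            stats::sd(res[tt$timepoint == "BSL"]))
})

test_that("the 30% between-pipeline scale is recovered from observations", {
  coh <- small_cohort()
  tcv <- observe_roi_table(coh, cv_profile())
  tfs <- observe_roi_table(coh, fs_profile())
  ratio <- mean(tfs$thickness) / mean(tcv$thickness)
  expect_lt(abs(ratio - 0.70), 0.02)
})

test_that("rendered vertex maps equal the ROI truth when noise-free", {
  coh <- small_cohort()
  tmpl <- combine_hemispheres(
    build_icosphere(2, 20, c(-22, 0, 0), "left"),
    build_icosphere(2, 20, c(22, 0, 0), "right"))
  atlas <- build_synthetic_atlas(tmpl, seed = 3)
  prof <- pipeline_profile("CV", 2, measurement_noise_sd = 0)
  obs <- render_pipeline_observation(coh, prof, atlas, tmpl,
                                     subjects = c("S001", "S002"),
                                     timepoints = "BSL", meshes = TRUE)
  v <- obs$maps[["S001|BSL"]]$values
  expect_equal(v, unname(coh$truth["S001", as.character(atlas), "BSL"]))
  # same template connectivity, different per-subject geometry
  expect_identical(obs$meshes$S001$faces, obs$meshes$S002$faces)
  expect_false(identical(obs$meshes$S001$vertices, obs$meshes$S002$vertices))
})

test_that("injected hippocampal correlation is recovered at the temporal-lobe mean", {
  tsel <- roi_registry()
  tsel <- tsel$roi_id[tsel$lobe == "Temporal"]
  rs <- vapply(1:10, function(s) {
    coh <- make_cohort(cohort_design(seed = s))
    tcv <- observe_roi_table(coh, cv_profile())
    b <- tcv[tcv$timepoint == "BSL" & tcv$group == "pMCI" &
               tcv$roi_id %in% tsel, ]
    tm <- tapply(b$thickness, b$subject, mean)
    hv <- coh$covariates$hippo_volume[match(names(tm), coh$covariates$subject)]
    stats::cor(tm, hv)
  }, 0)
  expect_lt(abs(mean(rs) - 0.4), 0.15)
})
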