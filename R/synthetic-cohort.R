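#' Cohort design for synthetic two-pipeline studies
#'
#' Defaults reproduce the reference study design: four diagnostic groups —
#' elderly controls (CTR, n=69), stable MCI (sMCI, 37), progressive MCI
#' (pMCI, 27) and Alzheimer's dementia (AD, 52) — observed at baseline and
#' months 12 and 24.
#'
#' @param groups named integer vector of group sizes.
#' @param timepoints ordered character vector of visits.
#' @param seed integer seed controlling every random draw of the cohort.
#' @return list of class `cohort_design`.
#' @export
cohort_design <- function(groups = c(CTR = 69L, sMCI = 37L, pMCI = 27L, AD = 52L),
                          timepoints = c("BSL", "M12", "M24"),
                          seed = 1L) {
  stopifnot(all(groups > 0L), length(timepoints) >= 1L)
  structure(list(groups = groups, timepoints = timepoints,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Pipeline observation profiles
#'
#' A profile describes how one reconstruction pipeline observes the common
#' cortical truth: its template resolution (icosphere subdivision level),
#' a multiplicative thickness scale, an additive offset, and measurement
#' noise. The default pair emulates the reference comparison: the `CV`
#' (Civet-style) profile observes the truth at scale 1, while the `FS`
#' (Freesurfer-style) profile measures systematically lower by about 30%
#' (scale 0.70) on a finer template, and — emulating a longitudinal
#' processing stream that pools repeated visits — has its follow-up
#' measurement noise shrunk by `longitudinal_noise_shrink`.
#'
#' @param name profile label (`"CV"`, `"FS"`, ...).
#' @param resolution_subdiv icosphere subdivision of the pipeline template.
#' @param thickness_scale multiplicative bias (unitless, in (0, 1.5]).
#' @param additive_offset additive bias (mm).
#' @param measurement_noise_sd per-vertex smooth noise SD (mm).
#' @param roi_noise_sd measurement noise SD of ROI-mean observations (mm).
#' @param longitudinal_noise_shrink factor applied to noise SDs at
#'   follow-up visits (1 = none).
#' @param shape_bias_amplitude amplitude (mm) of the pipeline's systematic
#'   smooth radial template deformation — the morphological signature that
#'   makes one algorithm's surfaces differ from the other's and that the
#'   registration has to remove. Deterministic per profile name.
#' @return list of class `pipeline_profile`.
#' @export
pipeline_profile <- function(name, resolution_subdiv, thickness_scale = 1,
                             additive_offset = 0, measurement_noise_sd = 0.25,
                             roi_noise_sd = 0.08,
                             longitudinal_noise_shrink = 1,
                             shape_bias_amplitude = 0) {
  stopifnot(thickness_scale > 0, thickness_scale <= 1.5,
            measurement_noise_sd >= 0, roi_noise_sd >= 0,
            longitudinal_noise_shrink > 0, shape_bias_amplitude >= 0)
  structure(list(name = name,
                 resolution_subdiv = as.integer(resolution_subdiv),
                 thickness_scale = thickness_scale,
                 additive_offset = additive_offset,
                 measurement_noise_sd = measurement_noise_sd,
                 roi_noise_sd = roi_noise_sd,
                 longitudinal_noise_shrink = longitudinal_noise_shrink,
                 shape_bias_amplitude = shape_bias_amplitude),
            class = "pipeline_profile")
}

#' @rdname pipeline_profile
#' @param resolution_subdiv subdivision level; the desk-scale defaults (4
#'   for CV, 5 for FS) preserve the 4:1 vertex-count ratio of the reference
#'   resolutions (levels 6 and 7).
#' @export
cv_profile <- function(resolution_subdiv = 4L) {
  pipeline_profile("CV", resolution_subdiv, thickness_scale = 1,
                   longitudinal_noise_shrink = 1)
}

#' @rdname pipeline_profile
#' @export
fs_profile <- function(resolution_subdiv = 5L) {
  pipeline_profile("FS", resolution_subdiv, thickness_scale = 0.70,
                   longitudinal_noise_shrink = 0.6,
                   shape_bias_amplitude = 2)
}

#' Default ground-truth effect configuration
#'
#' ROI-wise cross-sectional group offsets, between-subject spreads, and
#' two-year declines are taken from the packaged transcriptions of the
#' reference study's Civet-scale summary tables (cross-sectional contrasts
#' and longitudinal per-group changes). The printed sigma of a contrast is
#' interpreted as the pooled between-subject SD and used directly as the
#' per-group SD. Baseline absolute thickness is not printed per ROI in the
#' available material, so a flat 2.5 mm baseline is used. MMSE levels and
#' two-year declines follow the demographics table; hippocampal volume is
#' generated to correlate with the true temporal-lobe mean thickness at
#' group-specific target levels (weak in CTR, medium in pMCI/AD).
#'
#' @param zero_effects if `TRUE`, all group offsets and declines are zeroed
#'   (null cohort) while spreads and covariates are kept.
#' @return list of class `effect_config`.
#' @export
default_effect_config <- function(zero_effects = FALSE) {
  reg <- roi_registry()
  t3 <- load_fixture_table("T3")$records
  t4 <- load_fixture_table("T4")$records
  t1 <- load_fixture_table("T1")$records
  t3 <- t3[t3$pipeline == "CV", ]
  t4 <- t4[t4$pipeline == "CV", ]
  t3 <- t3[match(reg$roi_id, t3$roi_id), ]
  t4 <- t4[match(reg$roi_id, t4$roi_id), ]
  groups <- c("CTR", "sMCI", "pMCI", "AD")
  cross_offset <- rbind(CTR = rep(0, 28), sMCI = t3$d_smci,
                        pMCI = t3$d_pmci, AD = t3$d_ad)
  cross_sd <- (t3$s_smci + t3$s_pmci + t3$s_ad) / 3
  long_delta <- rbind(CTR = t4$d_ctr, sMCI = t4$d_smci,
                      pMCI = t4$d_pmci, AD = t4$d_ad)
  long_sd <- rbind(CTR = t4$s_ctr, sMCI = t4$s_smci,
                   pMCI = t4$s_pmci, AD = t4$s_ad)
  colnames(cross_offset) <- colnames(long_delta) <- colnames(long_sd) <-
    as.character(reg$roi_id)
  names(cross_sd) <- as.character(reg$roi_id)
  if (zero_effects) {
    cross_offset[] <- 0
    long_delta[] <- 0
  }
  t1 <- t1[match(groups, t1$group), ]
  structure(list(
    roi_ids = reg$roi_id,
    baseline_mean = 2.5,
    cross_offset = cross_offset,
    cross_sd = cross_sd,
    global_share = 0.6,
    long_delta = long_delta,
    long_sd = long_sd,
    long_global_share = 0.5,
    mmse_bsl_mean = stats::setNames(t1$mmse_bsl_mean, groups),
    mmse_bsl_sd = stats::setNames(t1$mmse_bsl_sd, groups),
    dmmse_mean = stats::setNames(t1$dmmse_mean, groups),
    dmmse_sd = stats::setNames(t1$dmmse_sd, groups),
    mmse_thickness_r = c(CTR = 0.1, sMCI = 0.2, pMCI = 0.3, AD = 0.3),
    hippo_mean = c(CTR = 7.0, sMCI = 6.3, pMCI = 5.9, AD = 5.5),
    hippo_sd = c(CTR = 0.9, sMCI = 0.9, pMCI = 0.9, AD = 0.9),
    hippo_thickness_r = c(CTR = 0.1, sMCI = 0.2, pMCI = 0.4, AD = 0.4),
    temporal_rois = reg$roi_id[reg$lobe == "Temporal"]),
    class = "effect_config")
}

# run expr with a private, seed-determined RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a ground-truth cohort
#'
#' Draws, for every subject, true per-ROI cortical thickness at each visit
#' on the source-pipeline (CV) scale, plus MMSE and hippocampal-volume
#' covariates. Between-subject variation splits into a global cortical
#' factor and ROI-specific deviations (`global_share` of the variance is
#' global); two-year declines are linear in time, so month 12 sits halfway.
#' Reproducible: the same design (including its seed) always yields the
#' identical cohort.
#'
#' @param design a [cohort_design()].
#' @param config an [default_effect_config()] (or a modified copy). A config
#'   whose ROI set does not match the registry is rejected.
#' @return list of class `ground_truth_cohort` with `subjects` (data frame:
#'   `subject`, `group`), `truth` (subject x ROI x timepoint array, mm),
#'   `covariates` (MMSE at baseline/M24, hippocampal volume cm^3) and the
#'   generating `design`/`config`.
#' @export
make_cohort <- function(design = cohort_design(),
                        config = default_effect_config()) {
  if (!identical(sort(config$roi_ids), sort(roi_registry()$roi_id))) {
    stop("config error: effect configuration references unknown ROIs")
  }
  nroi <- length(config$roi_ids)
  groups <- rep(names(design$groups), design$groups)
  n <- length(groups)
  subj <- sprintf("S%03d", seq_len(n))
  tps <- design$timepoints
  .with_seed(design$seed, {
    gs <- config$global_share
    z_g <- stats::rnorm(n)
    z_r <- matrix(stats::rnorm(n * nroi), n, nroi)
    bsl <- matrix(config$baseline_mean, n, nroi) +
      config$cross_offset[groups, , drop = FALSE] +
      (sqrt(gs) * z_g + sqrt(1 - gs) * z_r) *
        matrix(config$cross_sd, n, nroi, byrow = TRUE)
    gl <- config$long_global_share
    w_g <- stats::rnorm(n)
    w_r <- matrix(stats::rnorm(n * nroi), n, nroi)
    decline2 <- config$long_delta[groups, , drop = FALSE] +
      (sqrt(gl) * w_g + sqrt(1 - gl) * w_r) *
        config$long_sd[groups, , drop = FALSE]
    truth <- array(NA_real_, dim = c(n, nroi, length(tps)),
                   dimnames = list(subj, as.character(config$roi_ids), tps))
    frac <- c(BSL = 0, M12 = 0.5, M24 = 1)[tps]
    for (k in seq_along(tps)) truth[, , k] <- pmax(bsl + frac[k] * decline2, 0.2)
    # covariates: MMSE tied to the global factor, hippocampus to the true
    # temporal-lobe mean
    rm_ <- config$mmse_thickness_r[groups]
    mmse_bsl <- config$mmse_bsl_mean[groups] + config$mmse_bsl_sd[groups] *
      (rm_ * z_g + sqrt(1 - rm_^2) * stats::rnorm(n))
    dmmse <- config$dmmse_mean[groups] + config$dmmse_sd[groups] *
      (rm_ * w_g + sqrt(1 - rm_^2) * stats::rnorm(n))
    mmse_bsl <- pmin(pmax(round(mmse_bsl), 0), 30)
    mmse_m24 <- pmin(pmax(round(mmse_bsl + dmmse), 0), 30)
    tsel <- as.character(config$temporal_rois)
    ttmp <- rowMeans(bsl[, tsel, drop = FALSE])
    z_t <- stats::ave(ttmp, groups, FUN = function(x) {
      s <- stats::sd(x); if (is.na(s) || s == 0) x * 0 else (x - mean(x)) / s
    })
    rh <- config$hippo_thickness_r[groups]
    hippo <- config$hippo_mean[groups] + config$hippo_sd[groups] *
      (rh * z_t + sqrt(1 - rh^2) * stats::rnorm(n))
    covar <- data.frame(subject = subj, group = groups,
                        mmse_bsl = mmse_bsl, mmse_m24 = mmse_m24,
                        hippo_volume = hippo, stringsAsFactors = FALSE)
  })
  structure(list(subjects = data.frame(subject = subj, group = groups,
                                       stringsAsFactors = FALSE),
                 truth = truth, covariates = covar,
                 design = design, config = config),
            class = "ground_truth_cohort")
}

#' @export
print.ground_truth_cohort <- function(x, ...) {
  cat(sprintf("ground_truth_cohort: %d subjects (%s), %d ROIs, %s\n",
              nrow(x$subjects),
              paste(names(x$design$groups), x$design$groups,
                    sep = ":", collapse = " "),
              dim(x$truth)[2], paste(x$design$timepoints, collapse = "/")))
  invisible(x)
}

#' ROI-level observation of a cohort by one pipeline
#'
#' Applies the pipeline's multiplicative scale, additive offset and
#' ROI-level measurement noise to the true per-ROI thickness, giving the
#' tidy subjects x ROIs x timepoints table that all group statistics
#' consume. This is the aggregation shortcut equivalent (in expectation) to
#' rendering vertex maps with [render_pipeline_observation()] and averaging
#' them over a parcellation.
#'
#' @param cohort a [make_cohort()] result.
#' @param profile a [pipeline_profile()].
#' @param seed measurement-noise seed (defaults to the cohort seed offset
#'   by a profile-specific constant).
#' @return data frame of class `roi_table`: subject, group, pipeline,
#'   timepoint, roi_id, thickness (mm).
#' @export
observe_roi_table <- function(cohort, profile, seed = NULL) {
  tps <- cohort$design$timepoints
  nroi <- dim(cohort$truth)[2]
  n <- nrow(cohort$subjects)
  seed <- seed %||% (cohort$design$seed + 1000L * match(profile$name, c("CV", "FS"), nomatch = 3L))
  out <- .with_seed(seed, {
    do.call(rbind, lapply(seq_along(tps), function(k) {
      shrink <- if (tps[k] == "BSL") 1 else profile$longitudinal_noise_shrink
      obs <- profile$thickness_scale * cohort$truth[, , k] +
        profile$additive_offset +
        matrix(stats::rnorm(n * nroi, 0, profile$roi_noise_sd * shrink), n, nroi)
      data.frame(subject = rep(cohort$subjects$subject, nroi),
                 group = rep(cohort$subjects$group, nroi),
                 pipeline = profile$name,
                 timepoint = tps[k],
                 roi_id = rep(as.integer(colnames(cohort$truth)), each = n),
                 thickness = as.vector(obs),
                 stringsAsFactors = FALSE)
    }))
  })
  class(out) <- c("roi_table", "data.frame")
  out
}

# neighbour-averaging smoother on a mesh; rounds chosen so the effective
# kernel FWHM is roughly the requested value (random-walk variance grows
# linearly in rounds; each round adds about edge^2/2 of kernel variance)
.smooth_on_mesh <- function(values, adj, rounds) {
  v <- values
  for (i in seq_len(rounds)) v <- 0.5 * v + 0.5 * as.vector(adj %*% v)
  v
}

# row-normalized sparse adjacency of a mesh
.mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  A <- Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                            x = 1, dims = rep(n_vertices(mesh), 2L))
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(x = 1 / pmax(deg, 1)) %*% A
}

#' Render per-subject vertex observations for one pipeline
#'
#' Produces, for each requested subject and timepoint, a thickness map on
#' the pipeline's two-hemisphere icosphere template: vertex value =
#' `scale * true ROI thickness + offset + spatially smooth noise`
#' (Gaussian-like, FWHM ~ `noise_fwhm` mm, marginal SD equal to the
#' profile's `measurement_noise_sd`, shrunk at follow-up visits for
#' profiles emulating a longitudinal stream). Optionally each subject gets
#' a mild smooth radial deformation of the template geometry (same
#' connectivity, different shape), as real cortices differ in shape.
#'
#' @param cohort a [make_cohort()] result.
#' @param profile a [pipeline_profile()].
#' @param atlas per-vertex ROI labels from [build_synthetic_atlas()] on
#'   this profile's template.
#' @param template the template [triangle_mesh()] the atlas lives on.
#' @param subjects subset of subject ids (default all).
#' @param timepoints subset of visits (default all).
#' @param meshes if `TRUE`, also return per-subject deformed meshes.
#' @param deform_amplitude radial deformation amplitude (mm).
#' @param noise_fwhm smoothness of the measurement noise (mm).
#' @param seed noise seed (defaults like [observe_roi_table()]).
#' @return list with `maps` (named list `"subject|timepoint"` of
#'   [scalar_map()]) and `meshes` (named by subject, or `NULL`).
#' @export
render_pipeline_observation <- function(cohort, profile, atlas, template,
                                        subjects = NULL, timepoints = NULL,
                                        meshes = FALSE,
                                        deform_amplitude = 1,
                                        noise_fwhm = 20, seed = NULL) {
  stopifnot(length(atlas) == n_vertices(template))
  subjects <- subjects %||% cohort$subjects$subject
  timepoints <- timepoints %||% cohort$design$timepoints
  seed <- seed %||% (cohort$design$seed + 1000L * match(profile$name, c("CV", "FS"), nomatch = 3L) + 7L)
  adj <- .mesh_adjacency(template)
  e <- mesh_edges(template)
  elen <- mean(sqrt(rowSums((template$vertices[e[, 1L], , drop = FALSE] -
                               template$vertices[e[, 2L], , drop = FALSE])^2)))
  rounds <- max(1L, ceiling(2 * (noise_fwhm / 2.355 / elen)^2 / 3))
  vert_roi <- match(as.character(atlas), colnames(cohort$truth))
  si <- match(subjects, cohort$subjects$subject)
  ti <- match(timepoints, cohort$design$timepoints)
  ctr <- colMeans(template$vertices)
  dirs <- sweep(template$vertices, 2L, ctr)
  dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-9)
  bias <- 0
  if (meshes && profile$shape_bias_amplitude > 0) {
    bias <- .with_seed(sum(utf8ToInt(profile$name)) * 131L, {
      b <- .smooth_on_mesh(stats::rnorm(n_vertices(template)), adj, rounds)
      b / stats::sd(b) * profile$shape_bias_amplitude
    })
  }
  .with_seed(seed, {
    maps <- list()
    mesh_list <- if (meshes) list() else NULL
    for (a in seq_along(subjects)) {
      if (meshes) {
        raw <- stats::rnorm(n_vertices(template))
        sm <- .smooth_on_mesh(raw, adj, rounds)
        sm <- sm / stats::sd(sm) * deform_amplitude
        mesh_list[[subjects[a]]] <-
          triangle_mesh(template$vertices + dirs * (sm + bias),
                        template$faces, hemisphere = template$hemisphere)
      }
      for (k in ti) {
        shrink <- if (cohort$design$timepoints[k] == "BSL") 1 else
          profile$longitudinal_noise_shrink
        noise_sd <- profile$measurement_noise_sd * shrink
        base <- profile$thickness_scale * cohort$truth[si[a], vert_roi, k] +
          profile$additive_offset
        if (noise_sd > 0) {
          nz <- .smooth_on_mesh(stats::rnorm(length(base)), adj, rounds)
          nz <- nz / stats::sd(nz) * noise_sd
        } else nz <- 0
        key <- paste(subjects[a], cohort$design$timepoints[k], sep = "|")
        maps[[key]] <- scalar_map(pmax(base + nz, 0),
                                  mesh_id = paste0(profile$name, "-template"))
      }
    }
    list(maps = maps, meshes = mesh_list)
  })
}

#' Ground-truth smooth warp for registration recovery tests
#'
#' Draws random control-point displacements on a coarse B-spline lattice
#' and rescales them so the largest displacement over `probe_points` equals
#' `amplitude`. Small amplitudes relative to the control spacing keep the
#' transform invertible (positive Jacobian); a folding warning is issued
#' when `amplitude` exceeds 0.4x the smallest control spacing.
#'
#' @param seed integer seed.
#' @param amplitude maximal probe-point displacement (mm).
#' @param domain_lo,domain_hi warp domain corners (mm).
#' @param dims controls per axis (default 6).
#' @param probe_points points used to calibrate the amplitude.
#' @return a [control_lattice()] carrying the warp.
#' @export
make_synthetic_warp <- function(seed, amplitude, domain_lo, domain_hi,
                                dims = 6L, probe_points) {
  lat <- control_lattice(domain_lo, domain_hi, dims = dims)
  if (amplitude > 0.4 * min(lat$spacing)) {
    warning("amplitude large relative to control spacing: warp may fold")
  }
  if (amplitude == 0) return(lat)
  .with_seed(seed, {
    raw <- matrix(stats::rnorm(nrow(lat$disp) * 3L), ncol = 3L)
    lat$disp <- raw
    dv <- apply_ffd(lat, probe_points) - as.matrix(probe_points)
    lat$disp <- raw * (amplitude / max(sqrt(rowSums(dv^2))))
  })
  lat
}

#' Jacobian determinants of a free-form deformation
#'
#' Analytic spline Jacobian (identity plus displacement gradient) evaluated
#' by central finite differences of the C2 spline at the given points; used
#' to verify invertibility of synthetic warps.
#'
#' @param lattice a [control_lattice()].
#' @param points n x 3 matrix.
#' @param h differencing step (mm).
#' @return numeric vector of determinants.
#' @export
ffd_jacobian <- function(lattice, points, h = 1e-3) {
  points <- as.matrix(points)
  n <- nrow(points)
  J <- array(0, dim = c(n, 3L, 3L))
  for (ax in 1:3) {
    dp <- matrix(0, n, 3L); dp[, ax] <- h
    J[, , ax] <- (apply_ffd(lattice, points + dp) -
                    apply_ffd(lattice, points - dp)) / (2 * h)
  }
  J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
}
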