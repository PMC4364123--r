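#' Full-study run configuration
#'
#' Bundles all stage parameters of the two-workflow study (cross-sectional
#' and longitudinal): cohort design, the two pipeline profiles, template
#' geometry, registration settings, the statistical alphas (vertex FDR
#' 0.01; Tukey-Kramer 0.05 cross-sectional / 0.01 longitudinal) and the
#' effect-size gates (0.8 cross / 0.6 longitudinal). Desk-scale geometry
#' defaults — subdivision levels 4 (source) and 5 (target), radius 30 mm
#' hemispheres, 1.0 mm edge-map spacing, 12^3 lattice — preserve the
#' reference 4:1 between-pipeline vertex ratio at a size a single CPU
#' handles comfortably; the reference resolutions (levels 6/7, finer grid,
#' denser lattice) are plain parameter changes.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param design a [cohort_design()].
#' @param effect_config an [default_effect_config()].
#' @param cv,fs the two [pipeline_profile()]s.
#' @param hemisphere_radius,hemisphere_gap template geometry (mm).
#' @param grid_spacing edge-map spacing (mm).
#' @param lattice_dims registration control lattice (per axis).
#' @param reg registration settings ([registration_config()]).
#' @param fdr_alpha,tukey_alpha_cross,tukey_alpha_long,gate_cross,gate_long
#'   statistical thresholds.
#' @param n_template_subjects subjects per group used to build the average
#'   template surfaces (the reference design used 10 CTR + 10 sMCI + 10 AD).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       design = cohort_design(seed = seed),
                       effect_config = default_effect_config(),
                       cv = cv_profile(), fs = fs_profile(),
                       hemisphere_radius = 30, hemisphere_gap = 4,
                       grid_spacing = 1.0, lattice_dims = 12L,
                       reg = registration_config(),
                       fdr_alpha = 0.01, tukey_alpha_cross = 0.05,
                       tukey_alpha_long = 0.01,
                       gate_cross = 0.8, gate_long = 0.6,
                       n_template_subjects = 10L) {
  stopifnot(fdr_alpha > 0, fdr_alpha < 1, gate_cross > 0, gate_long > 0)
  structure(as.list(environment()), class = "run_config")
}

# the two-hemisphere icosphere template of one profile
.profile_template <- function(cfg, profile) {
  r <- cfg$hemisphere_radius
  cx <- r + cfg$hemisphere_gap / 2
  combine_hemispheres(
    build_icosphere(profile$resolution_subdiv, r, c(-cx, 0, 0), "left"),
    build_icosphere(profile$resolution_subdiv, r, c(cx, 0, 0), "right"))
}

#' Run the complete synthetic head-to-head study
#'
#' Executes the full stage chain: simulate the cohort; render both
#' pipelines' observations; build per-pipeline average surfaces from a
#' 10+10+10 template subset; register the source (CV) average onto the
#' target (FS) average through the edge map / GVF / FFD chain; establish
#' closest-point correspondence; assemble the hybrid per-subject thickness
#' dataset; compute vertex-wise contrast maps with FDR control,
#' disease-effect and overlap maps; ROI tables with Tukey-Kramer
#' post-hocs, Hedges g comparisons, thinning percentages and covariate
#' correlations with Steiger tests; and the gated forward-selected
#' logistic ROC comparison. Month-12 observations are generated but — as
#' in the reference analysis — only baseline and month 24 enter the
#' reports. Deterministic: identical configs give identical outputs.
#'
#' @param cfg a [run_config()].
#' @param stages subset of stage names to run (mainly for testing);
#'   downstream stages of a skipped stage are skipped too.
#' @return list of class `run_manifest` with per-stage results and timings.
#' @export
run_full_study <- function(cfg = run_config(),
                           stages = c("simulate", "register", "correspond",
                                      "vertex", "roi", "roc")) {
  man <- list(config = cfg, stages = list(), started = Sys.time())
  tic <- function() proc.time()[["elapsed"]]
  res <- list()

  ## simulate ---------------------------------------------------------------
  t0 <- tic()
  cohort <- make_cohort(cfg$design, cfg$effect_config)
  tmpl_cv <- .profile_template(cfg, cfg$cv)
  tmpl_fs <- .profile_template(cfg, cfg$fs)
  atlas_cv <- build_synthetic_atlas(tmpl_cv, seed = cfg$seed)
  atlas_fs <- build_synthetic_atlas(tmpl_fs, seed = cfg$seed)
  obs_cv <- render_pipeline_observation(cohort, cfg$cv, atlas_cv, tmpl_cv)
  obs_fs <- render_pipeline_observation(cohort, cfg$fs, atlas_fs, tmpl_fs)
  res$cohort <- cohort
  man$stages$simulate <- list(ok = TRUE, seconds = tic() - t0,
                              n_subjects = nrow(cohort$subjects))
  if (!"register" %in% stages) return(.finish_manifest(man, res))

  ## register ---------------------------------------------------------------
  t0 <- tic()
  sub <- cohort$subjects
  tpl_ids <- unlist(lapply(c("CTR", "sMCI", "AD"), function(g) {
    utils::head(sub$subject[sub$group == g], cfg$n_template_subjects)
  }))
  mesh_set <- function(profile, atlas, tmpl) {
    render_pipeline_observation(cohort, profile, atlas, tmpl,
                                subjects = tpl_ids, timepoints = "BSL",
                                meshes = TRUE)$meshes
  }
  avg_cv <- average_surface(mesh_set(cfg$cv, atlas_cv, tmpl_cv))
  avg_fs <- average_surface(mesh_set(cfg$fs, atlas_fs, tmpl_fs))
  em <- voxelize_and_edge_map(avg_fs, spacing = cfg$grid_spacing)
  gvf <- compute_gvf(em, cfg$reg)
  bb <- apply(rbind(avg_cv$vertices, avg_fs$vertices), 2L, range)
  pad <- 2 * cfg$grid_spacing
  lat <- control_lattice(bb[1L, ] - pad, bb[2L, ] + pad,
                         dims = cfg$lattice_dims)
  regres <- ffd_register(avg_cv, gvf, lat, cfg$reg, validate = FALSE)
  pre <- surface_distance(avg_cv, avg_fs)$mean_distance
  post <- surface_distance(regres$mesh, avg_fs)$mean_distance
  res$registration <- list(pre_mm = pre, post_mm = post,
                           ratio = post / pre, lattice = regres$lattice)
  man$stages$register <- list(ok = TRUE, seconds = tic() - t0,
                              pre_mm = pre, post_mm = post)
  if (!"correspond" %in% stages) return(.finish_manifest(man, res))

  ## correspond ---------------------------------------------------------------
  t0 <- tic()
  corr <- closest_point_search(regres$mesh$vertices, avg_fs$vertices)
  hybrid <- build_hybrid_dataset(obs_cv$maps, obs_fs$maps, corr)
  res$hybrid <- hybrid
  man$stages$correspond <- list(ok = TRUE, seconds = tic() - t0,
                                n_records = nrow(hybrid$records),
                                n_vertices = nrow(hybrid$thickness_cv),
                                mean_match_mm = mean(corr$match_distance))
  if (!"vertex" %in% stages) return(.finish_manifest(man, res))

  ## vertex stats -------------------------------------------------------------
  t0 <- tic()
  rec <- hybrid$records
  grp <- cohort$subjects$group[match(rec$subject, cohort$subjects$subject)]
  pick <- function(mat, g, tp) mat[, grp == g & rec$timepoint == tp, drop = FALSE]
  vertex <- list()
  for (pl in c("CV", "FS")) {
    mat <- if (pl == "CV") hybrid$thickness_cv else hybrid$thickness_fs
    cross <- lapply(c("sMCI", "pMCI", "AD"), function(g) {
      sm <- group_diff_map(pick(mat, "CTR", "BSL"), pick(mat, g, "BSL"),
                           contrast = paste0("CTR-", g))
      sm$fdr <- fdr_correct(sm$p, cfg$fdr_alpha)
      sm
    })
    names(cross) <- c("sMCI", "pMCI", "AD")
    long <- lapply(names(cfg$design$groups), function(g) {
      sm <- paired_t_map(pick(mat, g, "BSL"), pick(mat, g, "M24"),
                         contrast = paste0(g, ":BSL-M24"))
      sm$fdr <- fdr_correct(sm$p, cfg$fdr_alpha)
      sm
    })
    names(long) <- names(cfg$design$groups)
    vertex[[pl]] <- list(cross = cross, long = long)
  }
  vertex$disease_effect <- lapply(c("sMCI", "pMCI", "AD"), function(g) {
    disease_effect_map(vertex$FS$cross[[g]]$delta, vertex$CV$cross[[g]]$delta,
                       contrast = paste0("CTR-", g))
  })
  names(vertex$disease_effect) <- c("sMCI", "pMCI", "AD")
  vertex$overlap <- lapply(c("sMCI", "pMCI", "AD"), function(g) {
    overlap_map(vertex$CV$cross[[g]]$fdr$mask, vertex$FS$cross[[g]]$fdr$mask)
  })
  names(vertex$overlap) <- c("sMCI", "pMCI", "AD")
  res$vertex <- vertex
  man$stages$vertex <- list(ok = TRUE, seconds = tic() - t0)
  if (!"roi" %in% stages) return(.finish_manifest(man, res))

  ## roi stats ----------------------------------------------------------------
  t0 <- tic()
  tab <- rbind(roi_aggregate(obs_cv$maps, atlas_cv, cohort, "CV"),
               roi_aggregate(obs_fs$maps, atlas_fs, cohort, "FS"))
  roi <- list(table = tab)
  roi$cross_tukey <- lapply(split(tab[tab$timepoint == "BSL", ],
                                  tab$pipeline[tab$timepoint == "BSL"]),
                            roi_anova_tukey, alpha = cfg$tukey_alpha_cross)
  ch <- longitudinal_change(tab)
  roi$long_tukey <- lapply(split(ch, ch$pipeline), roi_anova_tukey,
                           value = "change", alpha = cfg$tukey_alpha_long)
  # Hedges g per ROI / pipeline, cross-sectional CTR vs AD and CTR vs pMCI
  g_of <- function(d, gA, gB, col) {
    a <- d[[col]][d$group == gA]; b <- d[[col]][d$group == gB]
    hedges_g_data(a, b)
  }
  eff <- list()
  for (pl in c("CV", "FS")) {
    b <- tab[tab$pipeline == pl & tab$timepoint == "BSL", ]
    for (g in c("pMCI", "AD")) {
      eff[[paste(pl, g, sep = ".")]] <-
        do.call(rbind, lapply(split(b, b$roi_id), function(d) {
          gg <- g_of(d, "CTR", g, "thickness")
          data.frame(roi_id = d$roi_id[1L], g = gg$g, se_g = gg$se_g)
        }))
    }
  }
  roi$effect_sizes <- eff
  roi$effect_comparison <- lapply(c("pMCI", "AD"), function(g) {
    cv <- eff[[paste("CV", g, sep = ".")]]
    fs <- eff[[paste("FS", g, sep = ".")]]
    do.call(rbind, lapply(seq_len(nrow(cv)), function(i) {
      cmp <- compare_effect_sizes(
        structure(list(g = cv$g[i], se_g = cv$se_g[i]), class = "effect_size_result"),
        structure(list(g = fs$g[i], se_g = fs$se_g[i]), class = "effect_size_result"))
      data.frame(roi_id = cv$roi_id[i], g_cv = cv$g[i], g_fs = fs$g[i],
                 z = cmp$z, p = cmp$p)
    }))
  })
  names(roi$effect_comparison) <- c("pMCI", "AD")
  roi$thinning_cross <- thinning_percent(tab, "cross")
  roi$thinning_long <- thinning_percent(tab, "longitudinal")
  # correlations with MMSE and hippocampal volume, CTR and pMCI
  cors <- list()
  for (g in c("CTR", "pMCI")) {
    for (cv_ in c("mmse_bsl", "hippo_volume")) {
      cors[[paste(g, cv_, sep = ".")]] <-
        pearson_by_roi(tab, cohort$covariates, cv_, group = g)
    }
  }
  roi$correlations <- cors
  # Steiger comparison of the two pipelines' r per ROI (shared covariate)
  roi$steiger <- lapply(names(cors), function(nm) {
    cr <- cors[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    b <- tab[tab$timepoint == "BSL" & tab$group == parts[1L], ]
    do.call(rbind, lapply(split(cr, cr$roi_id), function(d) {
      if (nrow(d) != 2L) return(NULL)
      dd <- b[b$roi_id == d$roi_id[1L], ]
      w <- stats::reshape(dd[, c("subject", "pipeline", "thickness")],
                          idvar = "subject", timevar = "pipeline",
                          direction = "wide")
      r12 <- stats::cor(w$thickness.CV, w$thickness.FS)
      st <- steiger_z(d$r[d$pipeline == "CV"], d$r[d$pipeline == "FS"],
                      r12, n = d$n[1L])
      data.frame(roi_id = d$roi_id[1L], covariate = nm,
                 r_cv = d$r[d$pipeline == "CV"], r_fs = d$r[d$pipeline == "FS"],
                 r12 = r12, z = st$z, p = st$p)
    }))
  })
  names(roi$steiger) <- names(cors)
  res$roi <- roi
  man$stages$roi <- list(ok = TRUE, seconds = tic() - t0)
  if (!"roc" %in% stages) return(.finish_manifest(man, res))

  ## roc ----------------------------------------------------------------------
  t0 <- tic()
  roc <- list()
  run_contrast <- function(mode, pos_group, gate, eff_key) {
    out <- list()
    for (pl in c("CV", "FS")) {
      fm <- roi_feature_matrix(tab, pl, mode)
      keep <- fm$groups %in% c("CTR", pos_group)
      X <- fm$X[keep, , drop = FALSE]
      y <- as.numeric(fm$groups[keep] == pos_group)
      eff_pl <- if (mode == "cross") roi$effect_sizes[[paste(pl, pos_group, sep = ".")]] else {
        chp <- ch[ch$pipeline == pl, ]
        do.call(rbind, lapply(split(chp, chp$roi_id), function(d) {
          gg <- g_of(d, "CTR", pos_group, "change")
          data.frame(roi_id = d$roi_id[1L], g = gg$g)
        }))
      }
      cand <- gate_candidates(eff_pl, gate)
      if (!nrow(cand)) {
        # gate emptied the candidate list (synthetic effects below the
        # threshold): fall back to the highest-effect ROIs, flagged
        cand <- utils::head(gate_candidates(eff_pl, 0), 3L)
        out[[paste0(pl, "_gate_relaxed")]] <- TRUE
      }
      sel <- forward_select(X, y, cand$roi_id, folds = 5L,
                            seed = cfg$seed + 17L)
      fit <- fit_logistic_score(X[, sel$selected, drop = FALSE], y)
      out[[pl]] <- roc_auc(fit$scores, y, selected_rois = sel$selected)
      out[[paste0(pl, "_cv_auc")]] <- utils::tail(sel$cv_auc, 1L)
    }
    if (!is.null(out$CV) && !is.null(out$FS)) {
      out$comparison <- compare_auc(out$CV, out$FS)
    }
    out
  }
  roc$cross_pmci <- run_contrast("cross", "pMCI", cfg$gate_cross)
  roc$cross_ad <- run_contrast("cross", "AD", cfg$gate_cross)
  roc$long_pmci <- run_contrast("longitudinal", "pMCI", cfg$gate_long)
  res$roc <- roc
  man$stages$roc <- list(ok = TRUE, seconds = tic() - t0)
  .finish_manifest(man, res)
}

.finish_manifest <- function(man, res) {
  man$results <- res
  man$finished <- Sys.time()
  class(man) <- "run_manifest"
  man
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest: stages",
      paste(names(x$stages), collapse = " -> "), "\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-10s %6.1f s\n", nm, st$seconds))
  }
  invisible(x)
}

#' Human-readable study report
#'
#' Renders the manifest's result tables (registration quality, vertex-map
#' counts, ROI Tukey-Kramer flags, effect sizes, correlations, ROC) as a
#' markdown summary, without recomputing anything.
#'
#' @param manifest a [run_full_study()] manifest.
#' @return character vector of markdown lines (invisibly printed).
#' @export
report <- function(manifest) {
  r <- manifest$results
  ln <- c("# Synthetic head-to-head cortical thickness comparison", "")
  if (is.null(r) || !length(r)) {
    return(c(ln, "(empty run: no stages completed)"))
  }
  if (!is.null(r$cohort)) {
    ln <- c(ln, "## Cohort",
            sprintf("- %d subjects (%s)", nrow(r$cohort$subjects),
                    paste(names(manifest$config$design$groups),
                          manifest$config$design$groups,
                          sep = ":", collapse = ", ")), "")
  }
  if (!is.null(r$registration)) {
    ln <- c(ln, "## Registration",
            sprintf("- mean surface distance %.2f mm -> %.2f mm (ratio %.2f)",
                    r$registration$pre_mm, r$registration$post_mm,
                    r$registration$ratio), "")
  }
  if (!is.null(r$vertex)) {
    ln <- c(ln, "## Vertex-wise maps (FDR-corrected)")
    for (g in names(r$vertex$overlap)) {
      ct <- r$vertex$overlap[[g]]$counts
      ln <- c(ln, sprintf("- CTR vs %s: both %d, CV-only %d, FS-only %d",
                          g, ct[["both"]], ct[["civet_only"]],
                          ct[["freesurfer_only"]]))
    }
    ln <- c(ln, "")
  }
  if (!is.null(r$roi)) {
    ln <- c(ln, "## ROI analysis")
    for (pl in names(r$roi$long_tukey)) {
      tk <- r$roi$long_tukey[[pl]]
      nf <- sum(tk$flag[tk$group1 == "CTR" & tk$group2 == "AD"])
      ln <- c(ln, sprintf("- %s: %d/28 ROIs with significant CTR-AD longitudinal thinning difference",
                          pl, nf))
    }
    ln <- c(ln, "")
  }
  if (!is.null(r$roc)) {
    ln <- c(ln, "## Discrimination (AUC)")
    for (nm in names(r$roc)) {
      rr <- r$roc[[nm]]
      if (is.null(rr$CV) || is.null(rr$FS)) next
      ln <- c(ln, sprintf("- %s: CV %.4f vs FS %.4f (z = %.2f, r = %.2f, p = %.3f)",
                          nm, rr$CV$auc, rr$FS$auc, rr$comparison$z,
                          rr$comparison$r, rr$comparison$p))
    }
    ln <- c(ln, "")
  }
  ln
}
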