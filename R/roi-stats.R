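# ROI-level group statistics: one-way ANOVA with Tukey-Kramer post-hocs,
# Hedges g effect sizes with cross-pipeline z comparison, thinning
# percentages, and the correlation machinery (Pearson, Steiger Z, Kendall
# tau with Greiner conversion).

#' Tukey-Kramer pairwise comparisons from group summaries
#'
#' Studentized-range post-hoc after one-way ANOVA, with the Kramer
#' correction for unequal group sizes: for groups i, j the statistic is
#' `q = |m_i - m_j| / sqrt(MSW/2 * (1/n_i + 1/n_j))` referred to the
#' studentized range with k groups and N - k error df. With equal n this
#' reduces to the classic Tukey HSD. Operating on summary statistics
#' (means, SDs, ns) makes the same routine usable both on raw data and on
#' printed summary tables.
#'
#' @param means,sds,ns numeric vectors, one entry per group (ns >= 2).
#' @param alpha family-wise level (0.05 cross-sectional, 0.01 longitudinal
#'   in the reference analysis).
#' @return list with `omnibus_p` (one-way ANOVA F test), `pairs` data frame
#'   (group1, group2, diff, q, p, flag), `msw`, `df`, `q_critical`.
#' @export
tukey_kramer <- function(means, sds, ns, alpha = 0.05) {
  k <- length(means)
  stopifnot(length(sds) == k, length(ns) == k, k >= 2L)
  if (any(ns < 2L)) stop("every group needs n >= 2")
  nms <- names(means) %||% as.character(seq_len(k))
  df <- sum(ns) - k
  msw <- sum((ns - 1) * sds^2) / df
  grand <- sum(ns * means) / sum(ns)
  msb <- sum(ns * (means - grand)^2) / (k - 1)
  omnibus_p <- stats::pf(msb / pmax(msw, 1e-300), k - 1, df,
                         lower.tail = FALSE)
  qc <- stats::qtukey(1 - alpha, k, df)
  ij <- utils::combn(k, 2L)
  diff <- means[ij[2L, ]] - means[ij[1L, ]]
  se <- sqrt(msw / 2 * (1 / ns[ij[1L, ]] + 1 / ns[ij[2L, ]]))
  q <- abs(diff) / pmax(se, 1e-300)
  p <- stats::ptukey(q, k, df, lower.tail = FALSE)
  pairs <- data.frame(group1 = nms[ij[1L, ]], group2 = nms[ij[2L, ]],
                      diff = as.numeric(diff), q = as.numeric(q),
                      p = as.numeric(p), flag = as.vector(q > qc),
                      stringsAsFactors = FALSE)
  list(omnibus_p = omnibus_p, pairs = pairs, msw = msw, df = df,
       q_critical = qc)
}

#' One-way ANOVA + Tukey-Kramer over the ROIs of a table
#'
#' Applies [tukey_kramer()] ROI by ROI to per-subject values (baseline
#' thickness or longitudinal change) grouped by diagnosis.
#'
#' @param table a `roi_table` data frame (one pipeline/timepoint slice, or
#'   a change table from [longitudinal_change()]).
#' @param value name of the value column.
#' @param alpha family-wise level.
#' @return data frame with one row per ROI x group pair: omnibus p,
#'   pairwise q/p/flag.
#' @export
roi_anova_tukey <- function(table, value = "thickness", alpha = 0.05) {
  do.call(rbind, lapply(split(table, table$roi_id), function(d) {
    gs <- split(d[[value]], factor(d$group, levels = unique(d$group)))
    if (any(lengths(gs) < 2L)) stop("group with fewer than 2 subjects")
    tk <- tukey_kramer(vapply(gs, mean, 0), vapply(gs, stats::sd, 0),
                       lengths(gs), alpha = alpha)
    cbind(roi_id = d$roi_id[1L], omnibus_p = tk$omnibus_p, tk$pairs)
  }))
}

#' Per-subject longitudinal change table
#'
#' Follow-up minus baseline thickness per subject/ROI/pipeline; subjects
#' missing either visit are dropped with a warning.
#'
#' @param table a `roi_table`.
#' @param from,to timepoint labels.
#' @return data frame like the input with a `change` column (mm).
#' @export
longitudinal_change <- function(table, from = "BSL", to = "M24") {
  b <- table[table$timepoint == from, ]
  f <- table[table$timepoint == to, ]
  key <- function(d) paste(d$subject, d$pipeline, d$roi_id)
  m <- match(key(b), key(f))
  if (anyNA(m)) warning(sum(is.na(m)), " record(s) missing the follow-up visit")
  ok <- !is.na(m)
  out <- b[ok, c("subject", "group", "pipeline", "roi_id")]
  out$baseline <- b$thickness[ok]
  out$change <- f$thickness[m[ok]] - b$thickness[ok]
  out
}

#' Hedges g standardized effect size
#'
#' Pooled-SD standardized mean difference with the small-sample correction
#' `J = 1 - 3 / (4(n1+n2) - 9)`; the variance follows the usual
#' large-sample expression `se^2 = (n1+n2)/(n1 n2) + g^2 / (2(n1+n2))`.
#'
#' @param mean1,sd1,n1 summary statistics of the first group.
#' @param mean2,sd2,n2 summary statistics of the second group.
#' @return object of class `effect_size_result`: `g`, `se_g`, `J`, `n1`,
#'   `n2`.
#' @export
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2L || n2 < 2L) stop("need n >= 2 per group")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled SD")
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  g <- J * (mean1 - mean2) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
  structure(list(g = g, se_g = se, J = J, n1 = n1, n2 = n2),
            class = "effect_size_result")
}

#' @rdname hedges_g
#' @param x,y raw samples of the two groups.
#' @export
hedges_g_data <- function(x, y) {
  hedges_g(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

#' Cross-pipeline comparison of two effect sizes
#'
#' Two-sided z-test of the difference of two Hedges g values computed on
#' the same contrast by different pipelines, treating the two estimates as
#' independent (`z = (g1-g2)/sqrt(se1^2+se2^2)`). A paired-bootstrap
#' alternative would condition on the shared subjects and is statistically
#' more defensible, but the simple z matches the reference analysis.
#'
#' @param g1,g2 [hedges_g()] results on the same contrast.
#' @return list with `z` and two-sided `p`.
#' @export
compare_effect_sizes <- function(g1, g2) {
  z <- (g1$g - g2$g) / sqrt(g1$se_g^2 + g2$se_g^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Thinning percentages
#'
#' Longitudinal mode: per-subject percentage change
#' `100 * (M24 - BSL) / BSL`, averaged within groups. Cross-sectional mode:
#' percentage difference of group mean baseline thickness relative to the
#' control group, `100 * (group - CTR) / CTR`.
#'
#' @param table a `roi_table`.
#' @param mode `"longitudinal"` or `"cross"`.
#' @param reference control group name (cross mode).
#' @return data frame of percentages per pipeline x ROI x group.
#' @export
thinning_percent <- function(table, mode = c("longitudinal", "cross"),
                             reference = "CTR") {
  mode <- match.arg(mode)
  if (mode == "longitudinal") {
    ch <- longitudinal_change(table)
    ch$pct <- 100 * ch$change / ch$baseline
    out <- stats::aggregate(pct ~ pipeline + roi_id + group, data = ch, FUN = mean)
  } else {
    b <- table[table$timepoint == "BSL", ]
    mns <- stats::aggregate(thickness ~ pipeline + roi_id + group, data = b,
                            FUN = mean)
    ref <- mns[mns$group == reference, ]
    m <- match(paste(mns$pipeline, mns$roi_id),
               paste(ref$pipeline, ref$roi_id))
    mns$pct <- 100 * (mns$thickness - ref$thickness[m]) / ref$thickness[m]
    out <- mns[mns$group != reference, c("pipeline", "roi_id", "group", "pct")]
  }
  out
}

#' Pearson correlation of ROI thickness with a covariate
#'
#' Product-moment correlation per ROI and pipeline between thickness (or
#' change) and a per-subject covariate, within one group.
#'
#' @param table a `roi_table` (or change table with a `value` column).
#' @param covariates data frame with `subject` and the covariate column.
#' @param covariate covariate column name.
#' @param group diagnostic group to correlate within.
#' @param timepoint visit at which to take the thickness.
#' @param value value column of `table`.
#' @return data frame of class `correlation_result`: roi_id, pipeline, r,
#'   n, covariate.
#' @export
pearson_by_roi <- function(table, covariates, covariate, group,
                           timepoint = "BSL", value = "thickness") {
  d <- table[table$group == group &
               (is.null(table$timepoint) | table$timepoint == timepoint), ]
  co <- covariates[[covariate]][match(d$subject, covariates$subject)]
  if (stats::sd(co, na.rm = TRUE) == 0) stop("constant covariate")
  out <- do.call(rbind, lapply(split(seq_len(nrow(d)), paste(d$pipeline, d$roi_id)),
                               function(ix) {
    n <- length(ix)
    if (n < 4L) stop("need n >= 4 per ROI")
    data.frame(roi_id = d$roi_id[ix[1L]], pipeline = d$pipeline[ix[1L]],
               r = stats::cor(d[[value]][ix], co[ix]), n = n,
               covariate = covariate, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Steiger's Z for two dependent correlations sharing one variable
#'
#' Tests `r1 = cor(x1, y)` against `r2 = cor(x2, y)` (one variable in
#' common) given `r12 = cor(x1, x2)`, using Fisher transforms and the
#' back-transformed average correlation (Steiger's Z1*). Antisymmetric in
#' (r1, r2); requires all correlations strictly inside (-1, 1).
#'
#' @param r1,r2 the two dependent correlations with the shared variable.
#' @param r12 correlation between the two non-shared variables.
#' @param n sample size (>= 10).
#' @return list with `z` and two-sided `p`.
#' @export
steiger_z <- function(r1, r2, r12, n) {
  if (any(abs(c(r1, r2, r12)) >= 1)) stop("correlations must be inside (-1,1)")
  if (n < 10L) stop("need n >= 10")
  z1 <- atanh(r1); z2 <- atanh(r2)
  rbar <- tanh((z1 + z2) / 2)  # back-transformed average
  f <- (1 - r12) / (2 * (1 - rbar^2))
  f <- min(f, 1)
  h <- (1 - f * rbar^2) / (1 - rbar^2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Kendall's tau with conversion to a Pearson-scale coefficient
#'
#' Tau-b rank correlation, its normal-approximation z, and the Greiner
#' relation `r = sin(pi * tau / 2)` mapping tau to the Pearson correlation
#' it implies under bivariate normality — the conversion used when feeding
#' rank correlations into the correlated-AUC machinery.
#'
#' @param x,y numeric vectors (n >= 10, not all tied).
#' @return list with `tau`, `z_tau`, `r_equivalent`, `n`.
#' @export
kendall_with_conversion <- function(x, y) {
  n <- length(x)
  if (n < 10L) stop("need n >= 10")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("all-tied input")
  tau <- stats::cor(x, y, method = "kendall")
  z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  list(tau = tau, z_tau = z, r_equivalent = sin(pi * tau / 2), n = n)
}

#' Recompute the longitudinal table's Tukey-Kramer flags from its printed
#' summaries
#'
#' Re-runs [tukey_kramer()] on the printed per-group means/SDs (group sizes
#' from the demographics table) of the packaged longitudinal ROI table and
#' compares the four flagged pairs (CTR-pMCI, CTR-AD, sMCI-pMCI, sMCI-AD)
#' against the printed significance marks. Cells whose decision flips when
#' every printed summary is perturbed by half its printing precision
#' (0.005) are reported as `marginal` (rounding-sensitive).
#'
#' @param alpha family-wise level (the reference longitudinal analysis used
#'   0.01).
#' @param precision half printing unit used for the marginal check.
#' @return list with `cells` (per pipeline/ROI/pair: printed, recomputed,
#'   agree, marginal), `agreement` (fraction agreeing over all cells) and
#'   `agreement_stable` (over non-marginal cells).
#' @export
recompute_longitudinal_flags <- function(alpha = 0.01, precision = 0.005) {
  t4 <- load_fixture_table("T4")$records
  t1 <- load_fixture_table("T1")$records
  ns <- stats::setNames(t1$n, t1$group)[c("CTR", "sMCI", "pMCI", "AD")]
  pairs <- list(ctr_pmci = c(1L, 3L), ctr_ad = c(1L, 4L),
                smci_pmci = c(2L, 3L), smci_ad = c(2L, 4L))
  flags_at <- function(means, sds) {
    tk <- tukey_kramer(means, sds, ns, alpha = alpha)
    key <- paste(tk$pairs$group1, tk$pairs$group2)
    vapply(pairs, function(ij) {
      tk$pairs$flag[key == paste(names(ns)[ij[1L]], names(ns)[ij[2L]])]
    }, logical(1L))
  }
  cells <- do.call(rbind, lapply(seq_len(nrow(t4)), function(i) {
    means <- stats::setNames(unlist(t4[i, c("d_ctr", "d_smci", "d_pmci", "d_ad")]),
                             names(ns))
    sds <- unlist(t4[i, c("s_ctr", "s_smci", "s_pmci", "s_ad")])
    rec <- flags_at(means, sds)
    # rounding sensitivity: push each pair's difference and the pooled SD
    # both ways by the printing precision
    marg <- vapply(seq_along(pairs), function(k) {
      ij <- pairs[[k]]
      up <- means; up[ij[2L]] <- up[ij[2L]] + precision
      up[ij[1L]] <- up[ij[1L]] - precision
      dn <- means; dn[ij[2L]] <- dn[ij[2L]] - precision
      dn[ij[1L]] <- dn[ij[1L]] + precision
      any(flags_at(up, pmax(sds - precision, 1e-4))[k] != rec[k],
          flags_at(dn, sds + precision)[k] != rec[k])
    }, logical(1L))
    printed <- unlist(t4[i, c("flag_ctr_pmci", "flag_ctr_ad",
                              "flag_smci_pmci", "flag_smci_ad")]) == 1
    data.frame(pipeline = t4$pipeline[i], roi_id = t4$roi_id[i],
               pair = names(pairs), printed = unname(printed),
               recomputed = unname(rec), marginal = marg,
               stringsAsFactors = FALSE)
  }))
  cells$agree <- cells$printed == cells$recomputed
  list(cells = cells,
       agreement = mean(cells$agree),
       agreement_stable = mean(cells$agree[!cells$marginal]))
}
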