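# Vertex-wise statistics on hybrid-template thickness arrays.
# Maps are vertex x subject matrices; all tests are massively vectorised
# and each vertex's p-value equals the corresponding single-vertex test.

.new_stat_map <- function(statistic, p, delta, contrast, n, zero_variance) {
  structure(list(statistic = statistic, p = p, delta = delta,
                 contrast = contrast, n = n, zero_variance = zero_variance),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map [%s]: %d vertices, %d with p < 0.01 (uncorrected)\n",
              x$contrast, length(x$p), sum(x$p < 0.01)))
  invisible(x)
}

#' Vertex-wise paired t map (within-group thinning)
#'
#' Paired two-sided t-test per vertex between two visits of the same
#' subjects; `delta` is the mean change (follow-up minus baseline, so
#' thinning is negative). Vertices with zero change variance are flagged
#' and given p = 1.
#'
#' @param maps_t0,maps_t1 vertex x subject matrices (same subjects, same
#'   column order).
#' @param contrast label stored in the result.
#' @return a `stat_map` with `statistic`, `p`, `delta` (mm), `n`.
#' @export
paired_t_map <- function(maps_t0, maps_t1, contrast = "t1-t0") {
  if (!all(dim(maps_t0) == dim(maps_t1))) stop("map dimensions differ")
  n <- ncol(maps_t0)
  if (n < 3L) stop("need at least 3 paired subjects")
  d <- maps_t1 - maps_t0
  delta <- rowMeans(d)
  sdd <- sqrt(rowSums((d - delta)^2) / (n - 1))
  zv <- sdd == 0
  tt <- ifelse(zv, 0, delta / (sdd / sqrt(n)))
  p <- ifelse(zv, 1, 2 * stats::pt(-abs(tt), df = n - 1))
  .new_stat_map(tt, p, delta, contrast, c(n = n), zv)
}

#' Vertex-wise two-sample (Welch) t map between groups
#'
#' Welch's unequal-variance t-test per vertex; `delta` is group B minus
#' group A mean thickness (atrophy in B relative to A is negative).
#'
#' @param maps_a,maps_b vertex x subject matrices of the two groups.
#' @param contrast label stored in the result.
#' @return a `stat_map`.
#' @export
group_diff_map <- function(maps_a, maps_b, contrast = "B-A") {
  na <- ncol(maps_a); nb <- ncol(maps_b)
  if (na < 3L || nb < 3L) stop("need at least 3 subjects per group")
  ma <- rowMeans(maps_a); mb <- rowMeans(maps_b)
  va <- rowSums((maps_a - ma)^2) / (na - 1)
  vb <- rowSums((maps_b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  zv <- se2 == 0
  tt <- ifelse(zv, 0, (mb - ma) / sqrt(se2))
  df <- ifelse(zv, 1,
               se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1))))
  p <- ifelse(zv, 1, 2 * stats::pt(-abs(tt), df = df))
  .new_stat_map(tt, p, mb - ma, contrast, c(nA = na, nB = nb), zv)
}

#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up procedure over the vertex p-values at level `alpha`; returns the
#' rejection mask and the largest rejected p (the effective vertex-wise
#' threshold).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (0.01 in the reference maps).
#' @return list with logical `mask` and numeric `threshold` (`NA` if no
#'   rejection).
#' @export
fdr_correct <- function(pvals, alpha = 0.01) {
  if (!length(pvals)) return(list(mask = logical(0), threshold = NA_real_))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  mask <- !is.na(adj) & adj <= alpha
  list(mask = mask,
       threshold = if (any(mask)) max(pvals[mask]) else NA_real_)
}

#' Disease-effect map (pipeline difference of thickness changes)
#'
#' Per-vertex difference `delta_FS - delta_CV` between the two pipelines'
#' thickness changes for the same contrast (between groups or between
#' timepoints). Negative values mean the FS-style pipeline registers more
#' atrophy at that vertex; swapping the arguments flips the sign exactly.
#'
#' @param delta_fs,delta_cv numeric vectors (or [scalar_map()]s) of the two
#'   pipelines' deltas on the hybrid template (mm).
#' @param contrast contrast descriptor (e.g. `"CTR-AD"` or `"BSL-M24"`).
#' @return object of class `disease_effect_map` with `values` and
#'   `contrast`.
#' @export
disease_effect_map <- function(delta_fs, delta_cv, contrast = "") {
  if (inherits(delta_fs, "scalar_map")) delta_fs <- delta_fs$values
  if (inherits(delta_cv, "scalar_map")) delta_cv <- delta_cv$values
  if (length(delta_fs) != length(delta_cv)) stop("delta lengths differ")
  structure(list(values = delta_fs - delta_cv, contrast = contrast),
            class = "disease_effect_map")
}

#' Overlap categorization of two significance masks
#'
#' Partitions the template vertices into `both`, `civet_only`,
#' `freesurfer_only` and `neither` according to the two pipelines'
#' FDR-corrected significance masks.
#'
#' @param mask_cv,mask_fs logical vectors on the same template.
#' @return object of class `overlap_map`: factor `category` plus the
#'   category `counts`.
#' @export
overlap_map <- function(mask_cv, mask_fs) {
  if (length(mask_cv) != length(mask_fs)) stop("mask lengths differ")
  cat_ <- ifelse(mask_cv & mask_fs, "both",
                 ifelse(mask_cv, "civet_only",
                        ifelse(mask_fs, "freesurfer_only", "neither")))
  cat_ <- factor(cat_, levels = c("both", "civet_only", "freesurfer_only",
                                  "neither"))
  structure(list(category = cat_, counts = table(cat_)),
            class = "overlap_map")
}
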