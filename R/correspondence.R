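#' Closest point search between two vertex sets
#'
#' For every source point, finds the index of the globally nearest target
#' point in Euclidean distance. This is the correspondence step that pairs
#' the two pipelines' thickness arrays on the hybrid template: matching is
#' vertex-to-vertex (thickness exists only at vertices) and one-directional,
#' source onto target. Distance ties are broken by the lowest target index
#' so the result is deterministic and equal to an exhaustive search.
#'
#' For small problems the search is an exact chunked brute force (distance
#' blocks formed with BLAS-level matrix products). Large problems are
#' routed through a coarse-anchor two-stage search that prunes candidates
#' by the triangle inequality; the pruning bound guarantees the result
#' (indices and distances) is identical to the brute force, which the test
#' suite verifies directly.
#'
#' @param source_points,target_points numeric matrices (n x 3, m x 3), mm.
#' @param chunk number of source points per distance block.
#' @param method `"auto"` (default: hierarchical when both sets are large),
#'   `"bruteforce"`, or `"hierarchical"`.
#' @return object of class `correspondence`: list with integer
#'   `match_index` (length n, 1-based into the target) and numeric
#'   `match_distance` (mm).
#' @export
closest_point_search <- function(source_points, target_points, chunk = 2048L,
                                 method = c("auto", "bruteforce",
                                            "hierarchical")) {
  method <- match.arg(method)
  s <- as.matrix(source_points); t <- as.matrix(target_points)
  if (nrow(s) == 0L) stop("empty source point set")
  if (nrow(t) == 0L) stop("empty target point set")
  use_hier <- switch(method,
                     auto = nrow(t) >= 4096L && nrow(s) >= 2048L,
                     bruteforce = FALSE,
                     hierarchical = TRUE)
  res <- if (use_hier) .cps_hier(s, t, chunk = chunk) else
    .cps_brute(s, t, chunk = chunk)
  structure(res, class = "correspondence")
}

.cps_brute <- function(s, t, chunk = 2048L) {
  t2 <- rowSums(t^2)
  n <- nrow(s)
  idx <- integer(n); dst <- numeric(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    sb <- s[lo:hi, , drop = FALSE]
    # argmin_j |s-t_j|^2 = argmax_j (2 s.t_j - |t_j|^2); the |s|^2 term is
    # constant per row and dropped
    score <- sweep(2 * tcrossprod(sb, t), 2L, t2, "-")
    j <- max.col(score, ties.method = "first")
    idx[lo:hi] <- j
    dst[lo:hi] <- sqrt(pmax(rowSums(sb^2) - score[cbind(seq_along(j), j)], 0))
  }
  list(match_index = idx, match_distance = dst)
}

# exact two-stage search: anchor every target to one of ~`coarse` coarse
# points; per group of queries sharing a nearest coarse point, restrict the
# exact search to targets whose anchor lies within 2*d0max + rmax of that
# coarse point (triangle inequality bound, so no true nearest neighbour can
# be pruned). Candidate subsets stay sorted, preserving the lowest-index
# tie break of the brute force.
.cps_hier <- function(s, t, coarse = 768L, chunk = 2048L) {
  M <- nrow(t)
  ci <- unique(as.integer(round(seq(1L, M, length.out = min(coarse, M)))))
  C <- t[ci, , drop = FALSE]
  anch <- .cps_brute(t, C, chunk = chunk)
  rmax <- max(anch$match_distance)
  by_cell <- split(seq_len(M), anch$match_index)
  pc <- .cps_brute(s, C, chunk = chunk)
  cc2 <- sweep(2 * tcrossprod(C, C), 2L, rowSums(C^2), "-")
  ccd <- sqrt(pmax(sweep(-cc2, 1L, rowSums(C^2), "+"), 0))  # coarse-coarse dist
  idx <- integer(nrow(s)); dst <- numeric(nrow(s))
  for (j in unique(pc$match_index)) {
    pts <- which(pc$match_index == j)
    bound <- 2 * max(pc$match_distance[pts]) + rmax + 1e-9
    cells <- which(ccd[j, ] <= bound)
    cand <- sort(unlist(by_cell[as.character(cells)], use.names = FALSE))
    sub <- .cps_brute(s[pts, , drop = FALSE], t[cand, , drop = FALSE],
                      chunk = chunk)
    idx[pts] <- cand[sub$match_index]
    dst[pts] <- sub$match_distance
  }
  list(match_index = idx, match_distance = dst)
}

#' @export
print.correspondence <- function(x, ...) {
  cat(sprintf("correspondence: %d matches, mean distance %.4g mm\n",
              length(x$match_index), mean(x$match_distance)))
  invisible(x)
}

#' Transfer a scalar map through a correspondence
#'
#' Pulls the target-mesh value onto each source vertex by nearest-vertex
#' lookup (no interpolation): output value at source vertex i is the map
#' value at `match_index[i]`.
#'
#' @param map [scalar_map()] defined on the correspondence's target mesh.
#' @param corr a [closest_point_search()] result.
#' @param n_target optional target vertex count; when supplied, the map
#'   length is checked against it.
#' @return a [scalar_map()] on the source mesh.
#' @export
transfer_thickness <- function(map, corr, n_target = NULL) {
  if (!is.null(n_target) && length(map$values) != n_target) {
    stop("scalar map length does not match target vertex count")
  }
  if (max(corr$match_index) > length(map$values)) {
    stop("correspondence indexes beyond the scalar map")
  }
  scalar_map(map$values[corr$match_index],
             mesh_id = paste0(map$mesh_id, "->source"))
}

#' Assemble the hybrid per-subject thickness dataset
#'
#' Given per-subject thickness maps from both pipelines, the pipeline-1
#' (source template, e.g. Civet-style) values are carried natively while the
#' pipeline-2 (target, e.g. Freesurfer-style) values are pulled onto the
#' hybrid template through the registration + closest-point correspondence.
#' One record is produced per available subject x timepoint; a subject
#' missing a timepoint in either pipeline is skipped with a warning.
#'
#' @param maps_cv named list (by `"subject|timepoint"`) of source-pipeline
#'   [scalar_map()]s on the source template.
#' @param maps_fs named list (same keys) of target-pipeline maps on the
#'   target template.
#' @param corr correspondence from deformed source vertices to target
#'   vertices.
#' @return list with `thickness_cv`, `thickness_fs` (vertex x record
#'   matrices on the hybrid template) and a `records` data frame
#'   (subject, timepoint).
#' @export
build_hybrid_dataset <- function(maps_cv, maps_fs, corr) {
  keys <- intersect(names(maps_cv), names(maps_fs))
  missing_keys <- setdiff(union(names(maps_cv), names(maps_fs)), keys)
  if (length(missing_keys)) {
    warning("skipping records missing in one pipeline: ",
            paste(missing_keys, collapse = ", "))
  }
  if (!length(keys)) stop("no overlapping subject/timepoint records")
  nv <- length(maps_cv[[keys[1]]]$values)
  t_cv <- matrix(NA_real_, nv, length(keys))
  t_fs <- matrix(NA_real_, nv, length(keys))
  for (i in seq_along(keys)) {
    t_cv[, i] <- maps_cv[[keys[i]]]$values
    t_fs[, i] <- transfer_thickness(maps_fs[[keys[i]]], corr)$values
  }
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  colnames(t_cv) <- colnames(t_fs) <- keys
  list(thickness_cv = t_cv, thickness_fs = t_fs,
       records = data.frame(key = keys, subject = parts[, 1L],
                            timepoint = parts[, 2L],
                            stringsAsFactors = FALSE))
}
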