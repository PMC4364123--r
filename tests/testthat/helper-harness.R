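# Shared expensive objects, built lazily and cached for the whole run.
.harness <- new.env(parent = emptyenv())

# radius-10 icosphere with its edge map and converged GVF: the standard
# registration test bed
reg_harness <- function() {
  if (is.null(.harness$reg)) {
    target <- build_icosphere(4, radius = 10)
    em <- voxelize_and_edge_map(target, spacing = 0.5)
    gvf <- compute_gvf(em, registration_config(gvf_sweeps = 60))
    .harness$reg <- list(target = target, em = em, gvf = gvf,
                         domain_lo = c(-13, -13, -13),
                         domain_hi = c(13, 13, 13))
  }
  .harness$reg
}

# brute-force nearest-neighbour oracle (plain loop, first-index ties)
cps_oracle <- function(s, t) {
  apply(as.matrix(s), 1L, function(p) {
    which.min(colSums((t(as.matrix(t)) - p)^2))
  })
}

# brute-force AUC oracle: explicit pair counting with half-credit ties
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# small default cohort reused across statistical tests
small_cohort <- function(seed = 1L) {
  key <- paste0("coh", seed)
  if (is.null(.harness[[key]])) {
    .harness[[key]] <- make_cohort(cohort_design(seed = seed))
  }
  .harness[[key]]
}
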