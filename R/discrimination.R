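# Effect-size-gated forward ROI selection, logistic scoring, and ROC/AUC
# with Hanley-McNeil standard errors and correlated-AUC comparison.

#' Gate candidate ROIs by effect size
#'
#' Keeps ROIs whose absolute standardized effect exceeds the threshold
#' (0.8 for cross-sectional contrasts, 0.6 for longitudinal, per the
#' reference protocol) and orders them by decreasing |g|, ties broken by
#' ROI id; the forward search then considers them in this order.
#'
#' @param effect_sizes data frame with `roi_id` and `g`.
#' @param threshold absolute effect-size gate.
#' @return data frame of retained ROIs in selection order (possibly empty).
#' @export
gate_candidates <- function(effect_sizes, threshold = 0.8) {
  keep <- effect_sizes[abs(effect_sizes$g) > threshold, , drop = FALSE]
  keep[order(-abs(keep$g), keep$roi_id), , drop = FALSE]
}

# IRLS ridge-penalized logistic regression (intercept unpenalized); the
# fallback fit when maximum likelihood diverges under perfect separation
.ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100L) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  pen <- c(0, rep(lambda, ncol(X1) - 1L))
  for (i in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1, X1 * w) + diag(pen, ncol(X1))
    gr <- crossprod(X1, y - mu) - pen * beta
    step <- solve(H, gr)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  list(coef = beta, fitted = stats::plogis(drop(X1 %*% beta)))
}

#' Logistic score on a set of ROI features
#'
#' Maximum-likelihood logistic regression of the binary label on the ROI
#' mean thickness (or change) features; returns in-sample predicted
#' probabilities as the discriminant score. Under perfect separation the
#' fit falls back to a lightly ridge-penalized IRLS with a note.
#'
#' @param X numeric feature matrix (subjects x ROIs).
#' @param y binary labels (0/1 or logical).
#' @return list with `scores`, `coef`, `separated` (logical).
#' @export
fit_logistic_score <- function(X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (anyNA(X)) stop("missing thickness values")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep || any(abs(fit$coefficients) > 1e3)) {
    rf <- .ridge_logistic(X, y)
    return(list(scores = rf$fitted, coef = rf$coef, separated = TRUE))
  }
  list(scores = fit$fitted.values, coef = fit$coefficients, separated = FALSE)
}

# Mann-Whitney AUC with midrank tie handling
.auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC area with Hanley-McNeil standard error
#'
#' AUC computed as the tie-corrected Mann-Whitney statistic (equal to the
#' proportion of positive/negative pairs ranked correctly, ties counting
#' one half); its standard error uses the Hanley-McNeil (1982) formula
#' with `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`, and the 95% CI is the normal
#' interval clipped to `[0, 1]`.
#'
#' @param scores numeric discriminant scores (higher = more likely positive).
#' @param labels binary labels.
#' @param selected_rois optional ordered ROI ids recorded in the result.
#' @return object of class `roc_result`: `auc`, `se_auc`, `ci95`,
#'   `n_pos`, `n_neg`, `scores`, `labels`, `selected_rois`.
#' @export
roc_auc <- function(scores, labels, selected_rois = NULL) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  a <- .auc_mw(scores, labels)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n1 * n0))
  ci <- pmin(pmax(a + c(-1, 1) * 1.96 * se, 0), 1)
  structure(list(auc = a, se_auc = se, ci95 = ci, n_pos = n1, n_neg = n0,
                 scores = scores, labels = labels,
                 selected_rois = selected_rois),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (SE %.4f, 95%% CI %.4f-%.4f; %d pos / %d neg)\n",
              x$auc, x$se_auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  if (!is.null(x$selected_rois)) {
    cat("  ROIs:", paste(x$selected_rois, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve coordinates
#'
#' @param roc a [roc_auc()] result.
#' @return data frame of (fpr, tpr) swept over score thresholds.
#' @export
roc_coordinates <- function(roc) {
  th <- c(Inf, sort(unique(roc$scores), decreasing = TRUE))
  do.call(rbind, lapply(th, function(t) {
    data.frame(threshold = t,
               fpr = mean(roc$scores[!roc$labels] >= t),
               tpr = mean(roc$scores[roc$labels] >= t))
  }))
}

# deterministic stratified fold assignment
.make_folds <- function(y, folds, seed) {
  .with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      ix <- sample(which(y == cl))
      f[ix] <- rep_len(seq_len(folds), length(ix))
    }
    f
  })
}

# cross-validated AUC of a logistic score on the given feature columns
.cv_auc <- function(X, y, cols, fold) {
  scores <- numeric(length(y))
  for (k in unique(fold)) {
    tr <- fold != k
    fit <- fit_logistic_score(X[tr, cols, drop = FALSE], y[tr])
    b <- fit$coef
    scores[!tr] <- drop(cbind(1, X[!tr, cols, drop = FALSE]) %*% b)
  }
  .auc_mw(scores, y)
}

#' Sequential forward ROI selection by cross-validated AUC
#'
#' Greedy forward search over the gated candidates: starting from the
#' empty set, each step adds the candidate whose inclusion maximizes the
#' k-fold cross-validated AUC of the logistic score, and stops when no
#' addition improves the AUC or `max_k` is reached. Folds are stratified
#' and seeded, so the selection is deterministic given the seed.
#'
#' @param X feature matrix (subjects x ROIs, columns named by ROI id).
#' @param y binary labels (at least 3 subjects per class).
#' @param candidates ordered candidate ROI ids (from [gate_candidates()]).
#' @param max_k maximal number of ROIs.
#' @param folds number of CV folds.
#' @param seed fold seed.
#' @return list with `selected` (ordered ROI ids), `cv_auc` (the accepted
#'   path of CV AUCs) and the fold assignment.
#' @export
forward_select <- function(X, y, candidates, max_k = 6L, folds = 5L,
                           seed = 1L) {
  y <- as.numeric(y)
  if (!length(candidates)) stop("no candidate ROIs")
  if (sum(y == 1) < 3L || sum(y == 0) < 3L) stop("need >= 3 subjects per class")
  candidates <- as.character(candidates)
  fold <- .make_folds(y, folds, seed)
  selected <- character(0)
  path <- numeric(0)
  best <- -Inf
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining) || length(selected) >= max_k) break
    trial <- vapply(remaining, function(cand) {
      .cv_auc(X, y, c(selected, cand), fold)
    }, 0)
    if (max(trial) <= best) break
    pick <- remaining[which.max(trial)]
    selected <- c(selected, pick)
    best <- max(trial)
    path <- c(path, best)
  }
  list(selected = selected, cv_auc = path, fold = fold)
}

# DeLong covariance structure of one or two AUCs on the same subjects
.delong_components <- function(scores, labels) {
  x <- scores[labels]; yn <- scores[!labels]
  v10 <- vapply(x, function(xi) mean((xi > yn) + 0.5 * (xi == yn)), 0)
  v01 <- vapply(yn, function(yi) mean((x > yi) + 0.5 * (x == yi)), 0)
  list(v10 = v10, v01 = v01)
}

#' Compare two correlated AUCs (Hanley-McNeil)
#'
#' Tests the difference of two AUCs measured on the same subjects with
#' `z = (A1 - A2) / sqrt(se1^2 + se2^2 - 2 r se1 se2)`, the ses from
#' [roc_auc()]. The between-score correlation `r` is estimated, following
#' the Hanley-McNeil prescription, either from the exact DeLong
#' covariance of the two empirical AUCs (method `"delong"`, the default:
#' the variance of the difference is then asymptotically exact, and the
#' test is well calibrated) or from the average of the within-class
#' Kendall rank correlations of the two score sets mapped to the Pearson
#' scale by the Greiner relation (method `"kendall"`, the table-free
#' reconstruction of the historical recipe; slightly conservative with
#' the original standard errors). `r = 0` recovers the independent-AUC
#' z-test.
#'
#' @param roc1,roc2 [roc_auc()] results on the same subjects and labels.
#' @param paired must be `TRUE`; unpaired inputs are an error.
#' @param method correlation estimator, `"kendall"` or `"delong"`.
#' @return object of class `auc_comparison`: `auc1`, `auc2`, `r`, `z`, `p`.
#' @export
compare_auc <- function(roc1, roc2, paired = TRUE,
                        method = c("delong", "kendall")) {
  method <- match.arg(method)
  if (!paired) stop("only the paired comparison is defined")
  if (!identical(roc1$labels, roc2$labels)) {
    stop("paired comparison requires identical subjects and labels")
  }
  lab <- roc1$labels
  if (method == "kendall") {
    rpos <- stats::cor(roc1$scores[lab], roc2$scores[lab], method = "kendall")
    rneg <- stats::cor(roc1$scores[!lab], roc2$scores[!lab], method = "kendall")
    tau <- mean(c(rpos, rneg), na.rm = TRUE)
    r <- sin(pi * tau / 2)
    se1 <- roc1$se_auc; se2 <- roc2$se_auc
    v <- se1^2 + se2^2 - 2 * r * se1 * se2
  } else {
    c1 <- .delong_components(roc1$scores, lab)
    c2 <- .delong_components(roc2$scores, lab)
    n1 <- sum(lab); n0 <- sum(!lab)
    var1 <- stats::var(c1$v10) / n1 + stats::var(c1$v01) / n0
    var2 <- stats::var(c2$v10) / n1 + stats::var(c2$v01) / n0
    cv <- stats::cov(c1$v10, c2$v10) / n1 + stats::cov(c1$v01, c2$v01) / n0
    r <- cv / sqrt(pmax(var1 * var2, 1e-300))
    v <- var1 + var2 - 2 * cv
  }
  z <- (roc1$auc - roc2$auc) / sqrt(pmax(v, 1e-300))
  structure(list(auc1 = roc1$auc, auc2 = roc2$auc, r = r, z = z,
                 p = 2 * stats::pnorm(-abs(z)), method = method),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC %.4f vs %.4f: z = %.2f, r = %.2f, p = %.4f (%s)\n",
              x$auc1, x$auc2, x$z, x$r, x$p, x$method))
  invisible(x)
}

#' ROI feature matrix for discrimination
#'
#' Builds the subjects x ROIs matrix the classifiers consume: baseline
#' thickness (`mode = "cross"`) or follow-up minus baseline change
#' (`mode = "longitudinal"`), for one pipeline.
#'
#' @param table a `roi_table`.
#' @param pipeline pipeline label.
#' @param mode `"cross"` or `"longitudinal"`.
#' @return list with `X` (matrix, columns named by ROI id), `subjects`,
#'   `groups`.
#' @export
roi_feature_matrix <- function(table, pipeline, mode = c("cross", "longitudinal")) {
  mode <- match.arg(mode)
  d <- table[table$pipeline == pipeline, ]
  if (mode == "cross") {
    d <- d[d$timepoint == "BSL", ]
    val <- d$thickness
  } else {
    d <- longitudinal_change(d)
    val <- d$change
  }
  subj <- unique(d$subject)
  rois <- sort(unique(d$roi_id))
  X <- matrix(NA_real_, length(subj), length(rois),
              dimnames = list(subj, as.character(rois)))
  X[cbind(match(d$subject, subj), match(d$roi_id, rois))] <- val
  list(X = X, subjects = subj,
       groups = d$group[match(subj, d$subject)])
}
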