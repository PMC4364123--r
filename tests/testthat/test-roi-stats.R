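test_that("Tukey-Kramer agrees with the aov/TukeyHSD oracle at unequal n", {
  set.seed(20)
  for (i in 1:5) {
    ns <- sample(5:30, 3)
    y <- c(rnorm(ns[1], 0), rnorm(ns[2], 0.4), rnorm(ns[3], 1))
    grp <- factor(rep(c("a", "b", "c"), ns))
    tk <- tukey_kramer(tapply(y, grp, mean), tapply(y, grp, sd),
                       as.vector(table(grp)), alpha = 0.05)
    hsd <- stats::TukeyHSD(stats::aov(y ~ grp))$grp
    expect_equal(sort(tk$pairs$p), sort(unname(hsd[, "p adj"])),
                 tolerance = 1e-10)
    # omnibus equals the one-way ANOVA F-test
    expect_equal(tk$omnibus_p,
                 summary(stats::aov(y ~ grp))[[1]][["Pr(>F)"]][1])
  }
})

test_that("with equal n Tukey-Kramer reduces to classic HSD", {
  set.seed(21)
  y <- rnorm(45, rep(c(0, 0.5, 1), each = 15))
  grp <- factor(rep(c("a", "b", "c"), each = 15))
  tk <- tukey_kramer(tapply(y, grp, mean), tapply(y, grp, sd),
                     rep(15L, 3), alpha = 0.05)
  # classic HSD: q = |diff| / sqrt(MSW / n)
  msw <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2))) / 42
  q12 <- abs(diff(tapply(y, grp, mean)[1:2])) / sqrt(msw / 15)
  expect_equal(tk$pairs$q[1], unname(q12))
})

test_that("a well-separated fourth group is flagged against all others", {
  tk <- tukey_kramer(c(0, 0, 0, 1), rep(0.1, 4), c(69, 37, 27, 52),
                     alpha = 0.05)
  ad_pairs <- tk$pairs$group2 == "4" | tk$pairs$group1 == "4"
  expect_true(all(tk$pairs$flag[ad_pairs]))
  expect_false(any(tk$pairs$flag[!ad_pairs]))
  tk0 <- tukey_kramer(rep(0.5, 4), rep(0.1, 4), c(69, 37, 27, 52))
  expect_false(any(tk0$pairs$flag))
  expect_error(tukey_kramer(c(0, 1), c(1, 1), c(1, 5)), "n >= 2")
})

test_that("Precuneus printed summaries reproduce the CTR-AD and sMCI-AD flags", {
  t4 <- load_fixture_table("T4")$records
  prec <- t4[t4$pipeline == "CV" & t4$roi_id == 31, ]
  tk <- tukey_kramer(
    means = unlist(prec[c("d_ctr", "d_smci", "d_pmci", "d_ad")]),
    sds = unlist(prec[c("s_ctr", "s_smci", "s_pmci", "s_ad")]),
    ns = c(69, 37, 27, 52), alpha = 0.01)
  flag_of <- function(a, b) tk$pairs$flag[tk$pairs$group1 == a & tk$pairs$group2 == b]
  expect_true(flag_of("d_ctr", "d_ad"))    # CTR vs AD
  expect_true(flag_of("d_smci", "d_ad"))   # sMCI vs AD
  expect_false(flag_of("d_ctr", "d_pmci"))
  expect_false(flag_of("d_smci", "d_pmci"))
})

test_that("recomputing the longitudinal table reproduces most printed flags", {
  rc <- recompute_longitudinal_flags(alpha = 0.01)
  expect_equal(nrow(rc$cells), 2 * 28 * 4)
  expect_gte(rc$agreement, 0.8)
  expect_gte(rc$agreement_stable, rc$agreement - 0.05)
  expect_true(any(rc$cells$marginal))  # rounding-sensitive cells exist and are listed
})

test_that("Hedges g matches its closed forms", {
  g <- hedges_g(1, 1, 10, 0, 1, 10)
  expect_equal(g$J, 1 - 3 / 71)
  expect_equal(g$g, 1 - 3 / 71)       # standardized diff 1 at n1=n2=10
  expect_equal(hedges_g(2, 1, 20, 2, 1, 25)$g, 0)
  expect_equal(g$se_g, sqrt(20 / 100 + g$g^2 / 40))
  # Middle Temporal posterior, Civet CTR-vs-AD printed summaries: |g| ~ 1.3
  gmt <- hedges_g(0, 0.25, 69, -0.33, 0.25, 52)
  expect_lt(abs(abs(gmt$g) - 1.3), 0.05)
  expect_error(hedges_g(1, 0, 10, 1, 0, 10), "zero pooled SD")
  # data interface agrees with the summary interface
  set.seed(22)
  x <- rnorm(20); y <- rnorm(25, 1)
  expect_equal(hedges_g_data(x, y)$g,
               hedges_g(mean(x), sd(x), 20, mean(y), sd(y), 25)$g)
})

test_that("effect-size comparison is antisymmetric and zero for equal effects", {
  g1 <- hedges_g(1, 1, 30, 0, 1, 30)
  expect_equal(compare_effect_sizes(g1, g1)$z, 0)
  expect_equal(compare_effect_sizes(g1, g1)$p, 1)
  g2 <- hedges_g(1.5, 1, 30, 0, 1, 30)
  expect_equal(compare_effect_sizes(g1, g2)$z, -compare_effect_sizes(g2, g1)$z)
})

test_that("thinning percentages follow their definitions", {
  coh <- small_cohort()
  tab <- observe_roi_table(coh, cv_profile())
  # uniform thickness change fabricated directly: 2.0 -> 1.9 is -5%
  fake <- data.frame(subject = rep(c("a", "b"), each = 2),
                     group = "CTR", pipeline = "CV",
                     timepoint = rep(c("BSL", "M24"), 2), roi_id = 3L,
                     thickness = rep(c(2.0, 1.9), 2))
  tp <- thinning_percent(fake, "longitudinal")
  expect_equal(tp$pct, -5)
  # no change -> 0%
  fake$thickness <- 2
  expect_equal(thinning_percent(fake, "longitudinal")$pct, 0)
  # default cohort: AD thins more than CTR on average
  tp2 <- thinning_percent(tab, "longitudinal")
  expect_gt(mean(abs(tp2$pct[tp2$group == "AD"])),
            mean(abs(tp2$pct[tp2$group == "CTR"])))
  # cross-sectional percentages are relative to CTR group means
  tp3 <- thinning_percent(tab, "cross")
  expect_false("CTR" %in% tp3$group)
  expect_lt(mean(tp3$pct[tp3$group == "AD"]), 0)
})

test_that("Pearson-by-ROI: self-correlation, null width, constant covariate", {
  coh <- small_cohort()
  tab <- observe_roi_table(coh, cv_profile())
  b3 <- tab[tab$roi_id == 3 & tab$timepoint == "BSL" & tab$group == "CTR", ]
  cov_self <- data.frame(subject = b3$subject, self = b3$thickness)
  r <- pearson_by_roi(tab[tab$roi_id == 3, ], cov_self, "self", "CTR")
  expect_equal(r$r, 1)
  # independent covariate at n = 69: the null sampling distribution of r
  # puts P(|r| < 0.24) at about 0.95 (normal approximation sd 1/sqrt(n-1))
  set.seed(23)
  rs <- vapply(1:200, function(i) {
    fake <- data.frame(subject = b3$subject, noise = rnorm(69))
    pearson_by_roi(tab[tab$roi_id == 3, ], fake, "noise", "CTR")$r
  }, 0)
  p_analytic <- 2 * pnorm(0.24 * sqrt(68)) - 1
  expect_lt(abs(mean(abs(rs) < 0.24) - p_analytic),
            3 * sqrt(p_analytic * (1 - p_analytic) / 200))
  const <- data.frame(subject = b3$subject, k = 1)
  expect_error(pearson_by_roi(tab, const, "k", "CTR"), "constant")
})

test_that("Steiger's Z: zero at equality, antisymmetric, nominal under the null", {
  expect_equal(steiger_z(0.4, 0.4, 0.5, 69)$z, 0)
  z1 <- steiger_z(0.5, 0.3, 0.4, 69)$z
  z2 <- steiger_z(0.3, 0.5, 0.4, 69)$z
  expect_equal(z1, -z2)
  expect_gt(z1, 0)
  expect_error(steiger_z(1, 0.3, 0.4, 69), "inside")
  set.seed(24)
  rej <- vapply(1:2000, function(i) {
    S <- matrix(c(1, .5, .3, .5, 1, .3, .3, .3, 1), 3)
    X <- matrix(rnorm(69 * 3), 69) %*% chol(S)
    steiger_z(cor(X[, 1], X[, 3]), cor(X[, 2], X[, 3]),
              cor(X[, 1], X[, 2]), 69)$p < 0.05
  }, NA)
  se2 <- 2 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(rej) - 0.05), se2)
})

test_that("Kendall tau conversion: closed forms and Greiner consistency", {
  x <- 1:20
  k <- kendall_with_conversion(x, x^3)  # monotone: perfectly concordant
  expect_equal(k$tau, 1)
  expect_equal(k$r_equivalent, 1)
  expect_equal(sin(pi * 0.5 / 2), sqrt(2) / 2)  # the tau = 0.5 mapping
  set.seed(25)
  z <- matrix(rnorm(1000), 500) %*% chol(matrix(c(1, .6, .6, 1), 2))
  kk <- kendall_with_conversion(z[, 1], z[, 2])
  expect_lt(abs(kk$r_equivalent - 0.6), 0.05)
  expect_error(kendall_with_conversion(rep(1, 20), 1:20), "tied")
  expect_error(kendall_with_conversion(1:5, 1:5), "n >= 10")
})
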