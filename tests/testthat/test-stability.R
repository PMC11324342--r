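test_that("ICC is 1 when subjects differ and replicates are exact", {
  v <- matrix(rep(c(0.2, 0.5, 0.8, 0.3), 3), 4, 3)
  est <- icc_estimate(v)
  expect_equal(est$icc, 1)
  expect_equal(as.character(koo_li_classify(est$icc)), "excellent")
})

test_that("ICC estimates recover the generating variance ratio", {
  # latent model: subject effect sd 3, occasion sd 1 -> ICC = 9/10
  set.seed(51)
  subj <- rnorm(40, sd = 3)
  v <- outer(subj, rep(1, 3)) + matrix(rnorm(120), 40, 3)
  expect_lt(abs(icc_estimate(v)$icc - 0.9), 0.07)

  # no subject effect -> ICC near 0
  iid <- matrix(rnorm(120), 40, 3)
  expect_lt(abs(icc_estimate(iid)$icc), 0.15)
})

test_that("agreement ICC matches the mixed-model variance decomposition", {
  set.seed(52)
  subj <- rnorm(60, sd = 2)
  v <- outer(subj, rep(1, 4)) + matrix(rnorm(240), 60, 4)
  long <- data.frame(y = as.vector(v),
                     subject = factor(rep(seq_len(60), 4)),
                     occ = factor(rep(1:4, each = 60)))
  fit <- lme4::lmer(y ~ 1 + (1 | subject) + (1 | occ), data = long)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sb <- vc$vcov[vc$grp == "subject"]
  so <- vc$vcov[vc$grp == "occ"]
  se <- vc$vcov[vc$grp == "Residual"]
  expect_equal(icc_estimate(v)$icc, sb / (sb + so + se), tolerance = 0.05)
})

test_that("ICC is stable under subject duplication and errors when degenerate", {
  set.seed(53)
  v <- outer(rnorm(25, sd = 2), rep(1, 3)) + matrix(rnorm(75), 25, 3)
  expect_equal(icc_estimate(rbind(v, v))$icc, icc_estimate(v)$icc,
               tolerance = 0.02)
  expect_error(icc_estimate(matrix(0.4, 5, 3)), "zero total variance")
  expect_error(icc_estimate(matrix(c(1, 2, NA, 4), 2, 2)), "complete")
})

test_that("Koo-Li bands place boundaries in the higher class", {
  expect_equal(as.character(koo_li_classify(c(0.3, 0.5, 0.74, 0.75, 0.89,
                                              0.9, 0.92))),
               c("poor", "moderate", "moderate", "good", "good",
                 "excellent", "excellent"))
})

test_that("per-probe stability report recovers the generator's ICC target", {
  base <- sim_cohort(n_probes = 100, n_informative = 0, seed = 54)$betas
  for (tgt in c(0.5, 0.9)) {
    long <- sim_longitudinal(base, icc_target = tgt, n_timepoints = 3,
                             seed = 55)
    sheet <- data.frame(
      sample_id = colnames(long),
      subject_id = sub("_T[0-9]+$", "", colnames(long)),
      timepoint = sub("^.*_", "", colnames(long)))
    rep <- icc_stability(long, sheet)
    expect_equal(nrow(rep), 100)
    expect_lt(abs(median(rep$icc, na.rm = TRUE) - tgt), 0.05)
  }
})

test_that("listwise deletion drops subjects with missing timepoints", {
  base <- sim_cohort(n_subjects = 10, n_responders = 5, n_probes = 5,
                     n_informative = 0, seed = 56)$betas
  long <- sim_longitudinal(base, icc_target = 0.8, n_timepoints = 3,
                           seed = 57)
  # remove one subject's T3 column entirely
  long <- long[, colnames(long) != "S01_T3"]
  sheet <- data.frame(
    sample_id = colnames(long),
    subject_id = sub("_T[0-9]+$", "", colnames(long)),
    timepoint = sub("^.*_", "", colnames(long)))
  rep <- icc_stability(long, sheet)
  expect_true(all(rep$n_subjects == 9))
})

test_that("delta correlation detects persistence and reversal", {
  sim <- sim_cohort(n_probes = 50, n_informative = 10, effect_delta = 0.2,
                    seed = 58)
  y <- sim$sheet$response
  same <- delta_correlation(sim$betas, sim$betas, y)
  expect_equal(same$rho, 1)
  expect_true(all(same$quadrants$quadrant %in% c("hyper-hyper", "hypo-hypo")))
  expect_equal(sum(same$quadrant_counts), 50)

  flipped <- ifelse(y == "R", "NR", "R")
  rev <- delta_correlation(sim$betas, sim$betas, y, flipped)
  expect_equal(rev$rho, -1)
  expect_true(all(rev$quadrants$quadrant %in% c("hyper-hypo", "hypo-hyper")))

  expect_error(delta_correlation(sim$betas, sim$betas, rep("R", 31)),
               "both classes")
})

test_that("persistent planted effects give high cross-timepoint correlation", {
  sim <- sim_cohort(n_probes = 300, n_informative = 30, effect_delta = 0.15,
                    seed = 59)
  long <- sim_longitudinal(sim$betas, icc_target = 0.9, n_timepoints = 2,
                           seed = 60)
  t1 <- long[, grepl("_T1$", colnames(long))]
  t2 <- long[, grepl("_T2$", colnames(long))]
  y <- sim$sheet$response
  res <- delta_correlation(t1, t2, y)
  expect_gt(res$rho, 0.5)
  # the planted probes keep their sign pattern across timepoints
  planted <- res$quadrants[res$quadrants$probe_id %in% sim$truth, ]
  expect_gt(mean(planted$quadrant %in% c("hyper-hyper", "hypo-hypo")), 0.9)
})
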