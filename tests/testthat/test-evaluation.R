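test_that("classification metrics match hand-counted examples", {
  y <- c(1, 1, 0, 0)
  perfect <- classification_metrics(c(0.9, 0.8, 0.2, 0.1), y)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auroc, 1)

  # 2 positives (0.9, 0.4), 2 negatives (0.6, 0.1): 3 of 4 pairs concordant
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.1), y), 0.75)

  # F1 from the formula at precision = recall = 0.7
  p <- r <- 0.7
  expect_equal(2 * p * r / (p + r), 0.7)
})

test_that("AUROC equals the rank-statistic U/(n+ n-) including ties", {
  set.seed(41)
  for (i in 1:40) {
    n1 <- sample(3:20, 1); n0 <- sample(3:20, 1)
    scores <- round(c(rnorm(n1, 0.5), rnorm(n0)), sample(c(1, 2, 8), 1))
    y <- rep(c(1, 0), c(n1, n0))
    u <- unname(suppressWarnings(
      stats::wilcox.test(scores[y == 1], scores[y == 0])$statistic))
    expect_equal(auroc(scores, y), u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(42)
  scores <- runif(40); y <- rbinom(40, 1, 0.5)
  a <- auroc(scores, y)
  expect_equal(auroc(qlogis(scores), y), a)
  expect_equal(auroc(scores^3, y), a)
  expect_warning(expect_true(is.na(auroc(scores, rep(1, 40)))), "single-class")
})

test_that("ROC curves are monotone and anchored at the corners", {
  set.seed(43)
  rc <- roc_curve(runif(50), rbinom(50, 1, 0.4))
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("likelihood summary reproduces the printed operating point", {
  op <- likelihood_summary(0.70, 0.70, pretest = 0.53)
  expect_equal(round(op$lr_plus, 2), 2.33)
  expect_equal(round(op$posttest, 3), 0.725)
  expect_equal(likelihood_summary(0.5, 0.5, 0.5)$lr_plus, 1)
  expect_equal(likelihood_summary(0.5, 1, 0.5)$lr_plus, Inf)
  # Bayes odds arithmetic oracle
  odds <- 0.53 / 0.47
  expect_equal(op$posttest, (7 / 3) * odds / (1 + (7 / 3) * odds))
})

test_that("a single model on separable data is perfect on the holdout", {
  m <- run_isolated(function() {
    sim <- sim_cohort(n_probes = 40, n_informative = 0, seed = 44)
    y <- sim$sheet$response
    sim$betas["cg00000001", ] <- ifelse(y == "R", 0.9, 0.1)
    ctrl <- suppressWarnings(stabsel_control(
      n_repeats = 10, cv = FALSE, nrounds = 60,
      n_permutations = 40, shadow_nrounds = 25))
    ens <- recalibrate("cg00000001", sim$betas, y, n_models = 1,
                       control = ctrl, seed = 3)
    ens$mean_metrics
  })
  expect_equal(unname(m["auroc"]), 1)
  expect_equal(unname(m["precision"]), 1)
  expect_equal(unname(m["recall"]), 1)
})

test_that("vertical averaging of identical models reproduces one curve", {
  res <- run_isolated(function() {
    sim <- sim_cohort(n_probes = 60, n_informative = 3,
                      effect_delta = 0.25, seed = 45)
    # train_fraction ~ 1 makes every model see the same training set
    ctrl <- suppressWarnings(stabsel_control(
      n_repeats = 10, cv = FALSE, nrounds = 60, n_permutations = 40,
      shadow_nrounds = 25, train_fraction = 0.999, subsample = 1))
    ens <- recalibrate(rownames(sim$betas)[1:10], sim$betas,
                       sim$sheet$response, n_models = 4, control = ctrl,
                       seed = 4)
    list(max_sd = max(ens$roc$tpr_sd), auroc_var = var(ens$metrics$auroc))
  })
  expect_equal(res$max_sd, 0)
  expect_equal(res$auroc_var, 0)
})

test_that("recalibration uses one shared holdout and respects the contract", {
  res <- run_isolated(function() {
    ctrl <- suppressWarnings(stabsel_control(
      n_repeats = 6, cv = FALSE, nrounds = 60,
      n_permutations = 40, shadow_nrounds = 25))
    sim <- sim_cohort(n_probes = 80, n_informative = 5,
                      effect_delta = 0.2, seed = 46)
    fit <- stabsel(sim$betas, sim$sheet$response, ctrl, seed = 5)
    ens <- recalibrate(fit, sim$betas, sim$sheet$response, n_models = 8,
                       seed = 6)
    empty <- fit; empty$predictor_set <- character(0)
    err <- tryCatch({
      recalibrate(empty, sim$betas, sim$sheet$response); NULL
    }, error = conditionMessage)
    list(n_pred = length(fit$predictor_set), holdout = ens$holdout,
         metrics = ens$metrics, mean_auroc = ens$mean_metrics["auroc"],
         tpr_mean = ens$roc$tpr_mean, err = err)
  })
  expect_gt(res$n_pred, 0)
  expect_length(res$holdout, 6)  # 20% of 31, stratified
  expect_equal(nrow(res$metrics), 8)
  expect_equal(unname(res$mean_auroc), mean(res$metrics$auroc))
  # mean ROC stays inside [0,1] and is monotone
  expect_true(all(diff(res$tpr_mean) >= 0))
  expect_match(res$err, "empty predictor set")
})

test_that("ensemble predictions average model probabilities on new data", {
  res <- run_isolated(function() {
    sim <- sim_cohort(n_probes = 50, n_informative = 5,
                      effect_delta = 0.3, seed = 47)
    ctrl <- suppressWarnings(stabsel_control(
      n_repeats = 10, cv = FALSE, nrounds = 60,
      n_permutations = 40, shadow_nrounds = 25))
    ens <- recalibrate(sim$truth, sim$betas, sim$sheet$response,
                       n_models = 5, control = ctrl, seed = 7)
    list(pred = predict(ens, sim$betas), samples = colnames(sim$betas))
  })
  expect_length(res$pred, length(res$samples))
  expect_true(all(res$pred >= 0 & res$pred <= 1))
  expect_named(res$pred, res$samples)
})
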