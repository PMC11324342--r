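# Booster-fitting work runs in short-lived subprocesses (run_isolated);
# the parent session only asserts on the returned summaries.

test_that("selection is deterministic given data and master seed", {
  res <- run_isolated(function() {
    ctrl <- suppressWarnings(stabsel_control(
      n_repeats = 10, cv = FALSE, nrounds = 60,
      n_permutations = 40, shadow_nrounds = 25))
    sim <- sim_cohort(n_probes = 120, n_informative = 5,
                      effect_delta = 0.2, seed = 31)
    a <- stabsel(sim$betas, sim$sheet$response, ctrl, seed = 7)
    b <- stabsel(sim$betas, sim$sheet$response, ctrl, seed = 7)
    c <- stabsel(sim$betas, sim$sheet$response, ctrl, seed = 8)
    list(same_imp = identical(a$importance, b$importance),
         same_pred = identical(a$predictor_set, b$predictor_set),
         same_shadow = identical(a$shadow$values, b$shadow$values),
         seed_changes = !identical(a$importance, c$importance))
  })
  expect_true(res$same_imp)
  expect_true(res$same_pred)
  expect_true(res$same_shadow)
  expect_true(res$seed_changes)
})

test_that("selection is invariant to probe row order", {
  res <- run_isolated(function() {
    ctrl <- suppressWarnings(stabsel_control(
      n_repeats = 10, cv = FALSE, nrounds = 60,
      n_permutations = 40, shadow_nrounds = 25))
    sim <- sim_cohort(n_probes = 120, n_informative = 5,
                      effect_delta = 0.2, seed = 32)
    a <- stabsel(sim$betas, sim$sheet$response, ctrl, seed = 7)
    set.seed(1)
    perm <- sample(nrow(sim$betas))
    b <- stabsel(sim$betas[perm, ], sim$sheet$response, ctrl, seed = 7)
    list(same_imp = identical(a$importance, b$importance),
         same_pred = identical(a$predictor_set, b$predictor_set))
  })
  expect_true(res$same_imp)
  expect_true(res$same_pred)
})

test_that("a perfectly separating probe dominates every repeat", {
  res <- run_isolated(function() {
    ctrl <- suppressWarnings(stabsel_control(
      n_repeats = 20, cv = FALSE, nrounds = 60,
      n_permutations = 40, shadow_nrounds = 25))
    sim <- sim_cohort(n_probes = 300, n_informative = 0, seed = 33)
    y <- sim$sheet$response
    betas <- sim$betas
    set.seed(33)
    betas["cg00000001", ] <- ifelse(y == "R", 0.9, 0.1) +
      runif(ncol(betas), -0.02, 0.02)
    fit <- stabsel(betas, y, ctrl, seed = 9)
    ranks <- apply(-fit$importance_matrix, 2, rank)["cg00000001", ]
    list(rank1_frac = mean(ranks == 1),
         top = names(fit$importance)[1],
         selected = "cg00000001" %in% fit$predictor_set)
  })
  expect_gte(res$rank1_frac, 0.95)
  expect_equal(res$top, "cg00000001")
  expect_true(res$selected)
})

test_that("held-out AUROC is centred at chance under permuted labels", {
  mean_auroc <- run_isolated(function() {
    ctrl <- stabsel_control(n_repeats = 20, cv = FALSE, nrounds = 60,
                            n_permutations = 0)
    sim <- sim_cohort(n_probes = 200, n_informative = 10,
                      effect_delta = 0.2, seed = 34)
    set.seed(34)
    y <- sample(sim$sheet$response)  # break the association
    fit <- stabsel(sim$betas, y, ctrl, seed = 10)
    mean(fit$repeat_auroc)
  })
  expect_lt(abs(mean_auroc - 0.5), 0.2)
})

test_that("shadow importances vanish on constant features", {
  sh <- run_isolated(function() {
    ctrl <- suppressWarnings(stabsel_control(n_permutations = 10,
                                             shadow_nrounds = 25))
    betas <- matrix(0.5, 20, 31,
                    dimnames = list(sprintf("cg%05d", 1:20),
                                    sprintf("S%02d", 1:31)))
    shadow_importances(betas, rep(c("R", "NR"), c(16, 15)), ctrl, seed = 1)
  })
  expect_equal(sh, rep(0, 10))
})

test_that("aggregate importance is the repeat mean and the bar separates it", {
  res <- run_isolated(function() {
    ctrl <- suppressWarnings(stabsel_control(
      n_repeats = 10, cv = FALSE, nrounds = 60,
      n_permutations = 40, shadow_nrounds = 25))
    sim <- sim_cohort(n_probes = 120, n_informative = 5,
                      effect_delta = 0.2, seed = 35)
    fit <- stabsel(sim$betas, sim$sheet$response, ctrl, seed = 11)
    fit[c("importance", "importance_matrix", "predictor_set", "shadow")]
  })
  agg <- rowMeans(res$importance_matrix)
  expect_equal(sort(agg, decreasing = TRUE)[1:5], res$importance[1:5])
  expect_setequal(res$predictor_set,
                  names(res$importance)[res$importance > res$shadow$threshold])
  expect_true(all(res$importance >= 0))
  # importances are sorted with a deterministic tie-break
  expect_true(all(diff(res$importance) <= 0))
})

test_that("probes with missing values are excluded from selection", {
  res <- run_isolated(function() {
    ctrl <- stabsel_control(n_repeats = 4, cv = FALSE, nrounds = 60,
                            n_permutations = 0)
    sim <- sim_cohort(n_probes = 60, n_informative = 3,
                      effect_delta = 0.2, seed = 36)
    sim$betas[5, 3] <- NA
    fit <- stabsel(sim$betas, sim$sheet$response, ctrl, seed = 2)
    list(dropped = fit$dropped_probes, kept = names(fit$importance),
         na_probe = rownames(sim$betas)[5])
  })
  expect_equal(res$dropped, res$na_probe)
  expect_false(res$na_probe %in% res$kept)
})

test_that("cross-validated early stopping picks a data-driven round count", {
  res <- run_isolated(function() {
    ctrl <- stabsel_control(n_repeats = 3, cv = TRUE, cv_folds = 5,
                            nrounds = 80, n_permutations = 0)
    sim <- sim_cohort(n_probes = 150, n_informative = 5,
                      effect_delta = 0.25, seed = 21)
    a <- stabsel(sim$betas, sim$sheet$response, ctrl, seed = 3)
    b <- stabsel(sim$betas, sim$sheet$response, ctrl, seed = 3)
    list(nrounds = a$repeat_nrounds, cap = ctrl$nrounds,
         deterministic = identical(a$importance, b$importance))
  })
  expect_true(all(res$nrounds >= 1 & res$nrounds <= res$cap))
  # strong planted signal stops well before the round cap
  expect_true(any(res$nrounds < res$cap))
  expect_true(res$deterministic)
})

test_that("control constructor validates its arguments", {
  expect_error(stabsel_control(train_fraction = 1.2), "train_fraction")
  expect_error(stabsel_control(cv_folds = 1), "cv_folds")
  expect_warning(stabsel_control(n_permutations = 10), "unstable")
})
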