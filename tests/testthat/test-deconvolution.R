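test_that("noiseless mixtures are recovered to solver tolerance", {
  ref <- sim_cell_reference(seed = 61)
  mix <- sim_cell_mixture(ref, n_samples = 25, noise_sd = 0, seed = 62)
  est <- estimate_proportions(mix$betas, ref)
  expect_equal(est$proportions, mix$proportions, tolerance = 1e-8)
  expect_true(all(est$residual_norm < 1e-8))
})

test_that("identity reference reads proportions straight off the betas", {
  types <- c("CD8T", "CD4T", "NK", "B", "Mono", "Neu")
  ref <- diag(6)
  dimnames(ref) <- list(types, paste0("cg", 1:6))
  w <- c(0.1, 0.2, 0.3, 0.1, 0.1, 0.2)
  betas <- matrix(w, 6, 1, dimnames = list(paste0("cg", 1:6), "S1"))
  est <- estimate_proportions(betas, ref)
  expect_equal(unname(est$proportions["S1", ]), w, tolerance = 1e-8)
})

test_that("noisy mixtures are recovered within 0.05 per cell type", {
  ref <- sim_cell_reference(seed = 63)
  mix <- sim_cell_mixture(ref, n_samples = 100, noise_sd = 0.02, seed = 64)
  est <- estimate_proportions(mix$betas, ref)
  mae <- colMeans(abs(est$proportions - mix$proportions))
  expect_true(all(mae < 0.05))
})

test_that("estimates respect the simplex constraints and probe order", {
  ref <- sim_cell_reference(seed = 65)
  mix <- sim_cell_mixture(ref, n_samples = 10, noise_sd = 0.05, seed = 66)
  est <- estimate_proportions(mix$betas, ref)
  expect_true(all(est$proportions >= -1e-10))
  expect_true(all(rowSums(est$proportions) <= 1 + 1e-8))

  shuf <- mix$betas[sample(nrow(mix$betas)), ]
  est2 <- estimate_proportions(shuf, ref)
  expect_equal(est2$proportions, est$proportions, tolerance = 1e-10)

  eq <- estimate_proportions(mix$betas, ref, sum_to_one = TRUE)
  expect_equal(unname(rowSums(eq$proportions)), rep(1, 10), tolerance = 1e-8)
})

test_that("the QP solution matches a dense simplex grid search", {
  set.seed(67)
  types <- paste0("T", 1:3)
  ref <- matrix(runif(3 * 30), 3, 30,
                dimnames = list(types, paste0("cg", 1:30)))
  w_true <- c(0.5, 0.3, 0.2)
  beta <- as.numeric(t(ref) %*% w_true) + rnorm(30, 0, 0.03)
  beta <- matrix(pmin(pmax(beta, 0), 1), 30, 1,
                 dimnames = list(colnames(ref), "S1"))
  est <- estimate_proportions(beta, ref)
  obj <- function(w) sum((beta[, 1] - as.numeric(t(ref) %*% w))^2)
  grid <- expand.grid(a = seq(0, 1, 0.01), b = seq(0, 1, 0.01))
  grid <- grid[grid$a + grid$b <= 1, ]
  vals <- apply(grid, 1, function(g) obj(c(g[1], g[2], 1 - g[1] - g[2])))
  best <- unlist(grid[which.min(vals), ])
  w_grid <- c(best[1], best[2], 1 - sum(best))
  expect_lte(obj(est$proportions["S1", ]), min(vals) + 1e-10)
  expect_equal(unname(est$proportions["S1", ]), unname(w_grid),
               tolerance = 0.02)
})

test_that("rank-deficient references fail loudly naming the culprits", {
  ref <- sim_cell_reference(seed = 68)
  ref["Neu", ] <- ref["Mono", ]  # perfectly collinear pair
  mix <- sim_cell_mixture(sim_cell_reference(seed = 68), 5, seed = 69)
  expect_error(estimate_proportions(mix$betas, ref),
               "rank-deficient.*(Mono|Neu)")
})

test_that("group comparisons flag a planted monocyte shift after BH", {
  ref <- sim_cell_reference(seed = 70)
  labels <- rep(c("R", "NR"), c(16, 15))
  hits <- 0
  for (s in 1:10) {
    mix <- sim_cell_mixture(ref, n_samples = 31, dirichlet_alpha = 8,
                            noise_sd = 0.02, seed = 70 + s)
    w <- mix$proportions
    w[labels == "R", "Mono"] <- pmax(w[labels == "R", "Mono"] - 0.1, 0.001)
    w <- w / rowSums(w)
    betas <- t(w %*% ref)
    colnames(betas) <- sprintf("S%02d", 1:31)
    est <- estimate_proportions(betas, ref)
    cmp <- compare_cell_groups(est$proportions, labels)
    if (cmp$p_bh[cmp$cell_type == "Mono"] < 0.05) hits <- hits + 1
    expect_equal(cmp$p_bh, bh_adjust(cmp$p))
  }
  expect_gte(hits, 9)
})

test_that("identical groups show no spurious cell-type differences", {
  ref <- sim_cell_reference(seed = 71)
  w <- matrix(rep(1 / 6, 6 * 20), 20, 6,
              dimnames = list(sprintf("S%02d", 1:20), rownames(ref)))
  betas <- t(w %*% ref)
  est <- estimate_proportions(betas, ref)
  cmp <- compare_cell_groups(est$proportions, rep(c("R", "NR"), 10))
  expect_true(all(!cmp$significant))
})
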