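# Shared fixtures and independent brute-force oracles.

# step-up FDR adjustment straight from the definition:
# adj(i) = min over j with p_(j) >= p_i of m * p_(j) / rank(j), clipped to 1
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- vapply(seq_len(m), function(i) {
    cand <- m * ranked[i:m] / (i:m)
    min(1, min(cand))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# O(n^2) gap grouping oracle: connected components of the graph joining
# values closer than the threshold, then the same size-floor rule
gap_bruteforce <- function(x, threshold = 0.1, out_cutoff = 0.01) {
  x <- x[!is.na(x)]
  n <- length(x)
  comp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(x[i] - x[j]) <= threshold) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  }
  sizes <- as.integer(table(comp))
  floor_n <- max(1, ceiling(out_cutoff * n))
  has_gap <- length(sizes) >= 2 && all(sizes >= floor_n)
  list(has_gap = has_gap, n_groups = if (has_gap) length(sizes) else 1L)
}

# Run one simulation-study replicate in a fresh R session. The large
# calibration/recovery studies fit thousands of boosters; giving each
# replicate its own short-lived process keeps the test session lean and
# makes replicates fully independent. A crashed worker is retried:
# results are seed-determined, so a clean rerun returns the same value.
run_isolated <- function(fun, args = list(), attempts = 10) {
  environment(fun) <- globalenv()
  pay <- tempfile(fileext = ".rds")
  out <- tempfile(fileext = ".rds")
  log <- tempfile(fileext = ".txt")
  on.exit(unlink(c(pay, out, log)), add = TRUE)
  saveRDS(list(fun = fun, args = args), pay)
  libs <- paste(sprintf("'%s'", .libPaths()), collapse = ", ")
  code <- sprintf(
    ".libPaths(c(%s, .libPaths())); p <- readRDS('%s'); suppressMessages(library(stabmeth)); saveRDS(do.call(p$fun, p$args), '%s')",
    libs, pay, out)
  rscript <- file.path(R.home("bin"), "Rscript")
  for (k in seq_len(attempts)) {
    status <- suppressWarnings(
      system2(rscript, c("-e", shQuote(code)), stdout = log, stderr = log))
    if (identical(status, 0L) && file.exists(out)) return(readRDS(out))
  }
  stop("isolated worker failed after ", attempts, " attempts:\n",
       paste(readLines(log, warn = FALSE), collapse = "\n"))
}

# one null-calibration replicate, split into its two measurements:
# admitted-probe fraction of the shadow bar, and the recalibrated mean
# AUROC of an arbitrary probe subset under null labels
null_admit_replicate <- function(r) {
  ctrl <- stabsel_control(n_repeats = 15, cv = FALSE, nrounds = 150,
                          n_permutations = 400, shadow_nrounds = 40)
  null <- sim_cohort(n_probes = 2000, n_informative = 0, effect_delta = 0,
                     seed = 1000 + r)
  fit <- stabsel(null$betas, null$sheet$response, ctrl, seed = 2000 + r)
  length(fit$predictor_set) / 2000
}

null_auroc_replicate <- function(r) {
  ctrl <- stabsel_control(n_repeats = 15, cv = FALSE, nrounds = 150,
                          n_permutations = 400, shadow_nrounds = 40)
  null <- sim_cohort(n_probes = 2000, n_informative = 0, effect_delta = 0,
                     seed = 1000 + r)
  ens <- recalibrate(rownames(null$betas)[1:40], null$betas,
                     null$sheet$response, n_models = 10, control = ctrl,
                     seed = 3000 + r)
  unname(ens$mean_metrics["auroc"])
}

# one signal-recovery replicate: fraction of planted probes selected
recovery_replicate <- function(delta, r) {
  ctrl <- stabsel_control(n_repeats = 15, cv = FALSE, nrounds = 150,
                          n_permutations = 400, shadow_nrounds = 40)
  sim <- sim_cohort(n_probes = 2000, n_informative = 20,
                    effect_delta = delta, seed = 4000 + r)
  fit <- stabsel(sim$betas, sim$sheet$response, ctrl, seed = 5000 + r)
  length(intersect(fit$predictor_set, sim$truth)) / 20
}

# clinical record with each response criterion set by construction
make_record <- function(endo, bio, clin) {
  data.frame(
    subject_id = "S01",
    ems_t1 = 3, ems_t2 = if (endo) 2 else 3,
    uceis_t1 = 7, uceis_t2 = if (endo) 5 else 7,
    crp_t1 = 20, crp_t2 = if (bio) 8 else 15,
    fcal_t1 = 4000, fcal_t2 = if (bio) 1500 else 3600,
    mayo_t1 = 10, mayo_t2 = if (clin) 6 else 9,
    rbs_t1 = 2, rbs_t2 = if (clin) 1 else 2,
    sccai_t1 = 10, sccai_t2 = if (clin) 4 else 9)
}

random_beta_matrix <- function(n_probes, n_samples, na_frac = 0) {
  x <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                              sprintf("S%02d", seq_len(n_samples))))
  if (na_frac > 0)
    x[sample(length(x), round(na_frac * length(x)))] <- NA
  x
}
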