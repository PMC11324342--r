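#' End-to-end synthetic analysis pipeline
#'
#' Runs the full biomarker-discovery workflow on generated data: cohort
#' simulation, endpoint classification, gap-probe filtering, stability
#' selection, recalibrated ensemble evaluation, longitudinal stability,
#' cell-type deconvolution and covariate/enrichment follow-up. Every
#' stage writes a CSV/JSON report into `out_dir` and a manifest records
#' seeds, problem sizes and file checksums. All stage seeds derive from
#' the master seed by fixed counters, so a rerun with the same arguments
#' is bit-identical.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param n_probes,n_informative,effect_delta,n_subjects,n_responders,
#'   beta_precision cohort simulation parameters, see [sim_cohort()].
#' @param icc_target,n_timepoints longitudinal parameters, see
#'   [sim_longitudinal()].
#' @param n_gap_probes gap-signal probes appended before filtering.
#' @param control [stabsel_control()] for selection and evaluation.
#' @param n_models recalibration ensemble size.
#' @return (invisibly) list with the stage results and the manifest.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         n_probes = 2000, n_informative = 20,
                         effect_delta = 0.15, n_subjects = 31,
                         n_responders = 16, beta_precision = 30,
                         icc_target = 0.9, n_timepoints = 3,
                         n_gap_probes = 100,
                         control = stabsel_control(), n_models = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- seed + seq(0, 8) * 1000L  # stage seeds by counter
  names(seeds) <- c("cohort", "clinical", "gap", "longitudinal", "select",
                    "evaluate", "deconv_ref", "deconv_mix", "enrich")
  jw <- function(x, file) jsonlite::write_json(
    x, file.path(out_dir, file), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cw <- function(x, file) utils::write.csv(
    x, file.path(out_dir, file), row.names = FALSE)

  # --- simulate -------------------------------------------------------
  cohort <- sim_cohort(n_subjects, n_responders, n_probes, n_informative,
                       effect_delta, beta_precision, seed = seeds["cohort"])
  clinical <- sim_clinical(cohort$sheet$response,
                           cohort$sheet$subject_id, seed = seeds["clinical"])
  gap <- sim_gap_probes(n_gap_probes, gap_fraction = 0.2, gap_size = 0.5,
                        n_samples = n_subjects, seed = seeds["gap"])
  colnames(gap$betas) <- colnames(cohort$betas)
  long <- sim_longitudinal(cohort$betas, icc_target, n_timepoints,
                           seed = seeds["longitudinal"])
  write_beta_matrix(rbind(cohort$betas, gap$betas),
                    file.path(out_dir, "betas_t1.tsv"))
  jw(list(informative = cohort$truth, gap = gap$truth), "truth.json")

  # --- classify -------------------------------------------------------
  if (is.null(clinical)) stop("stage classify: missing clinical records")
  calls <- classify_cohort(clinical)
  if (!all(calls$response == cohort$sheet$response))
    stop("stage classify: generated records inconsistent with labels")
  cw(calls, "response_calls.csv")
  cw(tally_responses(clinical), "response_tally.csv")
  labels <- calls$response

  # --- filter ---------------------------------------------------------
  filt <- filter_probes(rbind(cohort$betas, gap$betas))
  cw(filt$removed, "removed_probes.csv")

  # --- select ---------------------------------------------------------
  sel <- stabsel(filt$betas, labels, control, seed = seeds["select"])
  cw(data.frame(probe_id = names(sel$importance),
                importance = unname(sel$importance),
                predictor = names(sel$importance) %in% sel$predictor_set),
     "selection_ranking.csv")
  jw(list(n_predictors = length(sel$predictor_set),
          predictor_set = sel$predictor_set,
          shadow_threshold = sel$shadow$threshold,
          mean_repeat_auroc = mean(sel$repeat_auroc)),
     "selection_summary.json")

  # --- evaluate -------------------------------------------------------
  ens <- NULL
  if (length(sel$predictor_set) > 0) {
    ens <- recalibrate(sel, filt$betas, labels, n_models = n_models,
                       seed = seeds["evaluate"])
    cw(ens$metrics, "ensemble_metrics.csv")
    cw(ens$roc, "ensemble_roc.csv")
    jw(as.list(ens$mean_metrics), "ensemble_summary.json")
  } else {
    jw(list(note = "empty predictor set; evaluation skipped"),
       "ensemble_summary.json")
  }

  # --- stability ------------------------------------------------------
  long_sheet <- data.frame(
    sample_id = colnames(long),
    subject_id = sub("_T[0-9]+$", "", colnames(long)),
    timepoint = sub("^.*_(T[0-9]+)$", "\\1", colnames(long)),
    stringsAsFactors = FALSE)
  icc_rep <- icc_stability(long, long_sheet)
  cw(icc_rep, "icc_report.csv")
  t1c <- long[, long_sheet$timepoint == "T1"]
  t2c <- long[, long_sheet$timepoint == "T2"]
  lab_by_subject <- stats::setNames(labels, cohort$sheet$subject_id)
  dc <- delta_correlation(t1c, t2c,
                          lab_by_subject[sub("_T1$", "", colnames(t1c))],
                          lab_by_subject[sub("_T2$", "", colnames(t2c))])
  cw(dc$quadrants, "delta_quadrants.csv")
  jw(list(rho = dc$rho,
          quadrant_counts = as.list(dc$quadrant_counts),
          icc_band_counts = as.list(table(icc_rep$koo_li))),
     "stability_summary.json")

  # --- deconvolve -----------------------------------------------------
  ref <- sim_cell_reference(seed = seeds["deconv_ref"])
  mix <- sim_cell_mixture(ref, n_samples = n_subjects, noise_sd = 0.02,
                          seed = seeds["deconv_mix"])
  colnames(mix$betas) <- cohort$sheet$sample_id
  rownames(mix$proportions) <- cohort$sheet$sample_id
  est <- estimate_proportions(mix$betas, ref)
  cw(data.frame(sample_id = rownames(est$proportions),
                est$proportions, check.names = FALSE),
     "cell_proportions.csv")
  cw(compare_cell_groups(est$proportions, labels), "cell_comparison.csv")

  # --- covariates / enrichment ---------------------------------------
  cov_res <- enr <- NULL
  if (length(sel$predictor_set) > 0) {
    cov_sheet <- data.frame(sample_id = cohort$sheet$sample_id,
                            sccai = clinical$sccai,
                            steroid = clinical$steroid)
    cov_res <- covariate_regression(
      filt$betas[sel$predictor_set, , drop = FALSE], cov_sheet)
    cw(cov_res, "covariate_regressions.csv")

    ann <- data.frame(probe_id = rownames(cohort$betas),
                      gene = paste0("GENE", seq_len(nrow(cohort$betas))),
                      stringsAsFactors = FALSE)
    mapped <- map_probes_to_genes(sel$predictor_set, ann)
    universe <- sort(unique(ann$gene))
    sets <- with_seed(seeds["enrich"], {
      s <- lapply(1:10, function(i) sample(universe, 50))
      names(s) <- sprintf("SET%02d", 1:10)
      s$SET_SIGNAL <- unique(c(mapped$genes,
                               sample(universe, max(0, 30 - length(mapped$genes)))))
      s
    })
    enr <- overrepresentation(mapped$genes, sets, universe)
    cw(enr, "enrichment.csv")
  }

  # --- manifest -------------------------------------------------------
  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package = "stabmeth",
    version = as.character(utils::packageVersion("stabmeth")),
    master_seed = seed, stage_seeds = as.list(seeds),
    sizes = list(n_probes = n_probes, n_subjects = n_subjects,
                 n_informative = n_informative,
                 n_repeats = control$n_repeats,
                 n_permutations = control$n_permutations,
                 n_models = n_models),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jw(manifest, "manifest.json")
  invisible(list(cohort = cohort, clinical = clinical, calls = calls,
                 filtered = filt, selection = sel, ensemble = ens,
                 icc = icc_rep, delta = dc, proportions = est,
                 covariates = cov_res, enrichment = enr,
                 manifest = manifest))
}
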