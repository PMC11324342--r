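#' Intraclass correlation for one probe
#'
#' Two-way ANOVA decomposition of a subjects x timepoints matrix into
#' between-subject (MSR), between-timepoint (MSC) and residual (MSE) mean
#' squares, combined as ICC(A,1) -- two-way model, absolute agreement,
#' single measurement:
#' \deqn{ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))}
#' or as the consistency form ICC(C,1) = (MSR - MSE)/(MSR + (k-1) MSE).
#'
#' @param values numeric matrix, subjects x timepoints, complete cases.
#' @param form `"agreement"` (default) or `"consistency"`.
#' @return list: `icc`, `form`, `n_subjects`, `n_timepoints`, and the
#'   mean squares.
#' @export
icc_estimate <- function(values, form = c("agreement", "consistency")) {
  form <- match.arg(form)
  values <- as.matrix(values)
  if (any(is.na(values))) stop("ICC needs complete cases (listwise-delete first)")
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 timepoints")
  grand <- mean(values)
  rm <- rowMeans(values); cm <- colMeans(values)
  msr <- k * sum((rm - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  sse <- sum((values - outer(rm, rep(1, k)) -
                outer(rep(1, n), cm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- if (form == "agreement")
    msr + (k - 1) * mse + k / n * (msc - mse)
  else msr + (k - 1) * mse
  if (denom <= 0 || (msr == 0 && mse == 0))
    stop("zero total variance: ICC undefined")
  list(icc = (msr - mse) / denom, form = form,
       n_subjects = n, n_timepoints = k,
       ms = c(rows = msr, columns = msc, error = mse))
}

#' Koo-Li interpretation bands for ICC values
#'
#' poor < 0.5 <= moderate < 0.75 <= good < 0.9 <= excellent; boundary
#' values fall in the higher band.
#'
#' @param icc numeric vector of ICC estimates.
#' @return factor with levels poor/moderate/good/excellent.
#' @export
koo_li_classify <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent"))
}

#' Per-probe longitudinal stability report
#'
#' Reshapes a probes x samples matrix with repeated measures into one
#' subjects x timepoints matrix per probe and estimates the ICC. For each
#' probe, subjects missing any of the sheet's timepoints (or with NA
#' values) are listwise-deleted.
#'
#' @param betas probes x samples beta matrix; columns are sample ids.
#' @param sheet sample sheet with `sample_id`, `subject_id`, `timepoint`.
#' @param form ICC form, see [icc_estimate()].
#' @return data.frame: probe_id, icc, n_subjects, n_timepoints, form,
#'   koo_li (band), with one row per probe (NA icc where undefined).
#' @export
icc_stability <- function(betas, sheet, form = "agreement") {
  stopifnot(all(colnames(betas) %in% sheet$sample_id))
  sheet <- sheet[match(colnames(betas), sheet$sample_id), ]
  tps <- sort(unique(sheet$timepoint))
  subs <- sort(unique(sheet$subject_id))
  # index matrix: subject x timepoint -> column of betas (NA if absent)
  idx <- matrix(NA_integer_, length(subs), length(tps),
                dimnames = list(subs, tps))
  idx[cbind(match(sheet$subject_id, subs),
            match(sheet$timepoint, tps))] <- seq_len(nrow(sheet))
  res <- lapply(rownames(betas), function(p) {
    vals <- matrix(betas[p, ][idx], length(subs), length(tps))
    keep <- stats::complete.cases(vals)
    if (sum(keep) < 2)
      return(data.frame(probe_id = p, icc = NA_real_,
                        n_subjects = sum(keep),
                        n_timepoints = length(tps), form = form))
    est <- tryCatch(icc_estimate(vals[keep, , drop = FALSE], form),
                    error = function(e) NULL)
    data.frame(probe_id = p,
               icc = if (is.null(est)) NA_real_ else est$icc,
               n_subjects = sum(keep), n_timepoints = length(tps),
               form = form)
  })
  out <- do.call(rbind, res)
  out$koo_li <- koo_li_classify(out$icc)
  out
}

#' Between-timepoint persistence of group methylation differences
#'
#' For every probe, the group contrast (mean responder minus mean
#' non-responder beta) is computed at two timepoints; the Spearman
#' correlation of the two contrast vectors across probes measures how
#' stable the differential-methylation landscape is, and each probe is
#' assigned a sign quadrant (hyper-hyper, hypo-hypo, hyper-hypo,
#' hypo-hyper; a contrast of exactly 0 counts as hyper).
#'
#' @param betas_t1,betas_t2 probes x samples matrices sharing a probe set.
#' @param labels_t1,labels_t2 response labels per column (R positive).
#' @return list: `rho` (Spearman, across probes), `quadrants` data.frame
#'   (probe_id, delta_t1, delta_t2, quadrant), `quadrant_counts`.
#' @export
delta_correlation <- function(betas_t1, betas_t2, labels_t1,
                              labels_t2 = labels_t1) {
  probes <- intersect(rownames(betas_t1), rownames(betas_t2))
  if (length(probes) < 3) stop("need >= 3 shared probes")
  y1 <- .as_binary(labels_t1); y2 <- .as_binary(labels_t2)
  if (length(unique(y1)) < 2 || length(unique(y2)) < 2)
    stop("both classes required at each timepoint")
  d1 <- rowMeans(betas_t1[probes, y1 == 1, drop = FALSE]) -
    rowMeans(betas_t1[probes, y1 == 0, drop = FALSE])
  d2 <- rowMeans(betas_t2[probes, y2 == 1, drop = FALSE]) -
    rowMeans(betas_t2[probes, y2 == 0, drop = FALSE])
  quad <- ifelse(d1 >= 0,
                 ifelse(d2 >= 0, "hyper-hyper", "hyper-hypo"),
                 ifelse(d2 >= 0, "hypo-hyper", "hypo-hypo"))
  list(rho = spearman_rho(d1, d2),
       quadrants = data.frame(probe_id = probes, delta_t1 = unname(d1),
                              delta_t2 = unname(d2), quadrant = quad,
                              stringsAsFactors = FALSE),
       quadrant_counts = table(factor(quad, c("hyper-hyper", "hypo-hypo",
                                              "hyper-hypo", "hypo-hyper"))))
}
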