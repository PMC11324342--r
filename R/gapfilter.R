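#' Gap-signal call for one probe
#'
#' Sorts the probe's beta values and splits them into groups wherever two
#' consecutive sorted values differ by more than `threshold`. The probe is
#' called a gap signal when at least two groups form and every group holds
#' at least `max(1, ceiling(out_cutoff * n))` samples — i.e. the clusters
#' are not explained by a few outlying samples. Gap signals typically
#' track an underlying genetic variant rather than a methylation signal.
#'
#' @param betas numeric vector of beta values for one probe.
#' @param threshold minimum distance between clusters (beta units).
#' @param out_cutoff minimum group size as a fraction of n.
#' @return list: `has_gap`, `n_groups`, `largest_gap`, `group_sizes`.
#' @export
gap_call <- function(betas, threshold = 0.1, out_cutoff = 0.01) {
  betas <- betas[!is.na(betas)]
  if (length(betas) < 3) stop("gap call needs >= 3 non-missing values")
  s <- sort(betas)
  gaps <- diff(s)
  cut <- which(gaps > threshold)
  sizes <- diff(c(0, cut, length(s)))
  largest <- if (length(gaps)) max(gaps) else 0
  floor_n <- max(1, ceiling(out_cutoff * length(s)))
  has_gap <- length(sizes) >= 2 && all(sizes >= floor_n)
  # groups below the size floor are outliers, not evidence of multimodality
  list(has_gap = has_gap,
       n_groups = if (has_gap) length(sizes) else 1L,
       largest_gap = largest, group_sizes = sizes)
}

#' Remove gap-signal probes and drop-listed probes from a beta matrix
#'
#' @param betas probes x samples beta matrix.
#' @param threshold gap threshold passed to [gap_call()].
#' @param out_cutoff group-size floor passed to [gap_call()].
#' @param drop_list character vector of probe ids to remove regardless of
#'   the gap call (e.g. an externally supplied genetic-variant list).
#' @return list: `betas` (retained probes), `removed` (data.frame with
#'   probe_id and reason: "gap" and/or "drop_list").
#' @export
filter_probes <- function(betas, threshold = 0.1, out_cutoff = 0.01,
                          drop_list = character(0)) {
  validate_beta_matrix(betas)
  gap_flag <- vapply(seq_len(nrow(betas)), function(i)
    gap_call(betas[i, ], threshold, out_cutoff)$has_gap, logical(1))
  listed <- rownames(betas) %in% drop_list
  removed_idx <- gap_flag | listed
  reason <- ifelse(gap_flag & listed, "gap+drop_list",
                   ifelse(gap_flag, "gap", "drop_list"))[removed_idx]
  kept <- betas[!removed_idx, , drop = FALSE]
  if (nrow(kept) == 0) warning("all probes removed by filtering")
  list(betas = kept,
       removed = data.frame(probe_id = rownames(betas)[removed_idx],
                            reason = reason, stringsAsFactors = FALSE))
}
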