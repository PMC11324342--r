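#' Composite treatment-response endpoints
#'
#' Response to induction therapy is adjudicated per subject from paired
#' baseline (T1) and week-8 (T2) clinical scores:
#'
#' * endoscopic response: drop in endoscopic Mayo subscore >= 1 or in
#'   UCEIS >= 2;
#' * biochemical response: >= 50% drop in both CRP and faecal calprotectin,
#'   or absolute CRP <= 5.0 mg/L and calprotectin <= 250 ug/g;
#' * clinical response: total Mayo drop >= 3 points and >= 30% of baseline
#'   with rectal-bleeding subscore dropping >= 1 or ending <= 1, or a
#'   >= 50% drop in SCCAI.
#'
#' The composite label is endoscopic AND (clinical OR biochemical).
#' A record is one row (or one-row-equivalent list) with columns
#' `ems_t1, ems_t2, uceis_t1, uceis_t2, mayo_t1, mayo_t2, rbs_t1, rbs_t2,
#' sccai_t1, sccai_t2, crp_t1, crp_t2, fcal_t1, fcal_t2`.
#'
#' @param record clinical record (list or one-row data.frame).
#' @return logical.
#' @name endpoints
NULL

.need <- function(record, cols) {
  vals <- lapply(cols, function(cl) record[[cl]])
  if (any(vapply(vals, function(v) is.null(v) || is.na(v), logical(1))))
    stop("missing clinical score(s): ",
         paste(cols[vapply(vals, function(v) is.null(v) || is.na(v), logical(1))],
               collapse = ", "))
  invisible(vals)
}

#' @rdname endpoints
#' @export
endoscopic_response <- function(record) {
  .need(record, c("ems_t1", "ems_t2", "uceis_t1", "uceis_t2"))
  (record$ems_t1 - record$ems_t2) >= 1 ||
    (record$uceis_t1 - record$uceis_t2) >= 2
}

#' @rdname endpoints
#' @export
biochemical_response <- function(record) {
  .need(record, c("crp_t1", "crp_t2", "fcal_t1", "fcal_t2"))
  if (record$crp_t1 < 0 || record$crp_t2 < 0 ||
      record$fcal_t1 < 0 || record$fcal_t2 < 0)
    stop("CRP and faecal calprotectin must be non-negative")
  (record$crp_t2 <= 0.5 * record$crp_t1 &&
     record$fcal_t2 <= 0.5 * record$fcal_t1) ||
    (record$crp_t2 <= 5.0 && record$fcal_t2 <= 250)
}

#' @rdname endpoints
#' @export
clinical_response <- function(record) {
  have_mayo <- !is.null(record$mayo_t1) && !is.na(record$mayo_t1) &&
    !is.null(record$mayo_t2) && !is.na(record$mayo_t2) &&
    !is.null(record$rbs_t1) && !is.na(record$rbs_t1) &&
    !is.null(record$rbs_t2) && !is.na(record$rbs_t2)
  have_sccai <- !is.null(record$sccai_t1) && !is.na(record$sccai_t1) &&
    !is.null(record$sccai_t2) && !is.na(record$sccai_t2)
  if (!have_mayo && !have_sccai)
    stop("clinical response needs Mayo+RBS scores or SCCAI scores")
  mayo_ok <- FALSE
  if (have_mayo) {
    drop <- record$mayo_t1 - record$mayo_t2
    mayo_ok <- drop >= 3 && drop >= 0.30 * record$mayo_t1 &&
      ((record$rbs_t1 - record$rbs_t2) >= 1 || record$rbs_t2 <= 1)
  }
  sccai_ok <- have_sccai && record$sccai_t2 <= 0.5 * record$sccai_t1
  mayo_ok || sccai_ok
}

#' Composite response call for one record
#'
#' @param record clinical record (see [endpoints]).
#' @return list with logical fields `endoscopic`, `biochemical`,
#'   `clinical`, `composite` and a character vector `reasons` naming the
#'   satisfied criteria.
#' @export
composite_response <- function(record) {
  endo <- endoscopic_response(record)
  bio <- biochemical_response(record)
  clin <- clinical_response(record)
  comp <- endo && (clin || bio)
  list(endoscopic = endo, biochemical = bio, clinical = clin,
       composite = comp,
       reasons = c("endoscopic", "biochemical", "clinical")[c(endo, bio, clin)])
}

#' Tally response criteria over a cohort
#'
#' @param records data.frame of clinical records, one row per subject.
#' @return data.frame with one row per criterion (endoscopic, biochemical,
#'   clinical, composite): count and percentage (one decimal).
#' @export
tally_responses <- function(records) {
  crit <- c("endoscopic", "biochemical", "clinical", "composite")
  if (nrow(records) == 0) {
    return(data.frame(criterion = crit, n = 0L, pct = 0,
                      stringsAsFactors = FALSE))
  }
  calls <- lapply(seq_len(nrow(records)),
                  function(i) composite_response(records[i, , drop = FALSE]))
  n <- vapply(crit, function(cr)
    sum(vapply(calls, `[[`, logical(1), cr)), integer(1))
  data.frame(criterion = crit, n = unname(n),
             pct = round(100 * unname(n) / nrow(records), 1),
             stringsAsFactors = FALSE)
}

#' Classify every subject in a cohort
#'
#' @param records data.frame of clinical records with a `subject_id` column.
#' @return data.frame: subject_id, the three criterion flags, composite
#'   flag and the derived R/NR label.
#' @export
classify_cohort <- function(records) {
  calls <- lapply(seq_len(nrow(records)),
                  function(i) composite_response(records[i, , drop = FALSE]))
  data.frame(
    subject_id = records$subject_id,
    endoscopic = vapply(calls, `[[`, logical(1), "endoscopic"),
    biochemical = vapply(calls, `[[`, logical(1), "biochemical"),
    clinical = vapply(calls, `[[`, logical(1), "clinical"),
    composite = vapply(calls, `[[`, logical(1), "composite"),
    response = ifelse(vapply(calls, `[[`, logical(1), "composite"), "R", "NR"),
    stringsAsFactors = FALSE)
}
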