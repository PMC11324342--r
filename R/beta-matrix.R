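#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix of methylation fractions with
#' CpG probes as rows and samples as columns, probe identifiers as rownames
#' and sample identifiers as colnames. All non-missing values must lie in
#' \[0, 1\]; explicit `NA` is allowed.
#'
#' @param x numeric matrix, probes x samples.
#' @return `x`, invisibly, after validation.
#' @export
validate_beta_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("beta matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate probe identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1]: probe %s, sample %s (value %g)",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]],
                 x[bad[1, 1], bad[1, 2]]))
  }
  invisible(x)
}

#' Read a beta-value matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers and probe identifiers in the
#' first column. The literal string `NA` marks missing values.
#'
#' @param path file path.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return validated numeric beta matrix (probes x samples).
#' @export
read_beta_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("expected probe-id column plus >= 1 sample column")
  probes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & !(vals %in% c("NA", "")),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at probe %s, sample %s: '%s'",
                 probes[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]))
  dimnames(num) <- list(probes, colnames(vals))
  validate_beta_matrix(num)
  num
}

#' Write a beta-value matrix to TSV
#'
#' @param x beta matrix.
#' @param path output path.
#' @param digits significant digits retained (declared I/O precision).
#' @export
write_beta_matrix <- function(x, path, digits = 8) {
  validate_beta_matrix(x)
  out <- cbind(probe_id = rownames(x),
               as.data.frame(signif(x, digits), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Columns every sample sheet must carry; clinical score columns are those
# used by the composite endpoint.
.sheet_required <- c("sample_id", "subject_id", "timepoint", "response")
.clinical_cols <- c("ems_t1", "ems_t2", "uceis_t1", "uceis_t2",
                    "mayo_t1", "mayo_t2", "rbs_t1", "rbs_t2",
                    "sccai_t1", "sccai_t2", "crp_t1", "crp_t2",
                    "fcal_t1", "fcal_t2")

#' Validate a sample sheet
#'
#' One row per sample. Mandatory columns: `sample_id`, `subject_id`,
#' `timepoint` (one of T1/T2/T3), `response` (R, NR or unknown). Optional:
#' `steroid` (0/1), `sccai`, and the paired T1/T2 clinical score columns
#' consumed by the response endpoints (`ems_t1` ... `fcal_t2`).
#'
#' @param sheet data.frame.
#' @return `sheet`, invisibly.
#' @export
validate_sample_sheet <- function(sheet) {
  miss <- setdiff(.sheet_required, names(sheet))
  if (length(miss) > 0)
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (!all(sheet$timepoint %in% c("T1", "T2", "T3")))
    stop("timepoint must be one of T1, T2, T3")
  if (!all(sheet$response %in% c("R", "NR", "unknown")))
    stop("response must be R, NR or unknown")
  key <- paste(sheet$subject_id, sheet$timepoint)
  if (anyDuplicated(key))
    stop("duplicated (subject_id, timepoint): ", key[duplicated(key)][1])
  lab <- tapply(sheet$response, sheet$subject_id,
                function(v) length(unique(v)))
  if (any(lab > 1))
    stop("response label differs across timepoints for subject ",
         names(lab)[which(lab > 1)[1]])
  invisible(sheet)
}

#' Read a sample sheet CSV
#'
#' @param path CSV path with a header naming the mandatory columns.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

#' Read a probe-to-gene annotation map
#'
#' Two-column TSV (`probe_id`, `gene`); a probe may appear on several rows
#' (multi-gene annotation) or not at all (intergenic).
#'
#' @param path TSV path.
#' @return data.frame with columns `probe_id` and `gene`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("probe_id", "gene") %in% names(ann)))
    stop("annotation needs columns probe_id and gene")
  ann
}

#' Read gene sets in GMT format
#'
#' Standard tab-delimited GMT: set name, description, then member genes.
#'
#' @param path GMT path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  if (any(lengths(sets) == 0)) stop("empty gene set in GMT")
  sets
}
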