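#' Per-probe covariate regressions
#'
#' Regresses the methylation of each probe on each clinical covariate
#' (ordinary least squares, two-sided t-test on the slope), correcting
#' with Benjamini-Hochberg within each covariate family. By default the
#' covariates enter marginal models; `joint = TRUE` fits one model with
#' all covariates and reports partial slopes.
#'
#' @param betas probes x samples beta matrix (typically restricted to the
#'   predictor probes).
#' @param sheet sample sheet whose rows match the matrix columns
#'   (`sample_id`), carrying the covariate columns.
#' @param covariates character vector of sheet column names (default
#'   SCCAI as continuous and steroid use as binary).
#' @param joint logical; one joint model instead of marginal models.
#' @return data.frame: probe_id, covariate, slope (beta units per
#'   covariate unit), p, p_bh, significant (p_bh < 0.05).
#' @export
covariate_regression <- function(betas, sheet,
                                 covariates = c("sccai", "steroid"),
                                 joint = FALSE) {
  stopifnot(all(colnames(betas) %in% sheet$sample_id))
  sheet <- sheet[match(colnames(betas), sheet$sample_id), ]
  for (cv in covariates) {
    if (is.null(sheet[[cv]])) stop("covariate absent from sheet: ", cv)
    if (stats::var(sheet[[cv]]) == 0)
      stop("constant covariate: ", cv)
  }
  n <- ncol(betas)
  fam <- function(cv) {
    if (!joint) {
      x <- sheet[[cv]]
      xc <- x - mean(x)
      sxx <- sum(xc^2)
      yc <- betas - rowMeans(betas)
      slope <- as.numeric(yc %*% xc) / sxx
      resid <- yc - outer(slope, xc)
      se <- sqrt(rowSums(resid^2) / (n - 2) / sxx)
      tval <- slope / se
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    } else {
      x <- as.matrix(sheet[covariates])
      fit <- stats::lm(t(betas) ~ x)
      sm <- summary(fit)
      row <- paste0("x", cv)
      slope <- vapply(sm, function(s) s$coefficients[row, 1], numeric(1))
      p <- vapply(sm, function(s) s$coefficients[row, 4], numeric(1))
    }
    data.frame(probe_id = rownames(betas), covariate = cv,
               slope = unname(slope), p = unname(p),
               p_bh = bh_adjust(unname(p)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(covariates, fam))
  out$significant <- out$p_bh < 0.05
  rownames(out) <- NULL
  out
}

#' Map probes to annotated gene symbols
#'
#' @param probes character vector of probe ids.
#' @param annotation data.frame with `probe_id` and `gene` columns (a
#'   probe may map to several genes; intergenic probes are absent or have
#'   an empty gene).
#' @return list: `genes` (deduplicated symbols), `unannotated` (probes
#'   without any gene).
#' @export
map_probes_to_genes <- function(probes, annotation) {
  hits <- annotation[annotation$probe_id %in% probes &
                       !is.na(annotation$gene) &
                       nzchar(annotation$gene), , drop = FALSE]
  list(genes = sort(unique(hits$gene)),
       unannotated = sort(setdiff(probes, hits$probe_id)))
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided upper-tail hypergeometric test per gene set: the probability
#' of observing at least the seen overlap between the predictor genes and
#' the set, given the universe. Benjamini-Hochberg across sets.
#'
#' @param genes predictor gene symbols (must lie in the universe).
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe background gene symbols.
#' @return data.frame sorted by p: set_name, k (overlap), K (set size in
#'   universe), n (predictor genes), N (universe size), p, p_fdr,
#'   significant (p_fdr < 0.05). Empty input gives an empty frame.
#' @export
overrepresentation <- function(genes, sets, universe) {
  genes <- unique(genes)
  bad <- setdiff(genes, universe)
  if (length(bad) > 0)
    stop("predictor genes outside universe: ", paste(bad, collapse = ", "))
  empty <- data.frame(set_name = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p = numeric(0), p_fdr = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (length(genes) == 0 || length(sets) == 0) return(empty)
  nn <- length(genes); bign <- length(unique(universe))
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    bigk <- length(set)
    k <- length(intersect(genes, set))
    p <- stats::phyper(k - 1, bigk, bign - bigk, nn, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = bigk, n = nn, N = bign, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_adjust(out$p)
  out$significant <- out$p_fdr < 0.05
  out[order(out$p, out$set_name), , drop = FALSE]
}
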