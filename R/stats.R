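#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving and clipped to
#' 1. Thin wrapper over [stats::p.adjust()] so every module corrects
#' multiplicity identically.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction (the convention that reproduces the printed
#' cohort-characteristic p-values), df = 1, two-sided.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `statistic` and `p`.
#' @export
chisq_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: chi-square statistic undefined")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups. Exact p for small
#' tie-free samples, normal approximation with tie correction otherwise;
#' the output records which was used.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list with `U`, `p` and `method` ("exact" or "normal-approx").
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups need >= 1 observation")
  exact <- (length(x) < 50 && length(y) < 50) &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  p <- unname(ht$p.value)
  if (is.nan(p)) p <- 1  # all observations tied: no evidence of a shift
  list(U = unname(ht$statistic), p = p,
       method = if (exact) "exact" else "normal-approx")
}

#' Spearman rank correlation
#'
#' Ties are mid-ranked. A constant vector has no rank ordering, so the
#' coefficient is undefined and an error is raised.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors with >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}
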