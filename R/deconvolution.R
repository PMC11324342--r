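#' Reference-based cell-type proportion estimation
#'
#' Constrained projection of each sample's beta profile onto a cell-type
#' reference signature: for sample beta vector b and signature matrix F
#' (cell types x probes), solves the quadratic program
#' \deqn{min_w || b - F' w ||^2  subject to  w >= 0, sum(w) <= 1}
#' per sample (the classical whole-blood deconvolution projection; with
#' `sum_to_one = TRUE` the simplex equality constraint is used instead).
#'
#' @param betas probes x samples beta matrix.
#' @param reference cell-type x probe signature matrix; probes must be
#'   present in `betas` (at least as many shared probes as cell types).
#' @param sum_to_one logical; constrain proportions to sum exactly to 1.
#' @return list: `proportions` (samples x cell types), `residual_norm`
#'   (per-sample Euclidean residual), `probes_used`.
#' @export
estimate_proportions <- function(betas, reference, sum_to_one = FALSE) {
  shared <- intersect(colnames(reference), rownames(betas))
  t <- nrow(reference)
  if (length(shared) < t)
    stop("need at least as many shared probes as cell types")
  f <- reference[, shared, drop = FALSE]
  qrf <- qr(t(f))
  if (qrf$rank < t) {
    dep <- rownames(f)[qrf$pivot[(qrf$rank + 1):t]]
    stop("reference signature is rank-deficient; collinear cell types: ",
         paste(dep, collapse = ", "))
  }
  dmat <- f %*% t(f) + diag(1e-10, t)
  amat <- cbind(rep(-1, t), diag(t))
  bvec <- c(-1, rep(0, t))
  meq <- 0
  if (sum_to_one) {
    amat[, 1] <- 1
    bvec[1] <- 1
    meq <- 1
  }
  w <- matrix(NA_real_, ncol(betas), t,
              dimnames = list(colnames(betas), rownames(reference)))
  rn <- stats::setNames(numeric(ncol(betas)), colnames(betas))
  for (j in seq_len(ncol(betas))) {
    b <- betas[shared, j]
    sol <- quadprog::solve.QP(dmat, as.numeric(f %*% b), amat, bvec,
                              meq = meq)
    wj <- pmax(sol$solution, 0)
    w[j, ] <- wj
    rn[j] <- sqrt(sum((b - as.numeric(t(f) %*% wj))^2))
  }
  list(proportions = w, residual_norm = rn, probes_used = shared)
}

#' Compare estimated cell-type proportions between response groups
#'
#' Two-sided Mann-Whitney test (or Welch t) per cell type with
#' Benjamini-Hochberg correction across the cell types.
#'
#' @param proportions samples x cell-type matrix (from
#'   [estimate_proportions()]).
#' @param labels response labels per sample (R positive).
#' @param test `"mann-whitney"` (default) or `"welch"`.
#' @return data.frame: cell_type, the group medians, p, p_bh, significant
#'   (p_bh < 0.05).
#' @export
compare_cell_groups <- function(proportions, labels,
                                test = c("mann-whitney", "welch")) {
  test <- match.arg(test)
  y <- .as_binary(labels)
  if (length(unique(y)) < 2) stop("both groups required")
  p <- apply(proportions, 2, function(v) {
    if (test == "mann-whitney") mann_whitney(v[y == 1], v[y == 0])$p
    else stats::t.test(v[y == 1], v[y == 0])$p.value
  })
  out <- data.frame(
    cell_type = colnames(proportions),
    median_r = apply(proportions[y == 1, , drop = FALSE], 2, stats::median),
    median_nr = apply(proportions[y == 0, , drop = FALSE], 2, stats::median),
    p = unname(p), p_bh = bh_adjust(unname(p)),
    stringsAsFactors = FALSE)
  out$significant <- out$p_bh < 0.05
  rownames(out) <- NULL
  out
}
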