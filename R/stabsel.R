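#' Control parameters for stability-selected gradient boosting
#'
#' @param n_repeats number of resampled 70/30 selection repeats.
#' @param train_fraction fraction of samples in each training split.
#' @param cv logical; tune the number of boosting rounds per repeat by
#'   k-fold cross-validated early stopping on the training split.
#' @param cv_folds folds for the cross-validation.
#' @param nrounds boosting rounds (upper bound when `cv = TRUE`).
#' @param max_depth,eta,subsample gradient-boosting hyperparameters.
#' @param n_permutations shadow-variable refits used to set the selection
#'   threshold.
#' @param shadow_nrounds boosting rounds per shadow refit (reduced-cost
#'   refits; the shadow's importance, not predictive accuracy, is read off).
#' @param shadow_summary how the shadow importance distribution becomes a
#'   single selection bar: `"max"` (maximal-shadow rule, default) or
#'   `"quantile"`.
#' @param shadow_quantile quantile used when `shadow_summary = "quantile"`.
#' @param shadow_mode shadow construction: `"permute"` permutes a randomly
#'   chosen real probe across samples (label-independent by construction);
#'   `"noise"` injects an i.i.d. uniform feature.
#' @param shadow_drop which real probe is removed in each refit:
#'   `"different"` removes a probe chosen independently of the one
#'   permuted; `"same"` removes exactly the probe whose permuted copy is
#'   appended.
#' @param use_mvalues logical; model logit-transformed beta (M-values)
#'   instead of beta values.
#' @return list of class `stabsel_control`.
#' @export
stabsel_control <- function(n_repeats = 100, train_fraction = 0.7,
                            cv = TRUE, cv_folds = 10, nrounds = 200,
                            max_depth = 3, eta = 0.1, subsample = 0.8,
                            n_permutations = 1000, shadow_nrounds = 50,
                            shadow_summary = c("max", "quantile"),
                            shadow_quantile = 0.95,
                            shadow_mode = c("permute", "noise"),
                            shadow_drop = c("different", "same"),
                            use_mvalues = FALSE) {
  stopifnot(n_repeats >= 1, train_fraction > 0, train_fraction < 1,
            cv_folds >= 2, nrounds >= 1, n_permutations >= 0,
            shadow_nrounds >= 1)
  if (n_permutations > 0 && n_permutations < 50)
    warning("fewer than 50 shadow permutations gives an unstable threshold")
  structure(list(n_repeats = n_repeats, train_fraction = train_fraction,
                 cv = cv, cv_folds = cv_folds, nrounds = nrounds,
                 max_depth = max_depth, eta = eta, subsample = subsample,
                 n_permutations = n_permutations,
                 shadow_nrounds = shadow_nrounds,
                 shadow_summary = match.arg(shadow_summary),
                 shadow_quantile = shadow_quantile,
                 shadow_mode = match.arg(shadow_mode),
                 shadow_drop = match.arg(shadow_drop),
                 use_mvalues = use_mvalues),
            class = "stabsel_control")
}

# labels -> 0/1 integer vector, positive class "R" (or 1/TRUE)
.as_binary <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (!all(labels %in% c("R", "NR")))
      stop("character labels must be 'R'/'NR'")
    return(as.integer(labels == "R"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (all(labels %in% c(0, 1))) return(as.integer(labels))
  stop("labels must be R/NR, logical or 0/1")
}

# samples x features design matrix from a probes x samples beta matrix
.design <- function(betas, use_mvalues) {
  x <- t(betas)
  if (use_mvalues) {
    eps <- 1e-6
    x <- stats::qlogis(pmin(pmax(x, eps), 1 - eps))
  }
  x
}

.strat_sample <- function(y, fraction) {
  idx <- unlist(lapply(unique(y), function(cl) {
    i <- which(y == cl)
    sample(i, max(1, round(fraction * length(i))))
  }))
  sort(idx)
}

# Fit one booster; returns the model and its min-max-normalised total-gain
# importance over all features (unused features get 0).
.fit_gb <- function(x, y, control, nrounds, seed) {
  fit <- gbm_fit(x, y, nrounds = nrounds, eta = control$eta,
                 max_depth = control$max_depth,
                 subsample = control$subsample, seed = seed)
  v <- fit$importance
  if (max(v) > 0) v <- v / max(v)
  list(model = fit, importance = v)
}

# k-fold cross-validated round count: mean validation log-loss curve over
# the folds, minimised over rounds
.cv_nrounds <- function(x, y, control, seed) {
  k <- min(control$cv_folds, length(y))
  folds <- split(sample(seq_along(y)), rep_len(seq_len(k), length(y)))
  curves <- vapply(folds, function(f) {
    fit <- gbm_fit(x[-f, , drop = FALSE], y[-f],
                   nrounds = control$nrounds, eta = control$eta,
                   max_depth = control$max_depth,
                   subsample = control$subsample,
                   seed = sample.int(1e6, 1),
                   xval = x[f, , drop = FALSE], yval = y[f])
    fit$val_logloss
  }, numeric(control$nrounds))
  max(1L, which.min(rowMeans(curves)))
}

#' One stability-selection repeat
#'
#' Stratified 70/30 split, gradient-boosted trees fit on the training
#' split (optionally with cross-validated early stopping), normalised
#' feature importances and the held-out test AUROC.
#'
#' @param betas probes x samples beta matrix, complete (no NA).
#' @param labels response labels (R/NR, logical or 0/1; R is positive).
#' @param control [stabsel_control()].
#' @param seed integer seed for this repeat.
#' @return list: `importance` (normalised, named by probe), `auroc`
#'   (held-out test AUROC), `nrounds`, `train_idx`.
#' @export
stabsel_repeat <- function(betas, labels, control = stabsel_control(),
                           seed = 1) {
  y <- .as_binary(labels)
  if (min(table(y)) < 2) stop("need >= 2 samples per class")
  x <- .design(betas, control$use_mvalues)
  with_seed(seed, {
    repeat {
      tr <- .strat_sample(y, control$train_fraction)
      if (length(unique(y[tr])) == 2 &&
          length(unique(y[-tr])) == 2) break
      message("degenerate split resampled")
    }
    nrounds <- if (control$cv)
      .cv_nrounds(x[tr, , drop = FALSE], y[tr], control,
                  sample.int(1e6, 1)) else control$nrounds
    fit <- .fit_gb(x[tr, , drop = FALSE], y[tr], control, nrounds,
                   sample.int(1e6, 1))
    scores <- stats::predict(fit$model, x[-tr, , drop = FALSE])
    list(importance = fit$importance,
         auroc = auroc(scores, y[-tr]),
         nrounds = nrounds, train_idx = tr)
  })
}

#' Shadow-variable importance distribution
#'
#' Repeatedly refits the booster on data where one real probe has been
#' removed and one shadow probe appended (a permuted copy of a randomly
#' chosen real probe, so it carries the marginal distribution of real
#' methylation but no association with the labels). Each refit's
#' importances are min-max normalised and the shadow's value recorded;
#' the summary of this distribution is the selection bar.
#'
#' @inheritParams stabsel_repeat
#' @return numeric vector of length `control$n_permutations` of
#'   normalised shadow importances.
#' @export
shadow_importances <- function(betas, labels, control = stabsel_control(),
                               seed = 1) {
  y <- .as_binary(labels)
  x <- .design(betas, control$use_mvalues)
  p <- ncol(x)
  with_seed(seed, {
    vapply(seq_len(control$n_permutations), function(b) {
      src <- sample.int(p, 1)
      drop <- if (control$shadow_drop == "same") src else sample.int(p, 1)
      shadow <- if (control$shadow_mode == "permute")
        x[sample.int(nrow(x)), src] else stats::runif(nrow(x))
      xb <- cbind(x[, -drop, drop = FALSE], .shadow. = shadow)
      fit <- .fit_gb(xb, y, control, control$shadow_nrounds,
                     sample.int(1e6, 1))
      unname(fit$importance[".shadow."])
    }, numeric(1))
  })
}

#' Stability-selected gradient boosting with a shadow-variable threshold
#'
#' The core feature-selection procedure for two-group methylation
#' biomarker discovery at small n and large p. The data are resampled
#' `n_repeats` times into stratified 70/30 splits; a gradient-boosted tree
#' classifier is fit on each training split (10-fold cross-validated early
#' stopping by default) and its per-probe total-gain importances are
#' min-max normalised. The aggregated importance of a probe is the mean of
#' its normalised importances over all repeats. The selection threshold is
#' set by shadow-variable permutation: `n_permutations` reduced-cost
#' refits each carry one permuted (label-independent) shadow probe, and
#' the summary (by default the maximum) of the shadow's normalised
#' importances is the bar. Probes whose aggregated importance strictly
#' exceeds the bar form the predictor set.
#'
#' Probes containing missing values are excluded from selection (and
#' listed in the result); the procedure assumes complete features.
#'
#' @param betas probes x samples beta matrix.
#' @param labels response labels (R/NR, logical or 0/1; R is positive).
#' @param control [stabsel_control()].
#' @param seed master seed; all repeat and permutation seeds derive from
#'   it by counter, so results are reproducible end to end.
#' @return object of class `stabsel`: see Details. Key fields:
#'   `importance` (aggregated, sorted decreasing with deterministic
#'   probe-id tie-break), `predictor_set`, `shadow` (values, threshold,
#'   summary rule), `repeat_auroc`, `importance_matrix`.
#' @seealso [recalibrate()] for the downstream ensemble evaluation.
#' @export
stabsel <- function(betas, labels, control = stabsel_control(), seed = 1) {
  validate_beta_matrix(betas)
  stopifnot(inherits(control, "stabsel_control"))
  y <- .as_binary(labels)
  if (length(y) != ncol(betas)) stop("labels must match samples")
  complete <- !apply(is.na(betas), 1, any)
  dropped <- rownames(betas)[!complete]
  betas <- betas[complete, , drop = FALSE]
  # canonical probe order so selection is invariant to input row order
  betas <- betas[order(rownames(betas)), , drop = FALSE]
  seeds <- with_seed(seed,
    sample.int(.Machine$integer.max - 1, control$n_repeats + 2))
  reps <- lapply(seq_len(control$n_repeats), function(i)
    stabsel_repeat(betas, y, control, seeds[i]))
  imp_mat <- vapply(reps, `[[`, numeric(nrow(betas)), "importance")
  rownames(imp_mat) <- rownames(betas)
  agg <- rowMeans(imp_mat)
  shadow_vals <- if (control$n_permutations > 0)
    shadow_importances(betas, y, control, seeds[control$n_repeats + 1])
  else numeric(0)
  bar <- if (length(shadow_vals) == 0) 0
  else if (control$shadow_summary == "max") max(shadow_vals)
  else unname(stats::quantile(shadow_vals, control$shadow_quantile))
  ord <- order(-agg, names(agg))
  agg <- agg[ord]
  predictor_set <- names(agg)[agg > bar]
  structure(list(
    importance = agg,
    predictor_set = predictor_set,
    shadow = list(values = shadow_vals, threshold = bar,
                  summary = control$shadow_summary),
    repeat_auroc = vapply(reps, `[[`, numeric(1), "auroc"),
    repeat_nrounds = vapply(reps, `[[`, numeric(1), "nrounds"),
    importance_matrix = imp_mat,
    dropped_probes = dropped,
    n_samples = length(y), class_table = table(factor(y, 0:1)),
    control = control, seed = seed, call = match.call()),
    class = "stabsel")
}

#' @export
print.stabsel <- function(x, ...) {
  cat("Stability-selected gradient boosting\n")
  cat(sprintf("  %d probes x %d samples (%d R / %d NR), %d repeats\n",
              nrow(x$importance_matrix), x$n_samples,
              x$class_table["1"], x$class_table["0"],
              x$control$n_repeats))
  cat(sprintf("  shadow bar (%s of %d permutation refits): %.4f\n",
              x$shadow$summary, length(x$shadow$values),
              x$shadow$threshold))
  cat(sprintf("  predictor set: %d probes\n", length(x$predictor_set)))
  cat(sprintf("  mean held-out AUROC over repeats: %.3f\n",
              mean(x$repeat_auroc)))
  invisible(x)
}

#' @export
summary.stabsel <- function(object, n_top = 10, ...) {
  print(object)
  k <- min(n_top, length(object$importance))
  cat("\nTop probes by aggregated importance:\n")
  print(round(object$importance[seq_len(k)], 4))
  if (length(object$dropped_probes) > 0)
    cat(sprintf("\n%d probes excluded for missing values\n",
                length(object$dropped_probes)))
  invisible(object)
}

#' @export
coef.stabsel <- function(object, ...) object$importance

#' @export
plot.stabsel <- function(x, n_top = 25, ...) {
  k <- min(n_top, length(x$importance))
  v <- rev(x$importance[seq_len(k)])
  graphics::barplot(v, horiz = TRUE, las = 1, cex.names = 0.6,
                    xlab = "aggregated normalised importance",
                    main = "stability-selected probes", ...)
  graphics::abline(v = x$shadow$threshold, col = 2, lty = 2)
  invisible(x)
}
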