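#' Empirical ROC curve
#'
#' Operating points swept over the distinct score values, ties grouped, so
#' the curve (and its trapezoidal area) matches the rank-statistic
#' definition of the AUROC with mid-ranked ties.
#'
#' @param scores numeric classifier scores, higher = more positive.
#' @param labels binary labels (1/0, TRUE/FALSE or R/NR).
#' @return data.frame with columns `fpr`, `tpr`, monotone non-decreasing,
#'   from (0,0) to (1,1).
#' @export
roc_curve <- function(scores, labels) {
  y <- .as_binary(labels)
  if (length(unique(y)) < 2) stop("ROC undefined: single-class labels")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  keep <- c(diff(s) != 0, TRUE)  # last index of each tie group
  tp <- cumsum(y)[keep]; fp <- cumsum(1 - y)[keep]
  data.frame(fpr = c(0, fp / sum(1 - y)), tpr = c(0, tp / sum(y)))
}

#' Area under the ROC curve
#'
#' Trapezoid rule over the empirical ROC of [roc_curve()]; equals the
#' Mann-Whitney U statistic divided by the number of positive-negative
#' pairs.
#'
#' @inheritParams roc_curve
#' @return AUROC in \[0, 1\]; `NA` with a warning for single-class labels.
#' @export
auroc <- function(scores, labels) {
  y <- .as_binary(labels)
  if (length(unique(y)) < 2) {
    warning("AUROC undefined: single-class labels")
    return(NA_real_)
  }
  rc <- roc_curve(scores, y)
  sum(diff(rc$fpr) * (rc$tpr[-1] + rc$tpr[-nrow(rc)]) / 2)
}

#' Classification metrics at a decision threshold
#'
#' @inheritParams roc_curve
#' @param threshold predicted-probability cutoff for the positive call.
#' @return list: sensitivity, specificity, precision, recall (=
#'   sensitivity), f1, auroc, and the confusion counts (tp, fp, tn, fn).
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  y <- .as_binary(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(sensitivity = sens, specificity = spec, precision = prec,
       recall = sens, f1 = f1,
       auroc = if (length(unique(y)) == 2) auroc(scores, y) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Positive/negative likelihood ratios and post-test probability
#'
#' `lr_plus = sensitivity / (1 - specificity)`; the post-test probability
#' updates the pre-test odds by `lr_plus` (Bayes). At the operating point
#' a 0.70-sensitive, 0.70-specific classifier gives `lr_plus = 2.33`.
#'
#' @param sensitivity,specificity operating point, each in \[0, 1\].
#' @param pretest pre-test probability of the outcome, in (0, 1).
#' @return list: `lr_plus` (`Inf` when specificity = 1), `lr_minus`,
#'   `pretest`, `posttest`.
#' @export
likelihood_summary <- function(sensitivity, specificity, pretest) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            pretest > 0, pretest < 1)
  lr_plus <- if (specificity < 1) sensitivity / (1 - specificity) else Inf
  lr_minus <- if (specificity > 0) (1 - sensitivity) / specificity else Inf
  odds <- pretest / (1 - pretest)
  post <- if (is.finite(lr_plus)) lr_plus * odds / (1 + lr_plus * odds) else 1
  list(lr_plus = lr_plus, lr_minus = lr_minus,
       pretest = pretest, posttest = post)
}

# tpr of a step ROC at given fpr values (vertical averaging support)
.tpr_at <- function(rc, grid) {
  vapply(grid, function(g) max(rc$tpr[rc$fpr <= g]), numeric(1))
}

#' Recalibrated ensemble evaluation
#'
#' Withholds one stratified holdout (20% by default), then trains
#' `n_models` gradient boosters on resampled stratified subsets of the
#' remaining samples, restricted to the predictor probes, and evaluates
#' every model on the same holdout. The reported ROC curve is the vertical
#' average of the per-model curves over a common false-positive-rate grid;
#' summary metrics are arithmetic means over models.
#'
#' @param object a [stabsel] fit (its `predictor_set` is used), or a
#'   character vector of probe ids.
#' @param betas probes x samples beta matrix.
#' @param labels response labels (R positive).
#' @param n_models ensemble size.
#' @param holdout_fraction fraction withheld once for evaluation.
#' @param per_model_split logical; draw a fresh holdout per model instead
#'   of one shared holdout.
#' @param control [stabsel_control()]; booster hyperparameters reused.
#' @param seed master seed.
#' @param ... unused.
#' @return object of class `ssgb_ensemble`: per-model `metrics`
#'   data.frame, `mean_metrics`, averaged `roc` (fpr, tpr_mean, tpr_sd),
#'   fitted `models`, `features`, `holdout` sample ids.
#' @export
recalibrate <- function(object, ...) UseMethod("recalibrate")

#' @rdname recalibrate
#' @export
recalibrate.stabsel <- function(object, betas, labels, ...) {
  if (length(object$predictor_set) == 0)
    stop("empty predictor set: nothing to recalibrate")
  recalibrate(object$predictor_set, betas, labels,
              control = object$control, ...)
}

#' @rdname recalibrate
#' @export
recalibrate.character <- function(object, betas, labels, n_models = 50,
                                  holdout_fraction = 0.2,
                                  per_model_split = FALSE,
                                  control = stabsel_control(), seed = 1,
                                  ...) {
  validate_beta_matrix(betas)
  features <- object
  miss <- setdiff(features, rownames(betas))
  if (length(miss) > 0) stop("features absent from matrix: ",
                             paste(miss, collapse = ", "))
  features <- sort(features)  # canonical order: invariant to input order
  y <- .as_binary(labels)
  x <- .design(betas[features, , drop = FALSE], control$use_mvalues)
  grid <- seq(0, 1, length.out = 101)
  cl <- match.call()
  with_seed(seed, {
    pool_split <- function() {
      ho <- .strat_sample(y, holdout_fraction)
      if (length(unique(y[ho])) < 2 || length(unique(y[-ho])) < 2)
        stop("holdout lacks a class; increase holdout_fraction")
      ho
    }
    holdout <- if (!per_model_split) pool_split() else NULL
    fits <- lapply(seq_len(n_models), function(m) {
      ho <- if (per_model_split) pool_split() else holdout
      pool <- setdiff(seq_along(y), ho)
      tr <- pool[.strat_sample(y[pool], control$train_fraction)]
      fit <- .fit_gb(x[tr, , drop = FALSE], y[tr], control,
                     control$nrounds, sample.int(1e6, 1))
      scores <- stats::predict(fit$model, x[ho, , drop = FALSE])
      mets <- classification_metrics(scores, y[ho])
      rc <- roc_curve(scores, y[ho])
      list(model = fit$model, metrics = mets, tpr = .tpr_at(rc, grid),
           holdout = ho)
    })
    tpr_mat <- vapply(fits, `[[`, numeric(length(grid)), "tpr")
    met_names <- c("sensitivity", "specificity", "precision", "recall",
                   "f1", "auroc")
    met_df <- as.data.frame(t(vapply(fits, function(f)
      unlist(f$metrics[met_names]), numeric(length(met_names)))))
    met_df <- cbind(model = seq_len(n_models), met_df)
    conf <- colSums(t(vapply(fits, function(f)
      unlist(f$metrics[c("tp", "fp", "tn", "fn")]), numeric(4))))
    structure(list(
      metrics = met_df,
      mean_metrics = colMeans(met_df[met_names], na.rm = TRUE),
      roc = data.frame(fpr = grid, tpr_mean = rowMeans(tpr_mat),
                       tpr_sd = apply(tpr_mat, 1, stats::sd)),
      confusion_totals = conf,
      models = lapply(fits, `[[`, "model"),
      features = features,
      holdout = if (!per_model_split) colnames(betas)[holdout] else NULL,
      per_model_split = per_model_split,
      n_models = n_models, control = control, seed = seed,
      call = cl),
      class = "ssgb_ensemble")
  })
}

#' @export
print.ssgb_ensemble <- function(x, ...) {
  cat(sprintf("Recalibrated gradient-boosting ensemble: %d models on %d probes\n",
              x$n_models, length(x$features)))
  m <- x$mean_metrics
  cat(sprintf("  mean AUROC %.3f | precision %.3f | recall %.3f | F1 %.3f\n",
              m["auroc"], m["precision"], m["recall"], m["f1"]))
  cat(sprintf("  mean sensitivity %.3f | specificity %.3f\n",
              m["sensitivity"], m["specificity"]))
  invisible(x)
}

#' @export
summary.ssgb_ensemble <- function(object, ...) {
  print(object)
  cat("\nPer-model metric spread:\n")
  print(summary(object$metrics[-1]))
  invisible(object)
}

#' @export
plot.ssgb_ensemble <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr_mean, type = "l", lwd = 2,
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("mean ROC over %d models (AUROC %.2f)",
                                x$n_models, x$mean_metrics["auroc"]), ...)
  graphics::lines(x$roc$fpr,
                  pmin(1, x$roc$tpr_mean + x$roc$tpr_sd), lty = 3)
  graphics::lines(x$roc$fpr,
                  pmax(0, x$roc$tpr_mean - x$roc$tpr_sd), lty = 3)
  graphics::abline(0, 1, col = "grey")
  invisible(x)
}

#' Predict response probabilities from a recalibrated ensemble
#'
#' @param object `ssgb_ensemble`.
#' @param newdata probes x samples beta matrix containing the ensemble's
#'   predictor probes.
#' @param ... unused.
#' @return named vector of mean predicted responder probabilities.
#' @export
predict.ssgb_ensemble <- function(object, newdata, ...) {
  x <- .design(newdata[object$features, , drop = FALSE],
               object$control$use_mvalues)
  preds <- vapply(object$models, function(m) stats::predict(m, x),
                  numeric(nrow(x)))
  stats::setNames(rowMeans(preds), colnames(newdata))
}
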