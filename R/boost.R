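#' Gradient-boosted tree classifier
#'
#' Second-order (Newton) boosting of depth-limited regression trees on the
#' logistic loss, with exact greedy split search — the classical gradient
#' boosting machine specialised to two-class problems at small n and large
#' p. Leaf weights carry an L2 penalty (lambda = 1), children must hold a
#' minimum hessian weight of 1, and rows can be subsampled per tree.
#' Entirely deterministic given the seed: split ties break on feature
#' index then threshold, and subsampling uses a seeded generator.
#'
#' @param x numeric matrix, samples x features.
#' @param y binary labels (0/1, logical, or R/NR with R positive).
#' @param nrounds number of trees.
#' @param eta learning rate.
#' @param max_depth maximum tree depth.
#' @param subsample fraction of rows drawn (without replacement) per tree.
#' @param seed integer seed for subsampling.
#' @param xval,yval optional validation set; when given, the fit records
#'   the validation log-loss after every round (used for early stopping).
#' @return object of class `stab_gbm`: `trees`, `importance` (total split
#'   gain per feature, named), `train_pred`, `val_logloss`, `nrounds` and
#'   the call parameters.
#' @export
gbm_fit <- function(x, y, nrounds = 200, eta = 0.1, max_depth = 3,
                    subsample = 1, seed = 1, xval = NULL, yval = NULL) {
  x <- as.matrix(x)
  y <- .as_binary(y)
  stopifnot(nrow(x) == length(y), nrounds >= 1, eta > 0,
            max_depth >= 1, subsample > 0, subsample <= 1)
  res <- .gbm_train_cpp(x, as.numeric(y), as.integer(nrounds), eta,
                        as.integer(max_depth), subsample,
                        as.integer(seed %% .Machine$integer.max),
                        if (is.null(xval)) NULL else as.matrix(xval),
                        if (is.null(yval)) NULL else
                          as.numeric(.as_binary(yval)))
  imp <- res$importance
  names(imp) <- colnames(x)
  structure(list(trees = res$trees, importance = imp,
                 train_pred = res$train_pred,
                 val_logloss = res$val_logloss,
                 nrounds = nrounds, eta = eta, max_depth = max_depth,
                 subsample = subsample, seed = seed,
                 feature_names = colnames(x)),
            class = "stab_gbm")
}

#' Predict responder probabilities from a boosted tree model
#'
#' @param object `stab_gbm` fit.
#' @param newdata numeric matrix, samples x features, with the training
#'   feature columns (matched by name when available).
#' @param nrounds use only the first `nrounds` trees (default all).
#' @param ... unused.
#' @return vector of predicted probabilities.
#' @export
predict.stab_gbm <- function(object, newdata, nrounds = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  if (ncol(newdata) != length(object$importance))
    stop("newdata must carry the training features")
  .gbm_predict_cpp(object$trees, newdata,
                   as.integer(if (is.null(nrounds)) 0 else nrounds))
}

#' @export
print.stab_gbm <- function(x, ...) {
  cat(sprintf("Gradient-boosted trees: %d rounds, depth %d, eta %g, subsample %g\n",
              x$nrounds, x$max_depth, x$eta, x$subsample))
  used <- sum(x$importance > 0)
  cat(sprintf("  %d of %d features used in splits\n", used,
              length(x$importance)))
  invisible(x)
}
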