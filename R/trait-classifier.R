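# Methylation-based categorical predictors of species and sex.  These serve
# as a data-integrity check (plate-map or labelling errors), not as field
# sexing tools: strongly separable methylation signatures should classify
# perfectly out of bag.  The forest itself is the standard random forest;
# the contract here is the out-of-bag protocol — every sample is scored only
# by trees whose bootstrap excluded it.

#' Random-forest predictor of a categorical trait
#'
#' Trains a random forest (bootstrap-aggregated trees, `sqrt(p)` candidate
#' features per split) on beta values and reports the out-of-bag error and
#' confusion matrix.  Samples with label `"unknown"` or `NA` are excluded
#' (e.g. animals of unrecorded sex).
#'
#' @param beta numeric matrix, probes x samples.
#' @param labels character/factor vector of class labels, one per sample
#'   (column of `beta`).
#' @param n_trees number of trees (default 500).
#' @param seed integer seed.
#' @param target label of what is being predicted, recorded in the report
#'   (e.g. `"species"` or `"sex"`).
#' @return object of class `classifier_report`: `target`, `oob_error`,
#'   `confusion` (OOB votes only), `n_trees`, `seed`, `n_oob` (samples with
#'   at least one OOB vote), and the fitted `forest`.
#' @export
fit_rf_classifier <- function(beta, labels, n_trees = 500, seed = NULL,
                              target = "species") {
  keep <- !is.na(labels) & labels != "unknown"
  labels <- factor(as.character(labels[keep]))
  if (nlevels(labels) < 2L) stop("need at least 2 classes to train a classifier")
  if (any(table(labels) < 2L)) stop("every class needs at least 2 samples")
  X <- t(beta[, keep, drop = FALSE])
  rf <- with_seed_(seed,
    randomForest::randomForest(x = X, y = labels, ntree = n_trees))
  oob_pred <- rf$predicted                 # OOB votes only; NA if never OOB
  scored <- !is.na(oob_pred)
  oob_error <- mean(oob_pred[scored] != labels[scored])
  confusion <- table(truth = labels[scored], oob_prediction = oob_pred[scored])
  structure(list(target = target, oob_error = oob_error,
                 confusion = confusion, n_trees = n_trees, seed = seed,
                 n_oob = sum(scored), forest = rf),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Random-forest %s predictor: %d trees, OOB error = %.4f (%d/%d scored)\n",
              x$target, x$n_trees, x$oob_error, x$n_oob,
              sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}
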