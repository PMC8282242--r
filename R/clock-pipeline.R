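# Training, applying and cross-validating epigenetic clocks.  A clock is a
# sparse linear model on beta values whose output, after inverting the age
# transform with the sample's species parameters, is an age estimate in
# years (DNAm age).  Accuracy is always reported in years: Pearson R between
# DNAm age and chronological age, and the median absolute error.

align_design_ <- function(beta, samples, impute = FALSE) {
  missing_samples <- setdiff(samples$sample_id, colnames(beta))
  if (length(missing_samples))
    stop("samples absent from beta matrix: ",
         paste(missing_samples, collapse = ", "))
  X <- t(beta[, samples$sample_id, drop = FALSE])
  if (anyNA(X)) {
    if (!impute)
      stop("beta matrix contains missing values; set impute = TRUE for ",
           "per-probe mean imputation or remove the probes")
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  X
}

#' Train an epigenetic clock
#'
#' Regresses the transformed age of each sample on its beta values with the
#' elastic net (alpha 0.5 by default), the penalty chosen by internal
#' 10-fold cross-validation on the training set.  Multi-species training
#' puts all species in one design matrix with no species indicator: a
#' single formula serves every species, differing only through the
#' per-species transform parameters.
#'
#' @param beta numeric matrix, probes x samples (see [read_beta_matrix()]).
#' @param samples data.frame of sample records ([read_sample_sheet()]); all
#'   must be columns of `beta`.
#' @param transform an [age_transform()]; the dual-elephant clock uses
#'   `"identity"`, the multi-species chronological clock `"loglinear"`, the
#'   multi-species relative clock `"relative"`.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param seed integer seed for the internal CV fold shuffle.
#' @param n_folds internal CV folds for penalty selection (default 10).
#' @param n_lambda length of the penalty path (default 100).
#' @param impute impute missing betas by per-probe training means.
#' @return object of class `clock_model`: `intercept`, named nonzero
#'   `coefficients`, `alpha`, `lambda`, `transform`, `training_species`,
#'   `n_train`, `probe_means` (training means of the model probes, used for
#'   optional imputation at prediction time), and `cv_curve`.
#' @export
train_clock <- function(beta, samples, transform, alpha = 0.5, seed = NULL,
                        n_folds = 10, n_lambda = 100, impute = FALSE) {
  stopifnot(inherits(transform, "age_transform"))
  X <- align_design_(beta, samples, impute = impute)
  y <- transform_age(transform, samples$age_years, samples$species)
  if (nrow(X) < n_folds)
    stop(sprintf("need at least n_folds = %d samples to train", n_folds))
  if (var(y) == 0) {
    warning("degenerate response: all transformed ages identical; ",
            "returning an intercept-only model")
    model <- list(intercept = mean(y), coefficients = setNames(numeric(0), character(0)),
                  alpha = alpha, lambda = Inf, transform = transform,
                  training_species = sort(unique(samples$species)),
                  n_train = nrow(X),
                  probe_means = setNames(numeric(0), character(0)),
                  cv_curve = NULL)
    return(structure(model, class = "clock_model"))
  }
  cv <- cv_select_lambda(X, y, alpha = alpha, n_folds = n_folds, seed = seed,
                         n_lambda = n_lambda)
  l_idx <- which(cv$fit$lambdas == cv$lambda_min)[1L]
  coefs <- cv$fit$beta[, l_idx]
  nz <- coefs[coefs != 0]
  structure(list(intercept = cv$fit$intercepts[l_idx],
                 coefficients = nz, alpha = alpha, lambda = cv$lambda_min,
                 transform = transform,
                 training_species = sort(unique(samples$species)),
                 n_train = nrow(X),
                 probe_means = colMeans(X[, names(nz), drop = FALSE]),
                 cv_curve = cv$cv_curve),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("Epigenetic clock: %d CpGs, alpha = %g, lambda = %.4g\n",
              length(x$coefficients), x$alpha, x$lambda))
  cat(sprintf("  transform: %s | trained on %d samples (%s)\n",
              x$transform$kind, x$n_train,
              paste(x$training_species, collapse = ", ")))
  invisible(x)
}

#' Estimate DNAm age
#'
#' Applies a clock to a beta matrix: linear predictor on the model's CpGs,
#' then the inverse age transform with each sample's species parameters.
#'
#' @param model a `clock_model`.
#' @param beta numeric matrix, probes x samples.
#' @param samples data.frame with `sample_id` and `species` columns (the
#'   species picks the inverse-transform parameters); defaults to all
#'   columns of `beta` with an unspecified species, which is only valid for
#'   the identity transform.
#' @param impute if `TRUE`, probes absent from `beta` are filled with their
#'   training means; otherwise missing probes are an error.
#' @return numeric vector of estimated ages in years, named by sample.
#' @export
predict_age <- function(model, beta, samples = NULL, impute = FALSE) {
  stopifnot(inherits(model, "clock_model"))
  if (is.null(samples))
    samples <- data.frame(sample_id = colnames(beta), species = NA_character_,
                          stringsAsFactors = FALSE)
  probes <- names(model$coefficients)
  absent <- setdiff(probes, rownames(beta))
  if (length(absent) && !impute)
    stop("model probes absent from beta matrix: ",
         paste(absent, collapse = ", "))
  present <- setdiff(probes, absent)
  B <- beta[present, samples$sample_id, drop = FALSE]
  if (anyNA(B)) {
    if (!impute) stop("missing beta values for model probes; set impute = TRUE")
    mu <- model$probe_means[present]
    idx <- which(is.na(B), arr.ind = TRUE)
    B[idx] <- mu[idx[, 1L]]
  }
  lp <- model$intercept + drop(crossprod(B, model$coefficients[present]))
  if (length(absent))
    lp <- lp + sum(model$coefficients[absent] * model$probe_means[absent])
  setNames(inverse_transform_age(model$transform, lp, samples$species),
           samples$sample_id)
}

cv_report_ <- function(sample_id, fold_index, true_age, pred_age) {
  per_sample <- data.frame(sample_id = sample_id, fold_index = fold_index,
                           true_age_years = true_age,
                           predicted_age_years = pred_age,
                           stringsAsFactors = FALSE)
  r <- if (sd(pred_age) == 0 || sd(true_age) == 0) NA_real_ else
    cor(true_age, pred_age)
  structure(list(per_sample = per_sample, pearson_r = r,
                 mae_years = median(abs(pred_age - true_age)),
                 n = nrow(per_sample)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Clock cross-validation: n = %d, R = %.3f, MAE = %.2f years\n",
              x$n, x$pearson_r, x$mae_years))
  invisible(x)
}

#' Leave-one-sample-out cross-validation of a clock
#'
#' Omits one sample at a time, trains the elastic net (with its own internal
#' 10-fold penalty selection) on the remainder, and predicts the held-out
#' sample's age.  The held-out sample never influences standardization,
#' penalty selection, or coefficients.  Metrics are computed in years after
#' the inverse transform.
#'
#' @inheritParams train_clock
#' @return object of class `cv_report`: `per_sample`
#'   (sample_id, fold_index, true_age_years, predicted_age_years),
#'   `pearson_r`, `mae_years`, `n`.
#' @export
loocv <- function(beta, samples, transform, alpha = 0.5, seed = NULL,
                  n_folds = 10, n_lambda = 100, impute = FALSE) {
  n <- nrow(samples)
  if (n < n_folds + 1L)
    stop(sprintf("LOOCV needs at least %d samples so the internal %d-fold CV fits",
                 n_folds + 1L, n_folds))
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- train_clock(beta, samples[-i, , drop = FALSE], transform,
                     alpha = alpha, seed = derive_seed_(seed, paste0("loo", i)),
                     n_folds = n_folds, n_lambda = n_lambda, impute = impute)
    pred[i] <- predict_age(m, beta, samples[i, , drop = FALSE], impute = impute)
  }
  cv_report_(samples$sample_id, seq_len(n), samples$age_years, pred)
}

#' Species-stratified k-fold cross-validation (LOFO10)
#'
#' Ten-fold cross-validation in which every left-out fraction preserves the
#' species proportions of the full data: per-species fold sizes differ by at
#' most one from exact proportionality.
#'
#' @inheritParams train_clock
#' @param cv_folds number of outer folds (default 10).
#' @param stratify_by sample-sheet column defining the strata (default
#'   `"species"`).
#' @return a `cv_report`, as for [loocv()].
#' @export
lofo10 <- function(beta, samples, transform, alpha = 0.5, seed = NULL,
                   cv_folds = 10, stratify_by = "species", n_folds = 10,
                   n_lambda = 100, impute = FALSE) {
  strata <- samples[[stratify_by]]
  small <- names(which(table(strata) < cv_folds))
  if (length(small))
    stop("stratum with fewer samples than folds (", paste(small, collapse = ", "),
         "); merge strata or use loocv()")
  fold <- stratified_folds(strata, cv_folds, seed = derive_seed_(seed, "lofo"))
  pred <- numeric(nrow(samples))
  for (k in seq_len(cv_folds)) {
    test <- fold == k
    m <- train_clock(beta, samples[!test, , drop = FALSE], transform,
                     alpha = alpha, seed = derive_seed_(seed, paste0("fold", k)),
                     n_folds = n_folds, n_lambda = n_lambda, impute = impute)
    pred[test] <- predict_age(m, beta, samples[test, , drop = FALSE],
                              impute = impute)
  }
  cv_report_(samples$sample_id, fold, samples$age_years, pred)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `n_folds` folds such that within every
#' stratum the fold sizes differ by at most one; which folds receive the
#' remainder samples is randomized under the seed.
#'
#' @param strata character/factor vector of stratum labels.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..n_folds.
#' @export
stratified_folds <- function(strata, n_folds, seed = NULL) {
  with_seed_(seed, {
    fold <- integer(length(strata))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      n_s <- length(idx)
      base <- n_s %/% n_folds
      rem <- n_s %% n_folds
      sizes <- rep(base, n_folds)
      if (rem > 0) sizes[sample.int(n_folds, rem)] <- base + 1L
      fold[sample(idx)] <- rep(seq_len(n_folds), times = sizes)
    }
    fold
  })
}

#' Epigenetic age acceleration
#'
#' The discrepancy between DNAm age and chronological age: either the raw
#' difference (`delta`, the default) or the residual from regressing DNAm
#' age on chronological age (`residual`, which is mean-zero and
#' uncorrelated with age by construction).
#'
#' @param predicted DNAm age in years.
#' @param chronological chronological age in years (same length).
#' @param method `"delta"` or `"residual"`.
#' @return numeric vector of accelerations in years.
#' @export
age_acceleration <- function(predicted, chronological,
                             method = c("delta", "residual")) {
  method <- match.arg(method)
  if (length(predicted) != length(chronological))
    stop("predicted and chronological must have the same length")
  if (method == "delta") return(predicted - chronological)
  stats::residuals(stats::lm(predicted ~ chronological))
}

#' Pairwise correlations between acceleration measures
#'
#' @param accels named list of acceleration vectors over the same samples
#'   (one per clock).
#' @return symmetric matrix of Pearson correlations with unit diagonal;
#'   entries involving a constant vector are `NA` with a warning.
#' @export
acceleration_correlations <- function(accels) {
  stopifnot(is.list(accels), length(accels) >= 2L)
  lens <- lengths(accels)
  if (length(unique(lens)) != 1L)
    stop("all acceleration vectors must cover the same samples")
  m <- do.call(cbind, accels)
  const <- apply(m, 2L, sd) == 0
  if (any(const))
    warning("constant acceleration vector(s): ",
            paste(names(accels)[const], collapse = ", "),
            "; correlations undefined (NA)")
  out <- suppressWarnings(cor(m))
  diag(out) <- 1
  out
}
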