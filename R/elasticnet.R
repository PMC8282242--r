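# Bespoke elastic-net gaussian regression: cyclic coordinate descent with a
# glmnet-style lambda path and internal k-fold cross-validation for the
# penalty.  Conventions follow the reference implementation the field uses:
# the loss is scaled by 1/(2n) so lambda is comparable across sample sizes,
# predictors are standardized with the population (1/n) standard deviation,
# and the intercept is never penalized.

#' Elastic-net penalized least squares
#'
#' Fits the gaussian elastic net
#' \deqn{\frac{1}{2n}\sum_i (y_i - b_0 - x_i^T b)^2 +
#'       \lambda\left(\alpha\|b\|_1 + \frac{1-\alpha}{2}\|b\|_2^2\right)}
#' by cyclic coordinate descent with soft-thresholding updates.  With
#' `standardize = TRUE` (the default) predictors are scaled to unit
#' population variance before descent and coefficients are returned on the
#' original scale; the penalty then applies on the standardized scale.  With
#' `standardize = FALSE` the returned coefficients minimize the objective
#' above exactly as written.
#'
#' @param X numeric matrix, samples in rows, predictors in columns.
#' @param y numeric response vector.
#' @param alpha elastic-net mixing parameter in \[0, 1\]; 1 is the lasso,
#'   0 is ridge.  The clock pipeline uses 0.5.
#' @param lambda non-negative penalty (a single value; see [lambda_path()]
#'   and [cv_select_lambda()] for sequences).
#' @param standardize scale predictors to unit population variance before
#'   descent.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change per sweep.
#' @param max_iter maximum number of coordinate-descent sweeps.
#' @param debug if `TRUE`, record the penalized objective after every sweep
#'   (used to assert monotone descent).
#' @return an object of class `enet_fit` with elements `intercept`, `coefs`
#'   (original predictor scale), `lambda`, `alpha`, `n_iter`, `converged`,
#'   and, when `debug = TRUE`, `objective_trace`.
#' @seealso [cv_select_lambda()], [lambda_path()], [enet_objective()]
#' @export
enet_fit <- function(X, y, alpha = 0.5, lambda, standardize = TRUE,
                     tol = 1e-7, max_iter = 1e5, debug = FALSE) {
  fit <- enet_path_fit(X, y, alpha = alpha, lambdas = lambda,
                       standardize = standardize, tol = tol,
                       max_iter = max_iter, debug = debug)
  out <- list(intercept = fit$intercepts[1L],
              coefs = fit$beta[, 1L],
              lambda = lambda, alpha = alpha,
              n_iter = fit$n_iter[1L], converged = fit$converged[1L])
  if (debug) out$objective_trace <- fit$objective_trace[[1L]]
  structure(out, class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf("Elastic-net fit: alpha = %g, lambda = %g, %d nonzero of %d, %s\n",
              x$alpha, x$lambda, sum(x$coefs != 0), length(x$coefs),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Fit a whole descending lambda sequence with warm starts.  Internal: the
# clock pipeline and CV loop use this; enet_fit() is the single-lambda face.
# With early_stop = TRUE the path is truncated once the deviance ratio
# improves by less than fdev (relative) per step or exceeds devmax, the
# convention of the reference implementation; the returned `lambdas` are
# the ones actually fit.
enet_path_fit <- function(X, y, alpha, lambdas, standardize = TRUE,
                          tol = 1e-7, max_iter = 1e5, debug = FALSE,
                          early_stop = FALSE, fdev = 1e-5, devmax = 0.999) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 2L) stop("need at least 2 samples")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in X or y")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (any(lambdas < 0)) stop("lambda must be non-negative")
  if (is.unsorted(rev(lambdas))) lambdas <- sort(lambdas, decreasing = TRUE)

  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm, "-")
  xs <- sqrt(colMeans(Xc^2))              # population sd
  zero_var <- xs <= .Machine$double.eps * 10
  if (standardize) {
    scl <- ifelse(zero_var, 1, xs)
    Xc <- sweep(Xc, 2L, scl, "/")
  } else scl <- rep(1, p)
  ym <- mean(y)
  yc <- y - ym

  res <- .enet_path_cpp(Xc, yc, as.numeric(lambdas), alpha, tol,
                        as.integer(max_iter), debug,
                        if (early_stop) fdev else 0, devmax)
  if (res$n_fitted < length(lambdas)) {
    keep <- seq_len(res$n_fitted)
    lambdas <- lambdas[keep]
    res$beta <- res$beta[, keep, drop = FALSE]
    res$n_iter <- res$n_iter[keep]
    res$converged <- res$converged[keep]
  }
  beta_std <- res$beta
  beta <- beta_std / scl                  # back to original predictor scale
  beta[zero_var, ] <- 0
  intercepts <- ym - drop(crossprod(xm, beta))
  dimnames(beta) <- list(colnames(X), NULL)
  out <- list(beta = beta, intercepts = intercepts,
              lambdas = lambdas, alpha = alpha,
              n_iter = res$n_iter, converged = res$converged)
  if (debug) out$objective_trace <- res$objective_trace
  out
}

#' Penalized elastic-net objective
#'
#' Evaluates \eqn{\frac{1}{2n}\|y - b_0 - Xb\|^2 +
#' \lambda(\alpha\|b\|_1 + \frac{1-\alpha}{2}\|b\|_2^2)} for given
#' coefficients; used by the test suite to compare the solver against
#' independent optimizers.
#'
#' @inheritParams enet_fit
#' @param intercept,coefs coefficients at which to evaluate the objective.
#' @return the objective value (scalar).
#' @export
enet_objective <- function(X, y, intercept, coefs, alpha, lambda) {
  r <- y - intercept - drop(as.matrix(X) %*% coefs)
  sum(r^2) / (2 * length(y)) +
    lambda * (alpha * sum(abs(coefs)) + 0.5 * (1 - alpha) * sum(coefs^2))
}

#' glmnet-style lambda sequence
#'
#' Computes `lambda_max`, the smallest penalty at which every coefficient is
#' zero, as \eqn{\max_j |x_j^T y| / (n\alpha)} on standardized predictors and
#' centered response, and returns a log-uniform descending grid down to
#' `lambda_max * min_ratio`.  For ridge (`alpha = 0`) the formula would be
#' infinite, so alpha is floored at 0.001 for the grid endpoint only.
#'
#' @inheritParams enet_fit
#' @param n_lambda number of grid points.
#' @param min_ratio ratio of the smallest to the largest lambda; default
#'   0.01 when `n < p`, else 0.0001.
#' @param standardize compute the gradient bound on standardized predictors.
#' @return descending numeric vector of length `n_lambda` (or the single
#'   value 0 when the response is orthogonal to every predictor).
#' @export
lambda_path <- function(X, y, alpha = 0.5, n_lambda = 100, min_ratio = NULL,
                        standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(min_ratio)) min_ratio <- if (n < p) 0.01 else 1e-4
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm, "-")
  if (standardize) {
    xs <- sqrt(colMeans(Xc^2))
    xs[xs <= .Machine$double.eps * 10] <- 1
    Xc <- sweep(Xc, 2L, xs, "/")
  }
  yc <- y - mean(y)
  a_eff <- max(alpha, 0.001)
  # nudge guards against rounding making the head-of-path solution nonzero
  lambda_max <- max(abs(drop(crossprod(Xc, yc)))) / (n * a_eff) * (1 + 1e-9)
  if (lambda_max <= 0) return(0)
  exp(seq(log(lambda_max), log(lambda_max * min_ratio), length.out = n_lambda))
}

#' Select the penalty by k-fold cross-validation
#'
#' Assigns samples to `n_folds` folds by a seeded shuffle, fits the full
#' lambda path on each training split (standardization redone within the
#' split, so held-out samples never touch it), and returns the lambda
#' minimizing mean out-of-fold squared error together with the full CV
#' curve.  Ties are broken toward the larger (sparser) lambda.
#'
#' @inheritParams enet_fit
#' @inheritParams lambda_path
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @param fold_id optional explicit fold assignment (overrides the shuffle).
#' @param cv_tol convergence tolerance for the fold fits; these only rank
#'   penalties, so a looser tolerance than the final fit's `tol` suffices.
#' @param tol convergence tolerance for the returned full-data fit.
#' @return list with `lambda_min`, `cv_curve` (data.frame of lambda, mse,
#'   se, n_nonzero; `n_nonzero` is `NA` below `lambda_min`, where the
#'   full-data path is not refit), `fold_id`, and `fit` (the path fit on
#'   the full data down to `lambda_min`, from which coefficients at
#'   `lambda_min` can be read).
#' @details Fold fits use warm-started paths with deviance-based early
#'   termination; where a fold's path stops early its last solution is
#'   carried forward to the remaining (smaller) penalties, whose fits would
#'   differ negligibly by the stopping rule.
#' @export
cv_select_lambda <- function(X, y, alpha = 0.5, n_folds = 10, seed = NULL,
                             n_lambda = 100, min_ratio = NULL,
                             standardize = TRUE, fold_id = NULL,
                             cv_tol = 1e-4, tol = 1e-7) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_folds)
    stop(sprintf("n = %d is smaller than n_folds = %d; use fewer folds", n, n_folds))
  lambdas <- lambda_path(X, y, alpha, n_lambda = n_lambda,
                         min_ratio = min_ratio, standardize = standardize)
  if (length(lambdas) == 1L && lambdas == 0) {
    fit <- enet_path_fit(X, y, alpha, lambdas = 0, standardize = standardize)
    return(list(lambda_min = 0,
                cv_curve = data.frame(lambda = 0, mse = mean((y - mean(y))^2),
                                      se = NA_real_, n_nonzero = 0L),
                fold_id = rep(1L, n), fit = fit))
  }
  if (is.null(fold_id)) {
    fold_id <- with_seed_(seed, sample(rep_len(seq_len(n_folds), n)))
  }
  sqerr <- matrix(NA_real_, n, length(lambdas))
  for (k in seq_len(n_folds)) {
    test <- fold_id == k
    fit_k <- enet_path_fit(X[!test, , drop = FALSE], y[!test], alpha,
                           lambdas = lambdas, standardize = standardize,
                           tol = cv_tol, early_stop = TRUE)
    nf <- length(fit_k$lambdas)
    pred <- sweep(X[test, , drop = FALSE] %*% fit_k$beta, 2L,
                  fit_k$intercepts, "+")
    if (nf < length(lambdas))              # carry the last solution forward
      pred <- cbind(pred, pred[, rep(nf, length(lambdas) - nf), drop = FALSE])
    sqerr[test, ] <- (pred - y[test])^2
  }
  fold_mse <- rowsum(sqerr, fold_id) / as.vector(table(fold_id))
  mse <- colMeans(fold_mse)
  se <- apply(fold_mse, 2L, sd) / sqrt(n_folds)
  best <- which(mse <= min(mse))[1L]      # lambdas descend: first = largest
  fit <- enet_path_fit(X, y, alpha, lambdas = lambdas[seq_len(best)],
                       standardize = standardize, tol = tol)
  nnz <- rep(NA_integer_, length(lambdas))
  nnz[seq_len(best)] <- colSums(fit$beta != 0)
  list(lambda_min = lambdas[best],
       cv_curve = data.frame(lambda = lambdas, mse = mse, se = se,
                             n_nonzero = nnz),
       fold_id = fold_id, fit = fit)
}
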