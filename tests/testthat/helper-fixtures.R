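# Shared fixtures: small in-memory datasets and an independent convex
# optimizer used as an oracle for the elastic-net solver.

# Tiny deterministic beta matrix with dimnames.
tiny_beta <- function(n_probes = 3, n_samples = 2, seed = 7) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples, 0.05, 0.95), n_probes, n_samples,
              dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                              sprintf("S%04d", seq_len(n_samples))))
  m
}

# Independent oracle for the elastic-net objective: split b = b+ - b- with
# b+, b- >= 0; the objective becomes smooth and is minimized by box-
# constrained L-BFGS.  Shares no code with the coordinate-descent solver.
enet_oracle <- function(X, y, alpha, lambda, maxit = 2000) {
  n <- nrow(X); p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  obj <- function(par) {
    b <- par[1:p] - par[(p + 1):(2 * p)]
    r <- yc - Xc %*% b
    sum(r^2) / (2 * n) + lambda * (alpha * sum(par) +
                                   0.5 * (1 - alpha) * sum(b^2))
  }
  grad <- function(par) {
    b <- par[1:p] - par[(p + 1):(2 * p)]
    g <- -drop(crossprod(Xc, yc - Xc %*% b)) / n + lambda * (1 - alpha) * b
    c(g + lambda * alpha, -g + lambda * alpha)
  }
  fit <- optim(rep(0, 2 * p), obj, grad, method = "L-BFGS-B",
               lower = 0, control = list(maxit = maxit, factr = 10))
  b <- fit$par[1:p] - fit$par[(p + 1):(2 * p)]
  b0 <- mean(y) - sum(colMeans(X) * b)
  list(intercept = b0, coefs = b, objective = fit$value)
}

# Sample sheet for n animals of one or two species with uniform ages.
toy_samples <- function(n = 20, species = "asian_elephant", seed = 3,
                        age_max = 50) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             species = rep_len(species, n),
             sex = sample(c("F", "M"), n, replace = TRUE),
             age_years = runif(n, 1, age_max),
             tissue = "blood", age_confidence = 100,
             stringsAsFactors = FALSE)
}

# Temp file path (testthat cleans the session tempdir).
tmpfile <- function() tempfile(fileext = ".txt")
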