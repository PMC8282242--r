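# Epigenome-wide association screening.  Age EWAS is a marginal Pearson
# correlation test per probe (p-values identical to a univariate
# regression); sex EWAS is an ordinary least-squares model on beta values
# adjusting for chronological age; cohorts are combined on the signed
# normal-scale Z statistics by Stouffer's method with sqrt(n) weights.

# signed z from a two-sided p: z = sign * qnorm(1 - p/2), computed on the
# upper tail for numerical accuracy at tiny p.
signed_z_ <- function(p, sign_of) {
  z <- qnorm(p / 2, lower.tail = FALSE)
  ifelse(sign_of < 0, -z, z)
}

#' Marginal correlation screen against a numeric trait
#'
#' For every probe computes the Pearson correlation with the trait, the
#' t statistic `r * sqrt(n-2) / sqrt(1-r^2)`, the two-sided p from the
#' Student-t distribution with n-2 df, and a signed normal-scale statistic
#' `z = sign(r) * qnorm(1 - p/2)`.  Observations are used
#' pairwise-complete per probe.  Zero-variance probes get `r = NA`,
#' `p = 1`, `z = 0`.
#'
#' @param beta numeric matrix, probes x samples.
#' @param trait numeric vector, one value per sample (e.g. chronological
#'   age).
#' @return data.frame with columns `probe_id`, `r`, `n`, `t_stat`, `p`, `z`.
#' @export
correlation_screen <- function(beta, trait) {
  if (length(trait) != ncol(beta))
    stop("trait length must equal the number of samples")
  ok_trait <- !is.na(trait)
  B <- beta[, ok_trait, drop = FALSE]
  tr <- trait[ok_trait]
  if (anyNA(B)) {
    n <- rowSums(!is.na(B))
    r <- suppressWarnings(apply(B, 1L, cor, y = tr, use = "pairwise.complete.obs"))
  } else {
    n <- rep(ncol(B), nrow(B))
    r <- suppressWarnings(drop(cor(t(B), tr)))
  }
  if (any(n < 3L)) stop("fewer than 3 complete observations for some probes")
  r[!is.na(r) & abs(r) > 1] <- sign(r[!is.na(r) & abs(r) > 1]) # guard fp drift
  t_stat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  z <- signed_z_(p, r)
  bad <- is.na(r)
  p[bad] <- 1; z[bad] <- 0; t_stat[bad] <- NA_real_
  data.frame(probe_id = rownames(beta), r = r, n = as.integer(n),
             t_stat = t_stat, p = p, z = z, stringsAsFactors = FALSE)
}

#' Stouffer combination of cohort Z statistics
#'
#' \deqn{z_{meta} = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}}}
#' with weights \eqn{w_i = \sqrt{n_i}} (default) or equal weights, and
#' \eqn{p_{meta} = 2(1 - \Phi(|z_{meta}|))}.  With a single cohort the
#' meta Z equals that cohort's Z.
#'
#' @param z numeric vector of per-cohort signed Z statistics (one probe).
#' @param n per-cohort sample sizes (positive).
#' @param weights `"sqrt_n"` or `"equal"`.
#' @return list with `z_meta` and `p_meta`.
#' @export
stouffer_combine <- function(z, n, weights = c("sqrt_n", "equal")) {
  weights <- match.arg(weights)
  if (length(z) != length(n) || !length(z)) stop("need matching z and n, >= 1 cohort")
  if (any(n <= 0)) stop("cohort sample sizes must be positive")
  w <- if (weights == "sqrt_n") sqrt(n) else rep(1, length(n))
  z_meta <- sum(w * z) / sqrt(sum(w^2))
  list(z_meta = z_meta, p_meta = 2 * pnorm(abs(z_meta), lower.tail = FALSE))
}

#' Meta-analyze EWAS tables across cohorts
#'
#' Joins per-cohort screens (from [correlation_screen()] or the sex
#' screens) on `probe_id` and applies [stouffer_combine()] row-wise.
#' Probes absent from any cohort are dropped.
#'
#' @param tables named list of EWAS data.frames (columns `probe_id`, `z`,
#'   `n`).
#' @inheritParams stouffer_combine
#' @return data.frame with `probe_id`, per-cohort `z_<cohort>` columns,
#'   `z_meta`, `p_meta`.
#' @export
ewas_meta <- function(tables, weights = c("sqrt_n", "equal")) {
  weights <- match.arg(weights)
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables))) names(tables) <- paste0("cohort", seq_along(tables))
  common <- Reduce(intersect, lapply(tables, `[[`, "probe_id"))
  zs <- sapply(tables, function(tb) tb$z[match(common, tb$probe_id)])
  ns <- sapply(tables, function(tb) tb$n[match(common, tb$probe_id)])
  if (length(common) == 1L) { zs <- matrix(zs, 1L); ns <- matrix(ns, 1L) }
  w <- if (weights == "sqrt_n") sqrt(ns) else array(1, dim(ns))
  z_meta <- rowSums(w * zs) / sqrt(rowSums(w^2))
  out <- data.frame(probe_id = common, stringsAsFactors = FALSE)
  for (k in seq_along(tables)) out[[paste0("z_", names(tables)[k])]] <- zs[, k]
  out$z_meta <- z_meta
  out$p_meta <- 2 * pnorm(abs(z_meta), lower.tail = FALSE)
  out
}

#' Select top CpGs by direction
#'
#' Keeps probes with `p < p_threshold`, splits them by the sign of `z`, and
#' within each direction ranks by `|z|` descending (ties broken by probe id)
#' and truncates at `cap_per_direction`.  The result is invariant to the
#' input row order.
#'
#' @param rows EWAS data.frame (columns `probe_id`, `p`, `z`).
#' @param p_threshold nominal significance threshold (default 1e-5).
#' @param cap_per_direction maximum probes kept per direction (default 500).
#' @return list with elements `positive` and `negative`, each a data.frame
#'   subset of `rows` in rank order.
#' @export
select_top <- function(rows, p_threshold = 1e-5, cap_per_direction = 500) {
  pick <- function(dir) {
    keep <- rows[!is.na(rows$p) & rows$p < p_threshold &
                   sign(rows$z) == dir, , drop = FALSE]
    keep <- keep[order(-abs(keep$z), keep$probe_id), , drop = FALSE]
    utils::head(keep, cap_per_direction)
  }
  list(positive = pick(1), negative = pick(-1))
}

#' Cross-cohort concordance of aging effects
#'
#' Labels each probe present in both screens: `shared` if both p-values
#' pass the threshold and the Z signs agree, `divergent` if both pass and
#' the signs differ, otherwise `not_significant`.  Probes present in only
#' one cohort are excluded and counted in the `n_excluded` attribute.
#'
#' @param rows_a,rows_b EWAS data.frames for the two cohorts.
#' @param p_threshold significance threshold applied in both cohorts.
#' @return data.frame with `probe_id`, `z_a`, `z_b`, `label`; attribute
#'   `n_excluded` counts single-cohort probes.
#' @export
concordance <- function(rows_a, rows_b, p_threshold = 1e-5) {
  common <- intersect(rows_a$probe_id, rows_b$probe_id)
  ia <- match(common, rows_a$probe_id)
  ib <- match(common, rows_b$probe_id)
  sig <- rows_a$p[ia] < p_threshold & rows_b$p[ib] < p_threshold
  same <- sign(rows_a$z[ia]) == sign(rows_b$z[ib])
  label <- ifelse(!sig, "not_significant", ifelse(same, "shared", "divergent"))
  out <- data.frame(probe_id = common, z_a = rows_a$z[ia], z_b = rows_b$z[ib],
                    label = factor(label, levels = c("shared", "divergent",
                                                     "not_significant")),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- length(rows_a$probe_id) + length(rows_b$probe_id) -
    2L * length(common)
  out
}

#' Genomic-context summary of selected CpGs
#'
#' Cross-tabulates the direction of the association (hypermethylated with
#' the trait: `z > 0`; hypomethylated: `z < 0`) against region class,
#' TSS-distance bin, and CpG-island status.  Probes without annotation are
#' counted under `"unannotated"`.
#'
#' @param rows EWAS data.frame of the selected probes (columns `probe_id`,
#'   `z`).
#' @param annot probe annotation data.frame ([read_probe_annotation()]).
#' @param tss_bins breakpoints in bp for the TSS-distance bins.
#' @return data.frame with `context_type` (region/tss_bin/cgi), `context`,
#'   `n_hyper`, `n_hypo`.
#' @export
context_summary <- function(rows, annot,
                            tss_bins = c(-Inf, -1e4, -2e3, 0, 2e3, 1e4, Inf)) {
  idx <- match(rows$probe_id, annot$probe_id)
  hyper <- rows$z > 0
  tab_of <- function(ctx, type, base_levels) {
    ctx[is.na(ctx)] <- "unannotated"
    lev <- union(base_levels, unique(ctx))
    data.frame(context_type = rep(type, length(lev)), context = lev,
               n_hyper = vapply(lev, function(l) sum(hyper & ctx == l), 1L),
               n_hypo = vapply(lev, function(l) sum(!hyper & ctx == l), 1L),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  region <- annot$region_class[idx]
  bin_labels <- levels(cut(tss_bins[-1] - 1, breaks = tss_bins))
  tssb <- as.character(cut(annot$tss_distance[idx], breaks = tss_bins))
  cgi <- c("non_CGI", "CGI")[annot$cgi[idx] + 1L]
  rbind(tab_of(region, "region", REGION_LEVELS),
        tab_of(tssb, "tss_bin", bin_labels),
        tab_of(cgi, "cgi", c("non_CGI", "CGI")))
}

# Vectorized per-probe ordinary least squares on a shared design; returns
# the statistics for one chosen coefficient.
ols_screen_ <- function(beta, design, term) {
  Y <- t(beta)
  n <- nrow(Y); k <- ncol(design)
  if (n <= k) stop(sprintf("need more than %d samples for %d model terms", k, k))
  qr_x <- qr(design)
  if (qr_x$rank < k) stop("rank-deficient design (collinear covariates)")
  coefs <- qr.coef(qr_x, Y)
  res <- Y - design %*% coefs
  df <- n - k
  sigma2 <- colSums(res^2) / df
  xtxinv_kk <- solve(crossprod(design))[term, term]
  est <- coefs[term, ]
  se <- sqrt(sigma2 * xtxinv_kk)
  t_stat <- ifelse(se > 0, est / se, NA_real_)
  p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  z <- signed_z_(p, est)
  bad <- is.na(t_stat)
  p[bad] <- 1; z[bad] <- 0
  data.frame(probe_id = rownames(beta), estimate = est, n = n,
             t_stat = t_stat, p = p, z = z, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Sex EWAS adjusted for chronological age
#'
#' Per probe fits `beta ~ sex + age` by ordinary least squares (on beta
#' values) and reports the sex-coefficient t statistic (female minus male),
#' two-sided p with n-3 df, and the signed normal-scale z.  With
#' `adjust_for_age = FALSE` the model is `beta ~ sex` (n-2 df); in designs
#' where age and sex are confounded this inflates sex significance and is
#' provided only for comparison.
#'
#' @param beta numeric matrix, probes x samples.
#' @param samples sample sheet data.frame (`sex` in F/M, `age_years`).
#' @param adjust_for_age include chronological age as a covariate (default
#'   `TRUE`).
#' @return data.frame with `probe_id`, `estimate`, `n`, `t_stat`, `p`, `z`.
#' @export
sex_screen <- function(beta, samples, adjust_for_age = TRUE) {
  keep <- samples$sex %in% c("F", "M")
  samples <- samples[keep, , drop = FALSE]
  beta <- beta[, samples$sample_id, drop = FALSE]
  if (length(unique(samples$sex)) < 2L)
    stop("sex screen requires both sexes")
  female <- as.numeric(samples$sex == "F")
  design <- if (adjust_for_age)
    cbind(intercept = 1, female = female, age = samples$age_years)
  else cbind(intercept = 1, female = female)
  ols_screen_(beta, design, term = "female")
}

#' Sex-by-age interaction screen
#'
#' Per probe fits `beta ~ sex + age + sex:age` and reports the interaction
#' coefficient's t statistic (n-4 df), two-sided p, and signed z —
#' identifying CpGs whose aging pattern differs between females and males.
#'
#' @inheritParams sex_screen
#' @return data.frame as for [sex_screen()].
#' @export
interaction_screen <- function(beta, samples) {
  keep <- samples$sex %in% c("F", "M")
  samples <- samples[keep, , drop = FALSE]
  beta <- beta[, samples$sample_id, drop = FALSE]
  if (length(unique(samples$sex)) < 2L)
    stop("interaction screen requires both sexes")
  female <- as.numeric(samples$sex == "F")
  design <- cbind(intercept = 1, female = female, age = samples$age_years,
                  female_age = female * samples$age_years)
  ols_screen_(beta, design, term = "female_age")
}

#' Write an EWAS table as TSV
#'
#' @param rows EWAS data.frame.
#' @param path output path.
#' @export
write_ewas <- function(rows, path) {
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE)
  invisible(path)
}
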