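# Synthetic mammalian-array-like datasets with known ground truth.  The
# generator emulates the structure the pipeline is built for: two elephant
# species with zoo-population demographics, a conserved-probe panel in
# which a subset changes monotonically with age (hypermethylation enriched
# at promoters/CpG islands, hypomethylation elsewhere), X-linked
# sex-differential probes clustered on one scaffold, and species-level
# baseline offsets.  Effects act on the logit scale; betas are the inverse
# logit clipped to (0,1), so linear analysis on the beta scale remains
# sensible while values stay bounded.

#' Simulation configuration
#'
#' @param n_per_species named integer vector: samples per species.
#' @param age_range named list of `c(min, max)` ages in years per species.
#' @param n_probes total probes on the synthetic array.
#' @param n_age_probes probes with a true age effect.
#' @param n_sex_probes probes with a true sex effect (placed on scaffold
#'   `"X_like"`).
#' @param n_species_probes probes with a species baseline offset.
#' @param age_effect_sd scale (logit units per unit of transformed age) of
#'   the half-normal age-slope magnitudes.
#' @param sex_effect sex-difference magnitude, logit units.
#' @param species_effect species-offset magnitude, logit units.
#' @param noise_sd residual noise on the logit scale.
#' @param cgi_hyper_bias probability that an age probe in a CpG island or
#'   promoter gains methylation with age (probes elsewhere gain with
#'   probability `1 - cgi_hyper_bias`).
#' @param female_fraction probability a sample is female.
#' @param age_dist `"uniform"` across the age range, or `"zoo_skew"` (a
#'   mid-life-weighted mixture mimicking managed-population age pyramids).
#' @param seed integer seed; the generator is byte-reproducible given the
#'   config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_per_species = c(asian_elephant = 83, african_elephant = 57),
                       age_range = list(asian_elephant = c(2.36, 73.6),
                                        african_elephant = c(1.20, 48.5)),
                       n_probes = 2000, n_age_probes = 200,
                       n_sex_probes = 50, n_species_probes = 50,
                       age_effect_sd = 1.5, sex_effect = 2, species_effect = 2,
                       noise_sd = 0.4, cgi_hyper_bias = 0.8,
                       female_fraction = 0.8,
                       age_dist = c("uniform", "zoo_skew"), seed = 1) {
  age_dist <- match.arg(age_dist)
  if (n_age_probes + n_sex_probes + n_species_probes > n_probes)
    stop("effect probe counts exceed n_probes")
  if (any(c(n_probes, n_age_probes, n_sex_probes, n_species_probes) < 0))
    stop("probe counts must be non-negative")
  if (!all(names(n_per_species) %in% names(age_range)))
    stop("every species needs an age_range entry")
  structure(list(n_per_species = n_per_species, age_range = age_range,
                 n_probes = n_probes, n_age_probes = n_age_probes,
                 n_sex_probes = n_sex_probes,
                 n_species_probes = n_species_probes,
                 age_effect_sd = age_effect_sd, sex_effect = sex_effect,
                 species_effect = species_effect, noise_sd = noise_sd,
                 cgi_hyper_bias = cgi_hyper_bias,
                 female_fraction = female_fraction, age_dist = age_dist,
                 seed = seed),
            class = "sim_config")
}

#' Simulation presets
#'
#' * `"clocklike"`: two elephant species (83 + 57 samples), 2,000 probes of
#'   which 200 carry age signal — strong enough that a well-built clock
#'   recovers age accurately.
#' * `"null"`: one species, 60 samples, 500 probes, every effect zero —
#'   pure noise for calibration and leakage checks.
#' * `"sexlinked"`: as clocklike but with 200 X-linked sex probes for the
#'   sex screens.
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_preset <- function(preset = c("clocklike", "null", "sexlinked"), seed = 1,
                       ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    clocklike = list(),
    null = list(n_per_species = c(asian_elephant = 60),
                age_range = list(asian_elephant = c(1, 50)),
                n_probes = 500, n_age_probes = 0, n_sex_probes = 0,
                n_species_probes = 0),
    sexlinked = list(n_age_probes = 100, n_sex_probes = 200))
  do.call(sim_config, modifyList(base, c(list(seed = seed), list(...))))
}

#' Generate a synthetic methylation dataset
#'
#' Ages are drawn per species (uniform by default), sexes at the configured
#' female fraction.  For sample i and probe j the methylation logit is
#' `baseline_j + slope_j * g_j(age_i) + sex_delta_j * 1[female] +
#' species_delta_j * 1[non-reference species] + Normal(0, noise_sd)`, where
#' `g_j` is `age/max_age` (linear) or `log(age+1)/log(max_age+1)`
#' (log_early, faster early change) with the species' configured maximum
#' age; beta is the inverse logit clipped to \[0.001, 0.999\].  Age probes
#' in CpG islands or promoters are hypermethylating with probability
#' `cgi_hyper_bias`, other age probes with `1 - cgi_hyper_bias`.  Sex
#' probes sit on scaffold `"X_like"`.
#'
#' @param config a [sim_config()] or [sim_preset()].
#' @return list of class `sim_dataset`: `beta` (probes x samples),
#'   `samples` (sample sheet), `annotation` (probe manifest), `truth`
#'   (per-probe true effects: `baseline_logit`, `age_slope`, `age_scale`,
#'   `sex_delta`, `species_delta`).
#' @export
simulate_methylation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_(config$seed, {
    sp_names <- names(config$n_per_species)
    n <- sum(config$n_per_species)
    species <- rep(sp_names, config$n_per_species)
    ages <- unlist(lapply(sp_names, function(s) {
      rng <- config$age_range[[s]]
      ns <- config$n_per_species[[s]]
      if (config$age_dist == "uniform") runif(ns, rng[1], rng[2])
      else {                       # zoo_skew: mid-life-weighted mixture
        mid <- mean(rng); spread <- diff(rng) / 6
        a <- ifelse(runif(ns) < 0.7, rnorm(ns, mid, spread),
                    runif(ns, rng[1], rng[2]))
        pmin(pmax(a, rng[1]), rng[2])
      }
    }))
    sex <- ifelse(runif(n) < config$female_fraction, "F", "M")
    samples <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)), species = species, sex = sex,
      age_years = ages, tissue = "blood", age_confidence = 100,
      stringsAsFactors = FALSE)

    p <- config$n_probes
    probe_id <- sprintf("cg%05d", seq_len(p))
    roles <- rep("background", p)
    pool <- seq_len(p)
    take <- function(k) { s <- sample(pool, k); pool <<- setdiff(pool, s); s }
    age_idx <- take(config$n_age_probes)
    sex_idx <- take(config$n_sex_probes)
    spp_idx <- take(config$n_species_probes)
    roles[age_idx] <- "age"; roles[sex_idx] <- "sex"; roles[spp_idx] <- "species"

    region <- sample(REGION_LEVELS, p, replace = TRUE,
                     prob = c(.15, .15, .30, .10, .10, .20))
    cgi <- runif(p) < ifelse(region == "promoter", 0.7, 0.15)
    tss <- numeric(p)
    tss[region == "promoter"] <- runif(sum(region == "promoter"), -2000, 500)
    tss[region == "upstream"] <- runif(sum(region == "upstream"), -10000, -2000)
    tss[region == "downstream"] <- runif(sum(region == "downstream"), 2000, 10000)
    tss[region %in% c("exon", "intron")] <-
      runif(sum(region %in% c("exon", "intron")), 500, 20000)
    tss[region == "intergenic"] <- runif(sum(region == "intergenic"), 1e4, 1e5) *
      sample(c(-1, 1), sum(region == "intergenic"), replace = TRUE)
    chrom <- paste0("scaffold_", sample.int(20, p, replace = TRUE))
    chrom[sex_idx] <- "X_like"
    annotation <- data.frame(
      probe_id = probe_id, chrom = chrom,
      pos = sample.int(1e8, p), nearest_gene = sprintf("gene_%04d",
                                                       sample.int(800, p, TRUE)),
      tss_distance = as.integer(round(tss)), region_class = region, cgi = cgi,
      stringsAsFactors = FALSE)

    baseline <- ifelse(roles == "background" & runif(p) < 0.8,
                       sample(c(-2.5, 2.5), p, replace = TRUE) + rnorm(p, 0, 0.7),
                       rnorm(p, 0, 1))
    age_slope <- numeric(p)
    hyper_prob <- ifelse(cgi | region == "promoter",
                         config$cgi_hyper_bias, 1 - config$cgi_hyper_bias)
    sgn <- ifelse(runif(p) < hyper_prob, 1, -1)
    age_slope[age_idx] <- sgn[age_idx] *
      abs(rnorm(length(age_idx), 0, config$age_effect_sd))
    age_scale <- sample(c("linear", "log_early"), p, replace = TRUE)
    sex_delta <- numeric(p)
    sex_delta[sex_idx] <- config$sex_effect *
      sample(c(-1, 1), length(sex_idx), replace = TRUE)
    species_delta <- numeric(p)
    species_delta[spp_idx] <- config$species_effect *
      sample(c(-1, 1), length(spp_idx), replace = TRUE)

    max_age <- vapply(config$age_range, max, numeric(1))[species]
    g_lin <- matrix(ages / max_age, p, n, byrow = TRUE)
    g_log <- matrix(log(ages + 1) / log(max_age + 1), p, n, byrow = TRUE)
    G <- ifelse(matrix(age_scale == "linear", p, n), g_lin, g_log)
    logit_mu <- baseline + age_slope * G +
      outer(sex_delta, as.numeric(sex == "F")) +
      outer(species_delta, as.numeric(species != sp_names[1])) +
      matrix(rnorm(p * n, 0, config$noise_sd), p, n)
    beta <- pmin(pmax(stats::plogis(logit_mu), 0.001), 0.999)
    dimnames(beta) <- list(probe_id, samples$sample_id)

    truth <- data.frame(probe_id = probe_id, role = roles,
                        baseline_logit = baseline, age_slope = age_slope,
                        age_scale = age_scale, sex_delta = sex_delta,
                        species_delta = species_delta,
                        region_class = region, cgi = cgi,
                        stringsAsFactors = FALSE)
    structure(list(beta = beta, samples = samples, annotation = annotation,
                   truth = truth, config = config),
              class = "sim_dataset")
  })
}

#' Recovery of true age probes by an EWAS screen
#'
#' `recall_at_k` is the fraction of true age probes found within the top-k
#' rows by `|z|`; `sign_agreement` is the fraction of those recovered whose
#' Z sign matches the true slope sign.
#'
#' @param ewas_rows data.frame from [correlation_screen()].
#' @param truth the `truth` component of a [simulate_methylation()] result.
#' @param k number of top probes to consider (default: the number of true
#'   age probes).
#' @return list with `recall_at_k` and `sign_agreement`.
#' @export
truth_recovery_report <- function(ewas_rows, truth, k = NULL) {
  true_pos <- truth$probe_id[truth$age_slope != 0]
  if (is.null(k)) k <- length(true_pos)
  if (k > nrow(ewas_rows)) stop("k exceeds the number of probes screened")
  ord <- ewas_rows[order(-abs(ewas_rows$z), ewas_rows$probe_id), ]
  top <- ord$probe_id[seq_len(k)]
  hit <- intersect(top, true_pos)
  sign_ok <- if (length(hit)) {
    zs <- ewas_rows$z[match(hit, ewas_rows$probe_id)]
    sl <- truth$age_slope[match(hit, truth$probe_id)]
    mean(sign(zs) == sign(sl))
  } else NA_real_
  list(recall_at_k = if (length(true_pos)) length(hit) / length(true_pos)
       else NA_real_,
       sign_agreement = sign_ok)
}
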