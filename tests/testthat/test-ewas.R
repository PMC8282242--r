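test_that("correlation screen reproduces the t-distribution closed form", {
  # construct a probe with exactly r = 0.5 at n = 20 via Gram-Schmidt
  set.seed(41)
  n <- 20
  trait <- scale(rnorm(n))[, 1]
  e <- residuals(lm(rnorm(n) ~ trait)); e <- e / sd(e) * sd(trait)
  probe <- 0.5 * trait + sqrt(1 - 0.25) * e / sd(e) * sd(trait)
  beta <- rbind(p1 = (probe - min(probe)) / diff(range(probe)),
                p2 = (trait - min(trait)) / diff(range(trait)))
  rows <- correlation_screen(beta, trait)
  expect_equal(rows$r[1], 0.5, tolerance = 1e-8)
  expect_equal(rows$t_stat[1], 0.5 * sqrt(18) / sqrt(0.75), tolerance = 1e-6)
  expect_equal(rows$p[1], 2 * pt(0.5 * sqrt(18) / sqrt(0.75), 18,
                                 lower.tail = FALSE), tolerance = 1e-8)
  expect_equal(rows$p[1], 0.0249, tolerance = 1e-2)
  # probe identical (up to affine map) to the trait: r = 1, p ~ 0
  expect_equal(rows$r[2], 1, tolerance = 1e-12)
  expect_lt(rows$p[2], 1e-30)
})

test_that("z and p are mutually consistent and signs agree with r", {
  set.seed(42)
  beta <- matrix(runif(50 * 30), 50, 30,
                 dimnames = list(sprintf("cg%03d", 1:50), NULL))
  trait <- runif(30, 0, 60)
  rows <- correlation_screen(beta, trait)
  expect_true(all(sign(rows$z[rows$r != 0]) == sign(rows$r[rows$r != 0])))
  ok <- abs(rows$z) < 6
  p_back <- 2 * pnorm(abs(rows$z[ok]), lower.tail = FALSE)
  expect_lt(max(abs(p_back - rows$p[ok])), 1e-6)
})

test_that("zero-variance probes are flagged, tiny n rejected", {
  beta <- rbind(flat = rep(0.5, 10), ok = seq(0.1, 0.9, length.out = 10))
  rows <- correlation_screen(beta, 1:10)
  expect_true(is.na(rows$r[1]))
  expect_identical(rows$p[1], 1)
  expect_identical(rows$z[1], 0)
  expect_error(correlation_screen(beta[, 1:2], 1:2), "3")
})

test_that("correlation p-values agree with a permutation oracle", {
  set.seed(43)
  n <- 60
  trait <- runif(n, 1, 50)
  beta <- matrix(plogis(rnorm(5 * n, 0, 1)), 5, n,
                 dimnames = list(sprintf("cg%03d", 1:5), NULL))
  beta[1, ] <- plogis(0.03 * trait + rnorm(n, 0, 0.5))  # moderate signal
  rows <- correlation_screen(beta, trait)
  n_perm <- 2e4
  perm_p <- vapply(seq_len(nrow(beta)), function(j) {
    r_obs <- abs(cor(beta[j, ], trait))
    P <- replicate(n_perm, abs(cor(beta[j, ], sample(trait))))
    (sum(P >= r_obs) + 1) / (n_perm + 1)
  }, numeric(1))
  mc_se <- sqrt(perm_p * (1 - perm_p) / n_perm)
  expect_true(all(abs(rows$p - perm_p) < pmax(4 * mc_se, 5e-4)))
})

test_that("Stouffer combination follows its algebra", {
  # single cohort: identity
  one <- stouffer_combine(1.7, 40)
  expect_equal(one$z_meta, 1.7)
  # equal n, equal z: sqrt(2) scaling
  two <- stouffer_combine(c(2, 2), c(50, 50))
  expect_equal(two$z_meta, sqrt(2) * 2)
  # worked example: z = (2, -1), n = (100, 25)
  ex <- stouffer_combine(c(2, -1), c(100, 25))
  expect_equal(ex$z_meta, (10 * 2 - 5 * 1) / sqrt(125), tolerance = 1e-6)
  expect_equal(ex$p_meta, 2 * pnorm(abs(ex$z_meta), lower.tail = FALSE))
  expect_error(stouffer_combine(1, 0), "positive")
  # meta-analysis of a cohort with itself scales |z| by exactly sqrt(2)
  set.seed(44)
  tab <- data.frame(probe_id = sprintf("cg%02d", 1:20), z = rnorm(20), n = 30)
  meta <- ewas_meta(list(a = tab, b = tab))
  expect_equal(meta$z_meta, sqrt(2) * tab$z)
})

test_that("top selection reproduces brute force and ignores row order", {
  brute <- function(rows, thr, cap) {
    out <- list()
    for (dir in c(1, -1)) {
      keep <- rows[rows$p < thr & sign(rows$z) == dir, ]
      keep <- keep[order(-abs(keep$z), keep$probe_id), ]
      out[[if (dir > 0) "positive" else "negative"]] <-
        keep$probe_id[seq_len(min(cap, nrow(keep)))]
    }
    out
  }
  rows3 <- data.frame(probe_id = c("a", "b", "c"),
                      p = c(1e-6, 1e-4, 1e-7), z = c(3, 2, -4))
  sel <- select_top(rows3)
  expect_identical(sel$positive$probe_id, "a")
  expect_identical(sel$negative$probe_id, "c")
  set.seed(45)
  for (rep in 1:5) {
    rows <- data.frame(probe_id = sprintf("cg%04d", sample(9999, 800)),
                       z = rnorm(800, sd = 3))
    rows$p <- 2 * pnorm(abs(rows$z), lower.tail = FALSE)
    cap <- sample(c(5, 50, 500), 1)
    thr <- sample(c(1e-5, 1e-2, 0.2), 1)
    sel <- select_top(rows, thr, cap)
    ref <- brute(rows, thr, cap)
    expect_identical(sel$positive$probe_id, ref$positive)
    expect_identical(sel$negative$probe_id, ref$negative)
    shuf <- select_top(rows[sample(nrow(rows)), ], thr, cap)
    expect_identical(shuf$positive$probe_id, ref$positive)
  }
  # cap truncates to the top-|z| qualifiers; empty input gives empty sets
  empty <- select_top(data.frame(probe_id = character(), p = numeric(),
                                 z = numeric()))
  expect_identical(nrow(empty$positive), 0L)
})

test_that("concordance labels follow the shared/divergent rule", {
  a <- data.frame(probe_id = c("p1", "p2", "p3", "only_a"),
                  z = c(5, 5, 5, 2), p = c(1e-7, 1e-7, 1e-7, 0.04))
  b <- data.frame(probe_id = c("p1", "p2", "p3", "only_b"),
                  z = c(6, -6, 1, 1), p = c(1e-8, 1e-8, 0.3, 0.5))
  lab <- concordance(a, b)
  expect_identical(as.character(lab$label[match(c("p1", "p2", "p3"),
                                                lab$probe_id)]),
                   c("shared", "divergent", "not_significant"))
  expect_identical(attr(lab, "n_excluded"), 2L)
})

test_that("context summaries cross-tabulate direction by annotation", {
  rows <- data.frame(probe_id = c("a", "b", "c", "d"), z = c(3, 4, -5, 2))
  annot <- data.frame(probe_id = c("a", "b", "c"),
                      chrom = "s1", pos = 1:3, nearest_gene = "g",
                      tss_distance = c(-100L, -200L, 5000L),
                      region_class = c("promoter", "promoter", "intergenic"),
                      cgi = c(TRUE, TRUE, FALSE))
  tab <- context_summary(rows, annot)
  prom <- tab[tab$context_type == "region" & tab$context == "promoter", ]
  expect_identical(prom$n_hyper, 2L)
  expect_identical(prom$n_hypo, 0L)
  expect_identical(tab[tab$context == "unannotated", "n_hyper"][1], 1L)
  cgi_row <- tab[tab$context_type == "cgi" & tab$context == "CGI", ]
  expect_identical(cgi_row$n_hyper, 2L)
  # empty selection: all-zero table
  tab0 <- context_summary(rows[0, ], annot)
  expect_true(all(tab0$n_hyper == 0L) && all(tab0$n_hypo == 0L))
})

test_that("CGI-biased age effects surface in the context summary", {
  d <- simulate_methylation(sim_preset(
    "clocklike", seed = 77,
    n_per_species = c(asian_elephant = 60), n_probes = 600,
    n_age_probes = 150, n_sex_probes = 0, n_species_probes = 0,
    cgi_hyper_bias = 0.9))
  rows <- correlation_screen(d$beta, d$samples$age_years)
  sel <- select_top(rows, p_threshold = 1e-5)
  tab <- context_summary(rbind(sel$positive, sel$negative), d$annotation)
  cgi <- tab[tab$context_type == "cgi", ]
  frac <- with(cgi, n_hyper / (n_hyper + n_hypo))
  expect_gt(frac[cgi$context == "CGI"], frac[cgi$context == "non_CGI"])
})

test_that("sex screen detects pure sex effects and respects adjustment", {
  set.seed(46)
  n <- 80
  s <- toy_samples(n, seed = 46)
  sexF <- as.numeric(s$sex == "F")
  beta <- matrix(plogis(rnorm(3 * n, 0, 0.3)), 3, n,
                 dimnames = list(c("sexp", "agep", "noise"), s$sample_id))
  beta["sexp", ] <- plogis(2 * sexF + rnorm(n, 0, 0.3))
  beta["agep", ] <- plogis(0.05 * s$age_years + rnorm(n, 0, 0.3))
  rows <- sex_screen(beta, s)
  expect_lt(rows$p[rows$probe_id == "sexp"], 1e-10)
  expect_gt(rows$p[rows$probe_id == "agep"], 1e-3)
  expect_error(sex_screen(beta[, s$sex == "F"], s[s$sex == "F", ]), "both sexes")
})

test_that("unadjusted sex screen inflates under age-sex confounding", {
  set.seed(47)
  n <- 100
  sex <- rep(c("F", "M"), each = n / 2)
  age <- c(runif(n / 2, 30, 60), runif(n / 2, 5, 35))  # females older
  s <- data.frame(sample_id = sprintf("S%03d", 1:n), species = "asian_elephant",
                  sex = sex, age_years = age, tissue = "blood",
                  age_confidence = 100)
  p <- 200
  beta <- matrix(plogis(matrix(rnorm(p * n, 0, 0.4), p, n) +
                        rep(0.04 * age, each = p)), p, n,
                 dimnames = list(sprintf("cg%03d", 1:p), s$sample_id))
  adj <- sex_screen(beta, s, adjust_for_age = TRUE)
  raw <- sex_screen(beta, s, adjust_for_age = FALSE)
  expect_gt(mean(raw$p < 0.05), mean(adj$p < 0.05))
  # adjusted screen stays near nominal even though age drives methylation
  expect_lt(mean(adj$p < 0.05), 0.12)
})

test_that("interaction screen finds sex-specific aging and stays null otherwise", {
  set.seed(48)
  n <- 140
  sex <- rep(c("F", "M"), length.out = n)
  age <- runif(n, 1, 60)
  s <- data.frame(sample_id = sprintf("S%03d", 1:n), species = "asian_elephant",
                  sex = sex, age_years = age, tissue = "blood",
                  age_confidence = 100)
  sexF <- as.numeric(sex == "F")
  beta <- rbind(
    female_only = plogis(0.05 * age * sexF + 0.01 * age + rnorm(n, 0, 0.3)),
    both_same = plogis(0.05 * age + rnorm(n, 0, 0.3)))
  colnames(beta) <- s$sample_id
  rows <- interaction_screen(beta, s)
  expect_lt(rows$p[rows$probe_id == "female_only"], 1e-5)
  expect_gt(rows$p[rows$probe_id == "both_same"], 1e-3)
  expect_error(interaction_screen(beta[, 1:4], s[1:4, ]))
})
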