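# Fast clock-pipeline checks run on a down-scaled simulated dataset; the
# full-scale recovery and null calibrations live in test-acceptance.R.

small_sim <- function(seed = 5) {
  simulate_methylation(sim_preset(
    "clocklike", seed = seed,
    n_per_species = c(asian_elephant = 35, african_elephant = 25),
    n_probes = 300, n_age_probes = 60, n_sex_probes = 10,
    n_species_probes = 10))
}

test_that("trained clocks are sparse, deterministic, and self-consistent", {
  d <- small_sim()
  tr <- age_transform("identity")
  m1 <- train_clock(d$beta, d$samples, tr, seed = 42)
  m2 <- train_clock(d$beta, d$samples, tr, seed = 42)
  expect_gte(length(m1$coefficients), 1)
  expect_lte(length(m1$coefficients), 500)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$lambda, m2$lambda)
  expect_true(all(names(m1$coefficients) %in% rownames(d$beta)))

  # applying the model to its own training matrix reproduces fitted values
  pred <- predict_age(m1, d$beta, d$samples)
  lp <- m1$intercept + drop(crossprod(
    d$beta[names(m1$coefficients), d$samples$sample_id, drop = FALSE],
    m1$coefficients))
  expect_equal(unname(pred), unname(pmax(lp, 0)))
  expect_gt(cor(pred, d$samples$age_years), 0.8)
})

test_that("degenerate constant-age training yields an intercept-only model", {
  d <- small_sim()
  s <- d$samples
  s$age_years <- rep(10, nrow(s))
  expect_warning(m <- train_clock(d$beta, s, age_transform("identity")),
                 "degenerate")
  expect_length(m$coefficients, 0)
  expect_equal(unname(predict_age(m, d$beta, s)), rep(10, nrow(s)))
})

test_that("prediction inverts the transform with per-species parameters", {
  d <- small_sim()
  tr <- age_transform("relative",
                      max_lifespan = c(asian_elephant = 85,
                                       african_elephant = 122))
  m <- train_clock(d$beta, d$samples, tr, seed = 1)
  # all-zero model: every sample maps to the inverse transform of the
  # intercept, scaled by its species lifespan
  m0 <- m
  m0$coefficients <- setNames(numeric(0), character(0))
  pred0 <- predict_age(m0, d$beta, d$samples)
  expect_equal(unname(pred0),
               m0$intercept * c(asian_elephant = 85,
                                african_elephant = 122)[d$samples$species],
               ignore_attr = TRUE)
  ratio <- pred0[d$samples$species == "asian_elephant"][1] /
    pred0[d$samples$species == "african_elephant"][1]
  expect_equal(unname(ratio), 85 / 122)
  # missing model probes error unless imputation is enabled
  probes <- names(m$coefficients)
  expect_error(predict_age(m, d$beta[setdiff(rownames(d$beta), probes[1]), ],
                           d$samples), probes[1])
  p_imp <- predict_age(m, d$beta[setdiff(rownames(d$beta), probes[1]), ],
                       d$samples, impute = TRUE)
  expect_equal(length(p_imp), nrow(d$samples))
})

test_that("stratified folds preserve species proportions to within one", {
  species <- rep(c("asian_elephant", "african_elephant"), c(83, 57))
  f <- stratified_folds(species, 10, seed = 3)
  tab <- table(species, f)
  expect_true(all(tab["asian_elephant", ] %in% 8:9))
  expect_true(all(tab["african_elephant", ] %in% 5:6))
  expect_identical(stratified_folds(species, 10, seed = 3), f)
  expect_false(identical(stratified_folds(species, 10, seed = 4), f))
})

test_that("lofo10 refuses strata smaller than the fold count", {
  d <- small_sim()
  s <- d$samples[c(which(d$samples$species == "asian_elephant"),
                   which(d$samples$species == "african_elephant")[1:5]), ]
  expect_error(lofo10(d$beta, s, age_transform("identity")), "loocv")
})

test_that("cv_report metrics are recomputable from per-sample rows", {
  d <- small_sim()
  cv <- lofo10(d$beta, d$samples, age_transform("identity"), seed = 2)
  ps <- cv$per_sample
  expect_equal(cv$pearson_r,
               cor(ps$true_age_years, ps$predicted_age_years))
  expect_equal(cv$mae_years,
               median(abs(ps$predicted_age_years - ps$true_age_years)))
  expect_gt(cv$pearson_r, 0.8)
  # same seed reproduces folds and predictions exactly
  cv2 <- lofo10(d$beta, d$samples, age_transform("identity"), seed = 2)
  expect_identical(cv$per_sample, cv2$per_sample)
})

test_that("perfect predictions give R = 1 and MAE = 0", {
  rep <- mammclock:::cv_report_(sprintf("S%d", 1:5), 1:5,
                                c(1, 5, 10, 20, 40), c(1, 5, 10, 20, 40))
  expect_equal(rep$pearson_r, 1)
  expect_equal(rep$mae_years, 0)
})

test_that("age acceleration follows its two definitions", {
  chron <- c(5, 10, 20, 40, 60)
  expect_equal(age_acceleration(chron, chron, "delta"), rep(0, 5))
  expect_equal(age_acceleration(chron, chron, "residual"), rep(0, 5),
               ignore_attr = TRUE)
  shifted <- chron + 2
  expect_equal(age_acceleration(shifted, chron, "delta"), rep(2, 5))
  expect_equal(age_acceleration(shifted, chron, "residual"), rep(0, 5),
               ignore_attr = TRUE)
  set.seed(9)
  pred <- chron * 1.1 + rnorm(5)
  res <- age_acceleration(pred, chron, "residual")
  expect_lt(abs(mean(res)), 1e-10)
  expect_lt(abs(cor(res, chron)), 1e-8)
  expect_error(age_acceleration(1:3, 1:4), "length")
})

test_that("acceleration correlations form a proper matrix", {
  set.seed(10)
  a <- rnorm(20)
  m <- acceleration_correlations(list(c1 = a, c2 = a, c3 = -a))
  expect_equal(unname(m["c1", "c2"]), 1)
  expect_equal(unname(m["c1", "c3"]), -1)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_warning(m2 <- acceleration_correlations(list(a = a, b = rep(0, 20))),
                 "constant")
  expect_true(is.na(m2["a", "b"]))
})

test_that("clocks trained on overlapping signal have correlated accelerations", {
  d <- small_sim(seed = 8)
  tr <- age_transform("identity")
  m1 <- train_clock(d$beta, d$samples, tr, seed = 1)
  m2 <- train_clock(d$beta, d$samples, tr, seed = 2, alpha = 0.9)
  acc1 <- age_acceleration(predict_age(m1, d$beta, d$samples),
                           d$samples$age_years)
  acc2 <- age_acceleration(predict_age(m2, d$beta, d$samples),
                           d$samples$age_years)
  m <- acceleration_correlations(list(a = acc1, b = acc2))
  expect_gt(m["a", "b"], 0)
})
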