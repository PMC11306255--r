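test_that("simulation is reproducible and validates its config", {
  cfg <- sim_config(n_per_sex = 20)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_cohort(cfg, seed = 99)
  expect_false(identical(s1$measurements$value, s3$measurements$value))

  expect_error(sim_config(n_per_sex = 0), "n_per_sex")
  expect_error(sim_config(missingness_rate = 1.5), "missingness_rate")
  expect_error(sim_config(clinic_ages = c(9, 8)), "clinic_ages")
  expect_error(sim_config(cross_measure_timing_correlation = 2),
               "cross_measure_timing_correlation")
  bad <- sim_config(n_per_sex = 5)
  bad$measures$height$timing_sd <- -1
  expect_error(validate_sim_config(bad), "timing_sd")
})

test_that("zero missingness yields the complete assessment grid", {
  cfg <- sim_config(n_per_sex = 10, missingness_rate = 0)
  s <- simulate_cohort(cfg)
  ht <- s$measurements[s$measurements$measure == "height", ]
  expect_identical(nrow(ht), 10L * 2L * 9L)
  # BMC only at its five clinic occasions
  bmc <- s$measurements[s$measurements$measure == "bmc", ]
  expect_identical(nrow(bmc), 10L * 2L * 5L)
  expect_setequal(unique(bmc$occasion), c(3L, 5L, 7L, 8L, 9L))
})

test_that("degenerate timing correlation 1 gives one shared scaled effect", {
  cfg <- sim_config(n_per_sex = 40, cross_measure_timing_correlation = 1)
  s <- simulate_cohort(cfg)
  b <- reshape(s$true_effects[, c("id", "measure", "beta")], idvar = "id",
               timevar = "measure", direction = "wide")
  r <- cor(b[, -1])
  expect_equal(unname(r[upper.tri(r)]), rep(1, sum(upper.tri(r))),
               tolerance = 1e-10)
})

test_that("realized timing SDs and correlations match the config at n=2000", {
  cfg <- sim_config(n_per_sex = 1000, seed = 7,
                    cross_measure_timing_correlation = 0.55)
  s <- simulate_cohort(cfg)
  b_h <- s$true_effects$beta[s$true_effects$measure == "height"]
  # config height timing SD is 1.0; Monte-Carlo tolerance at n=2000
  expect_lt(abs(sd(b_h) - 1.0), 0.05)
  expect_lt(abs(mean(b_h)), 0.07)
  b <- reshape(s$true_effects[, c("id", "measure", "beta")], idvar = "id",
               timevar = "measure", direction = "wide")
  r <- cor(b[, -1])
  expect_lt(max(abs(r[upper.tri(r)] - 0.55)), 0.06)
})

test_that("explicit timing correlation matrix is reproduced", {
  R <- matrix(c(1, .3, .5, .3, 1, .7, .5, .7, 1), 3)
  mk <- function() measure_def("clinic", "continuous",
                               curve_f = height_curve_f(),
                               curve_m = height_curve_m(),
                               timing_sd = 1, size_sd = 3,
                               residual_sd = 0.8)
  cfg <- sim_config(n_per_sex = 1000, seed = 3,
                    measures = list(m1 = mk(), m2 = mk(), m3 = mk()),
                    timing_cor_matrix = R)
  s <- simulate_cohort(cfg)
  b <- reshape(s$true_effects[, c("id", "measure", "beta")], idvar = "id",
               timevar = "measure", direction = "wide")
  expect_lt(max(abs(cor(b[, -1]) - R)), 0.05)
})

test_that("simulated GRS correlates with latent timing as configured", {
  cfg <- sim_config(n_per_sex = 1000, grs_timing_correlation = 0.25, seed = 5)
  s <- simulate_cohort(cfg)
  lat <- s$true_effects$latent_timing[s$true_effects$measure == "height"]
  expect_lt(abs(cor(s$covariates$grs, lat) - 0.25), 0.05)
  expect_equal(mean(s$covariates$grs), 0, tolerance = 1e-12)
  expect_equal(sd(s$covariates$grs), 1, tolerance = 1e-12)
})

test_that("stage discretization thresholds and inconsistencies behave", {
  expect_identical(discretize_to_stages(c(0.2, 1.49), c(1.5, 2.5, 3.5, 4.5)),
                   c(1L, 1L))
  expect_identical(discretize_to_stages(c(1.51, 5.2), c(1.5, 2.5, 3.5, 4.5)),
                   c(2L, 5L))
  # binary axillary scale: one threshold
  expect_identical(discretize_to_stages(c(1.2, 1.8), 1.5), c(1L, 2L))
  expect_error(discretize_to_stages(1, c(2, 1)), "strictly increasing")

  # binomial check on the knock-down rate
  set.seed(8)
  st <- discretize_to_stages(rep(3, 1e4), c(1.5, 2.5, 3.5, 4.5),
                             inconsistency_rate = 0.05)
  frac <- mean(st == 2L)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1e4))
})

test_that("ordinal series are monotone without injected inconsistencies", {
  cfg <- sim_config(n_per_sex = 40, inconsistency_rate = 0)
  s <- simulate_cohort(cfg)
  for (m in c("pubic_hair", "breast", "genitalia", "axillary_hair", "voice")) {
    d <- s$measurements[s$measurements$measure == m, ]
    d <- d[order(d$id, d$age), ]
    mono <- tapply(d$value, d$id, function(v) all(diff(v) >= 0))
    expect_true(all(unlist(mono)), label = paste("monotone", m))
  }
})

test_that("menarche is reported at the first questionnaire after onset", {
  cfg <- sim_config(n_per_sex = 50, menarche_recall_sd = 0,
                    missingness_rate = 0)
  s <- simulate_cohort(cfg)
  men <- s$measurements[s$measurements$measure == "menarche", ]
  truth <- unique(s$true_effects[s$true_effects$measure == "menarche" &
                                   s$true_effects$sex == "F",
                                 c("id", "menarche_age")])
  rep1 <- men[men$value == 1 & !is.na(men$reported_age), ]
  rep1 <- rep1[!duplicated(rep1$id), ]
  m <- merge(rep1, truth, by = "id")
  # with zero recall noise the reported age is the true event age
  expect_equal(m$reported_age, m$menarche_age, tolerance = 1e-10)
  # and the report indeed comes after the event
  expect_true(all(m$age >= m$menarche_age))
})
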