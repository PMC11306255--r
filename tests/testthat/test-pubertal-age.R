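test_that("menarche age is the first reported onset", {
  q <- data.frame(id = rep(1:3, each = 3),
                  age = rep(c(11, 12.5, 13.5), 3),
                  value = c(0, 1, 1,  0, 0, 0,  0, 0, 1),
                  reported_age = c(NA, 12.3, 12.5,  NA, NA, NA,
                                   NA, NA, 13.1))
  men <- derive_menarche_age(q)
  expect_equal(men$menarche_age[men$id == 1], 12.3) # first report wins
  expect_true(is.na(men$menarche_age[men$id == 2])) # never reported
  expect_equal(men$menarche_age[men$id == 3], 13.1)
})

test_that("menarche derivation inverts the generator exactly without recall noise", {
  cfg <- sim_config(n_per_sex = 100, menarche_recall_sd = 0,
                    missingness_rate = 0, seed = 13)
  s <- simulate_cohort(cfg)
  men <- derive_menarche_age(
    s$measurements[s$measurements$measure == "menarche", ])
  truth <- unique(s$true_effects[s$true_effects$measure == "menarche" &
                                   s$true_effects$sex == "F",
                                 c("id", "menarche_age")])
  m <- merge(men, truth, by = "id")
  ok <- !is.na(m$menarche_age.x)
  expect_gt(mean(ok), 0.8) # late onsets can fall after the last questionnaire
  expect_equal(m$menarche_age.x[ok], m$menarche_age.y[ok], tolerance = 1e-10)
})

test_that("voice cleaning removes only regressions below the running maximum", {
  v <- data.frame(id = c(1, 1, 1, 1, 2, 2, 2),
                  age = c(12, 13, 14, 15, 12, 13, 14),
                  value = c(1, 2, 3, 2, 1, 2, 3))
  out <- clean_voice_series(v)
  expect_identical(nrow(out), 6L)
  expect_identical(attr(out, "n_removed"), 1L)
  expect_equal(out$value[out$id == 1], c(1, 2, 3))
  expect_equal(out$value[out$id == 2], c(1, 2, 3)) # monotone: untouched

  set.seed(3)
  # injected regressions: each knocked-down stage > 1 regresses the series
  cfg <- sim_config(n_per_sex = 300, inconsistency_rate = 0.05, seed = 17)
  s <- simulate_cohort(cfg)
  vv <- s$measurements[s$measurements$measure == "voice", ]
  cleaned <- clean_voice_series(vv)
  frac <- attr(cleaned, "n_removed") / nrow(vv)
  # removal fraction is of the order of the inconsistency rate (only
  # regressions below the running max are removed, so somewhat fewer)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.05)
})

test_that("the full battery derives seven measures per sex with recovery", {
  coh <- shared_cohort()
  pa <- suppressWarnings(derive_all_measures(coh$measurements))
  meas_f <- colnames(pa$ages)[colSums(!is.na(pa$ages[pa$ages$sex == "F", ])) > 0]
  meas_m <- colnames(pa$ages)[colSums(!is.na(pa$ages[pa$ages$sex == "M", ])) > 0]
  expect_setequal(setdiff(meas_f, c("id", "sex")),
                  c("height", "weight", "bmc", "pubic_hair", "breast",
                    "axillary_hair", "menarche"))
  expect_setequal(setdiff(meas_m, c("id", "sex")),
                  c("height", "weight", "bmc", "pubic_hair", "genitalia",
                    "axillary_hair", "voice"))
  # derived ages sit in the plausible pubertal window
  vals <- unlist(pa$ages[setdiff(names(pa$ages), c("id", "sex"))])
  expect_true(all(vals[!is.na(vals)] > 6 & vals[!is.na(vals)] < 20))

  # per-measure means track the generator's sex-specific landmark ages
  sm <- summarize_timing(pa$ages)$timing
  expect_lt(abs(sm$mean_y[sm$measure == "height" & sm$sex == "F"] - 11.74), 0.3)
  expect_lt(abs(sm$mean_y[sm$measure == "height" & sm$sex == "M"] - 13.45), 0.3)
  expect_lt(abs(sm$mean_y[sm$measure == "breast" & sm$sex == "F"] - 11.5), 0.3)
  # voice breaking is a 3-point scale whose upper transition is barely
  # inside the questionnaire window; its landmark is the least precise of
  # the battery (a few tenths of a year at this sample size)
  expect_lt(abs(sm$mean_y[sm$measure == "voice" & sm$sex == "M"] - 14.2), 0.8)
})

test_that("a cohort without BMC yields a table without it, with a warning", {
  coh <- shared_cohort()
  sub <- coh$measurements[coh$measurements$measure %in%
                            c("height", "breast", "menarche"), ]
  w <- testthat::capture_warnings(
    pa <- derive_all_measures(sub, default_specs()[c("height", "breast",
                                                     "bmc", "menarche")]))
  expect_true(any(grepl("absent", w)))
  expect_false("bmc" %in% names(pa$ages))
  expect_true(all(c("height", "breast", "menarche") %in% names(pa$ages)))
})

test_that("timing summaries and sequence fractions behave", {
  ages <- data.frame(id = 1:4, sex = "F",
                     m1 = c(11, 12, 13, 11.5),
                     m2 = c(12, 13, 14, 12.5),
                     m3 = c(13, 14, 15, 13.5))
  sm <- summarize_timing(ages)
  expect_equal(sm$timing$sd_y[sm$timing$measure == "m1"], sd(ages$m1))
  # m1 is always first, m3 always last
  sq <- sm$sequence
  expect_equal(sq$pct_first[sq$measure == "m1"], 100)
  expect_equal(sq$pct_last[sq$measure == "m3"], 100)
  expect_equal(sum(sq$pct_first), 100)
  expect_equal(sum(sq$pct_last), 100)

  # constant column: zero SD; ties split equally
  tie <- data.frame(id = 1:2, sex = "M", m1 = c(10, 10), m2 = c(10, 12))
  smt <- summarize_timing(tie)
  expect_equal(smt$timing$sd_y[smt$timing$measure == "m1"], 0)
  expect_equal(smt$sequence$pct_first,
               c(75, 25)) # individual 1 ties both measures first
})
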