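test_that("default scenario matches the survey design it emulates", {
  sc <- make_default_scenario(seed = 5)
  expect_length(sc$wave_years, 4L)
  expect_equal(diff(sc$wave_years), rep(6, 3))
  expect_identical(sc$n_per_wave, 44000L)
  expect_identical(sc$mrr$mrr_lo, 8.0)
  expect_identical(sc$mrr$mrr_hi, 2.75)
  # same seed gives behaviourally identical scenarios
  sc2 <- make_default_scenario(seed = 5)
  a <- seq(20, 79, by = 7)
  for (s in sc$sexes) {
    expect_identical(sc$incidence(a, 2009, s), sc2$incidence(a, 2009, s))
    expect_identical(sc$m0(a, s), sc2$m0(a, s))
  }
  expect_identical(sc$age_weights, sc2$age_weights)
  # incidence peaks near 65 and declines beyond
  imid <- sc$incidence(20:79, 2009, "male")
  expect_equal((20:79)[which.max(imid)], 65)
  expect_true(all(diff(imid[1:46]) > 0) && all(diff(imid[47:60]) < 0))
})

test_that("survey generation is reproducible and honors the scenario", {
  sc <- make_default_scenario(seed = 3, n_per_wave = 5000)
  d1 <- generate_survey(sc, 2006)
  d2 <- generate_survey(sc, 2006)
  expect_identical(d1, d2)
  expect_false(identical(d1, generate_survey(sc, 2006, seed = 99)))
  expect_true(all(d1$age >= 20 & d1$age <= 79))
  expect_true(all(d1$weight > 0))
  expect_true(all(d1$disease %in% c(0L, 1L)))
  expect_true(all(d1$survey_year == 2006L))
  expect_error(generate_survey(sc, 2001), "not one of the scenario's waves")
  # zero-incidence scenario produces no cases
  sc0 <- scenario_spec(incidence = function(a, t, s) 0 * a,
                       m0 = function(a, s) 1e-4 * exp(0.09 * a),
                       mrr = mrr_profile(8, 2.75),
                       wave_years = c(2000, 2006), n_per_wave = 2000)
  expect_equal(sum(generate_survey(sc0, 2000)$disease), 0L)
})

test_that("sample prevalence sits within binomial noise of the model truth", {
  # unweighted large sample concentrated by conditioning on one age
  sc <- make_default_scenario(seed = 17, n_per_wave = 200000)
  sc$weight_sdlog <- 0
  d <- generate_survey(sc, 2012, n = 200000)
  p_true <- solve_prevalence_forward(sc, 60.5, 2012, "male")$p
  k <- d$age == 60 & d$sex == "male"
  n60 <- sum(k)
  se <- sqrt(p_true * (1 - p_true) / n60)
  expect_lt(abs(mean(d$disease[k]) - p_true), 3 * se)
})

test_that("weight-normalized prevalence is unbiased over replicates", {
  sc <- make_default_scenario(seed = 1, n_per_wave = 10000)
  ages_chk <- c(40, 60)
  p_true <- vapply(ages_chk, function(a)
    solve_prevalence_forward(sc, a + 0.5, 2012, "female")$p, numeric(1))
  est <- matrix(NA_real_, 200, length(ages_chk))
  for (r in 1:200) {
    d <- generate_survey(sc, 2012, seed = 3000 + r)
    for (j in seq_along(ages_chk)) {
      k <- d$age == ages_chk[j] & d$sex == "female"
      est[r, j] <- sum(d$weight[k] * d$disease[k]) / sum(d$weight[k])
    }
  }
  bias <- colMeans(est) - p_true
  mcse <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(bias) < 2 * mcse + 1e-12))
})

test_that("mortality schedule lookup interpolates and clamps", {
  d <- expand.grid(year = c(2000, 2010), sex = c("male", "female"),
                   age = c(40, 50), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$rate <- c(0.01, 0.02, 0.012, 0.022, 0.03, 0.04, 0.032, 0.042)
  ms <- mortality_schedule(d)
  # stored node value returned exactly
  expect_identical(mortality_at(ms, 40, 2000, "male"), 0.01)
  expect_identical(mortality_at(ms, 50, 2010, "female"), 0.042)
  # bilinear in the interior
  expect_equal(mortality_at(ms, 45, 2005, "male"),
               mean(c(0.01, 0.02, 0.03, 0.04)), tolerance = 1e-12)
  # constant extrapolation at the edges
  expect_identical(mortality_at(ms, 30, 1990, "male"), 0.01)
  expect_identical(mortality_at(ms, 90, 2030, "male"), 0.04)
  expect_error(mortality_at(ms, 40, 2000, "other"), "not present")
  d2 <- rbind(d, d[1, ])
  expect_error(mortality_schedule(d2), "duplicate")
  d$rate[1] <- -1
  expect_error(mortality_schedule(d), "nonnegative")
})

test_that("generated mortality schedule equals the compartment mixture", {
  # no disease: schedule must reproduce m0 on the grid
  sc0 <- scenario_spec(incidence = function(a, t, s) 0 * a,
                       m0 = function(a, s) 1e-4 * exp(0.08 * a),
                       mrr = mrr_profile(8, 2.75),
                       wave_years = c(2000, 2006))
  ms0 <- generate_mortality_schedule(sc0, ages = c(30, 50, 70),
                                     years = c(2000, 2006))
  expect_equal(mortality_at(ms0, c(30, 50, 70), 2000, "male"),
               1e-4 * exp(0.08 * c(30, 50, 70)), tolerance = 1e-10)
  # equal mortality in both compartments: schedule equals m0 despite p > 0
  sc1 <- scenario_spec(incidence = function(a, t, s) rep(0.01, length(a)),
                       m0 = function(a, s) 1e-4 * exp(0.08 * a),
                       mrr = mrr_profile(1, 1),
                       wave_years = c(2000, 2006))
  ms1 <- generate_mortality_schedule(sc1, ages = c(40, 60), years = 2000)
  expect_equal(mortality_at(ms1, c(40, 60), 2000, "female"),
               1e-4 * exp(0.08 * c(40, 60)), tolerance = 1e-10)
  # mixture arithmetic: m0 (1 + p (MRR - 1))
  expect_equal(0.01 * (1 + 0.1 * (2 - 1)), 0.011)
  sc2 <- make_default_scenario()
  ms2 <- generate_mortality_schedule(sc2, ages = 50:55, years = 2009)
  sol <- solve_prevalence_forward(sc2, 50:55, 2009, "male")
  expect_equal(mortality_at(ms2, 50:55, 2009, "male"),
               sc2$m0(50:55, "male") *
                 (1 + sol$p * (mrr_at(sc2$mrr, 50:55) - 1)),
               tolerance = 1e-10)
})

test_that("standard population derived from the scenario is a proper standard", {
  sc <- make_default_scenario()
  std <- default_standard_population(sc)
  expect_s3_class(std, "standard_population")
  expect_equal(nrow(std), 6L)
  expect_equal(sum(std$weight), 1, tolerance = 1e-12)
  expect_identical(std$midpoint, c(25, 35, 45, 55, 65, 75))
  # weights follow the declining age pyramid
  expect_true(all(diff(std$weight) < 0))
})
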