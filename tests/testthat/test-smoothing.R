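test_that("wave fit recovers a logistic-in-age prevalence at large n", {
  sc <- make_inspan_scenario(seed = 31)
  d <- generate_survey(sc, 2012, n = 200000, prevalence = inspan_prevalence)
  wf <- fit_wave(d)
  expect_s3_class(wf, "wave_fit")
  expect_length(wf$knots, 5L)
  expect_equal(wf$knots, seq(20.5, 79.5, length.out = 7)[2:6])
  g <- wf$grid
  expect_true(all(is.finite(g$eta)))
  interior <- g$age >= 25 & g$age <= 75
  err <- abs(plogis(g$eta) -
               inspan_prevalence(g$age + 0.5, 2012, g$sex))
  expect_lt(max(err[interior]), 0.01)
})

test_that("wave fitting is invariant to the weight scale and weight mass", {
  sc <- make_inspan_scenario(n_per_wave = 20000, seed = 8)
  d <- generate_survey(sc, 2006, n = 20000, prevalence = inspan_prevalence)
  # constant rescaling of all weights
  d_scaled <- d; d_scaled$weight <- d$weight * 7.3
  f1 <- fit_wave(d); f2 <- fit_wave(d_scaled)
  expect_equal(f1$grid$eta, f2$grid$eta, tolerance = 1e-8)
  # duplicating every record at half weight carries the same weight mass
  d_dup <- rbind(d, d); d_dup$weight <- d_dup$weight / 2
  f3 <- fit_wave(d_dup)
  expect_equal(f1$grid$eta, f3$grid$eta, tolerance = 1e-8)
})

test_that("wave fitting rejects degenerate inputs", {
  d <- data.frame(id = 1:10, age = rep(50L, 10), sex = "male",
                  survey_year = 2000L, disease = rep(0:1, 5), weight = 1)
  expect_error(fit_wave(d), "distinct ages")
  d2 <- data.frame(id = 1:10, age = 41:50, sex = "male",
                   survey_year = 2000L, disease = 0L, weight = 1)
  expect_error(fit_wave(d2), "outcome classes")
  d3 <- d; d3$weight[3] <- -1
  expect_error(fit_wave(d3), "positive")
  d4 <- data.frame(id = 1:4, age = c(30L, 40L, 30L, 40L),
                   sex = "male", survey_year = c(2000L, 2000L, 2006L, 2006L),
                   disease = c(0L, 1L, 0L, 1L), weight = 1)
  expect_error(fit_wave(d4), "single survey year")
})

test_that("pooling reproduces a surface of exact model form", {
  surf <- exact_poly_surface()
  g <- expand.grid(age = seq(20, 79.5, by = 0.5), year = c(2000, 2018),
                   sex = c("male", "female"), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  expect_equal(predict_surface(surf, g$age, g$year, g$sex, type = "link"),
               poly_eta(g$age, g$year, g$sex), tolerance = 1e-9)
  expect_equal(predict_surface(surf, g$age, g$year, g$sex),
               plogis(poly_eta(g$age, g$year, g$sex)), tolerance = 1e-9)
})

test_that("pooling requires at least two survey years", {
  d <- expand.grid(age = 20:79 + 0.5, year = 2006, sex = "male",
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$eta <- -3 + 0.02 * d$age
  expect_error(pool_logit_data(d), "at least two")
})

test_that("no temporal signal gives zero year coefficients, symmetric sexes give zero sex terms", {
  d <- expand.grid(age = 20:79 + 0.5, year = c(2000, 2006, 2012, 2018),
                   sex = c("male", "female"), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$eta <- -5 + 0.05 * d$age          # no year, no sex dependence
  surf <- pool_logit_data(d, age_domain = c(20, 80))
  k <- length(surf$coef) / 4          # blocks: base, year, sex, year x sex
  expect_equal(max(abs(surf$coef[(k + 1):(4 * k)])), 0, tolerance = 1e-10)
  # the fitted surface is flat in time: zero cohort-direction year part
  expect_equal(directional_derivative(surf, 50, 2009, "male"),
               directional_derivative(surf, 50, 2003, "male"),
               tolerance = 1e-12)
})

test_that("analytic directional derivative matches its finite-difference check", {
  surf <- exact_poly_surface()
  set.seed(77)
  a <- runif(100, 20.5, 79.5); t <- runif(100, 2000, 2018)
  s <- sample(c("male", "female"), 100, replace = TRUE)
  dan <- directional_derivative(surf, a, t, s)
  dfd <- directional_derivative(surf, a, t, s, method = "finite_difference")
  expect_lt(max(abs(dan - dfd)), 1e-6)
  # closed form of the polynomial surface
  p <- plogis(poly_eta(a, t, s))
  expect_equal(dan, p * (1 - p) * poly_deta(a, t, s), tolerance = 1e-8)
  # flat surface: zero derivative
  d <- expand.grid(age = 20:79 + 0.5, year = c(2000, 2006), sex = "male",
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$eta <- -2
  flat <- pool_logit_data(d, age_domain = c(20, 80))
  expect_equal(directional_derivative(flat, 40:60, 2003, "male"),
               rep(0, 21), tolerance = 1e-10)
})

test_that("surface draws follow the stored coefficient distribution", {
  fx <- pipeline_fixture()
  surf <- fx$surf
  # same seed, same draw
  expect_identical(sample_surface(surf, seed = 4)$coef,
                   sample_surface(surf, seed = 4)$coef)
  # zero covariance collapses to the point estimate
  s0 <- surf; s0$vcov <- matrix(0, length(surf$coef), length(surf$coef))
  expect_identical(sample_surface(s0, seed = 1)$coef, surf$coef)
  # draw mean within Monte-Carlo error of the estimate
  set.seed(11)
  draws <- vapply(1:10000, function(k) sample_surface(surf)$coef,
                  numeric(length(surf$coef)))
  mc_se <- sqrt(diag(surf$vcov) / 10000)
  dev <- abs(rowMeans(draws) - surf$coef)
  expect_true(all(dev < 4 * mc_se + 1e-12))
  # draw covariance consistent with the stored covariance (loose check)
  emp <- stats::cov(t(draws))
  expect_lt(max(abs(emp - surf$vcov)) / max(diag(surf$vcov)), 0.1)
})

test_that("two-stage procedure approximately recovers an in-span truth", {
  # coarse envelope at moderate n; the corner cells of the age x year domain
  # carry the most sampling noise
  sc <- make_inspan_scenario(n_per_wave = 50000, seed = 204)
  waves <- lapply(sc$wave_years, function(y)
    fit_wave(generate_survey(sc, y, prevalence = inspan_prevalence)))
  surf <- pool_waves(waves)
  g <- expand.grid(age = 20:79, year = sc$wave_years,
                   sex = c("male", "female"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  err <- abs(predict_surface(surf, g$age, g$year, g$sex) -
               inspan_prevalence(g$age, g$year, g$sex))
  expect_lt(max(err), 0.05)
  expect_lt(stats::median(err), 0.005)
  # fitted prevalence stays inside (0, 1)
  ph <- predict_surface(surf, g$age, g$year, g$sex)
  expect_true(all(ph > 0 & ph < 1))
})
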