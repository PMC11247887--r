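test_that("incidence equation evaluates to its arithmetic value", {
  # no excess mortality and flat prevalence: no incidence
  expect_identical(eval_incidence_equation(p = 0.1, dp = 0, m = 0.01, mrr = 1), 0)
  # frozen hand-computed values of the two equation terms
  expect_equal(eval_incidence_equation(p = 0.1, dp = 0, m = 0.01, mrr = 2),
               1 / 1100, tolerance = 1e-12)
  expect_equal(eval_incidence_equation(p = 0.2, dp = 0.004, m = 0.02, mrr = 3),
               0.004 / 0.8 + 0.02 * 0.4 / 1.4, tolerance = 1e-12)
  # vectorized and recycled
  expect_length(eval_incidence_equation(c(0.1, 0.2), 0, 0.01, 2), 2L)
})

test_that("incidence equation rejects out-of-domain inputs", {
  expect_error(eval_incidence_equation(1, 0, 0.01, 2), "\\[0, 1\\)")
  expect_error(eval_incidence_equation(-0.1, 0, 0.01, 2), "\\[0, 1\\)")
  expect_error(eval_incidence_equation(0.5, 0, -0.01, 2), "nonnegative")
  expect_error(eval_incidence_equation(0.5, 0, 0.01, 0), "positive")
  expect_error(eval_pde_rhs(1, 0.01, 0.01, 2), "\\[0, 1\\)")
})

test_that("rearranged equation is the exact inverse of the incidence form", {
  # disease-free population: change equals incidence
  expect_identical(eval_pde_rhs(p = 0, i = 0.005, m = 0.01, mrr = 2), 0.005)
  expect_equal(eval_pde_rhs(p = 0.1, i = 1 / 1100, m = 0.01, mrr = 2), 0,
               tolerance = 1e-15)
  # round trip over random valid tuples, both directions
  set.seed(101)
  for (k in 1:200) {
    p <- runif(1, 0, 0.95); dp <- runif(1, -0.02, 0.05)
    m <- runif(1, 0, 0.2); mrr <- runif(1, 0.2, 12)
    i <- eval_incidence_equation(p, dp, m, mrr)
    expect_equal(eval_pde_rhs(p, i, m, mrr), dp, tolerance = 1e-12)
    dp2 <- eval_pde_rhs(p, i, m, mrr)
    expect_equal(eval_incidence_equation(p, dp2, m, mrr), i, tolerance = 1e-12)
  }
  # equal-mortality limit: equation reduces to dp / (1 - p)
  p <- seq(0, 0.9, by = 0.1); dp <- 0.01
  expect_equal(eval_incidence_equation(p, dp, m = 0.05, mrr = 1), dp / (1 - p))
})

test_that("mortality rate ratio profile is log-linear with clamping", {
  prof <- mrr_profile(8.0, 2.75)
  expect_identical(mrr_at(prof, 30), 8.0)
  expect_identical(mrr_at(prof, 80), 2.75)
  expect_equal(mrr_at(prof, 55), sqrt(8 * 2.75), tolerance = 1e-12)
  # clamped to anchors outside the interval
  expect_identical(mrr_at(prof, c(18, 25)), c(8.0, 8.0))
  expect_identical(mrr_at(prof, 95), 2.75)
  # log(MRR) affine in age: vanishing second differences on the interior
  lm_ <- log(mrr_at(prof, seq(30, 80, by = 5)))
  expect_equal(max(abs(diff(diff(lm_)))), 0, tolerance = 1e-12)
  expect_error(mrr_profile(0, 2.75), "positive")
  expect_error(mrr_profile(8, -1), "positive")
  expect_error(mrr_profile(8, 2.75, age_lo = 80, age_hi = 30), "age_lo")
})

test_that("forward solver matches closed forms along characteristics", {
  # no inflow, empty initial state: prevalence stays zero
  sc0 <- scenario_spec(incidence = function(a, t, s) 0 * a,
                       m0 = function(a, s) 1e-4 * exp(0.09 * a),
                       mrr = mrr_profile(8, 2.75),
                       wave_years = c(2000, 2006))
  expect_equal(max(abs(solve_prevalence_forward(sc0, 20:79, 2003, "male")$p)), 0)
  # constant incidence, no excess mortality: p(a) = 1 - exp(-c a)
  cc <- 0.005
  sc1 <- scenario_spec(incidence = function(a, t, s) rep(cc, length(a)),
                       m0 = function(a, s) 0 * a, mrr = mrr_profile(1, 1),
                       wave_years = c(2000, 2006))
  ages <- seq(20, 79, by = 0.5)
  got <- solve_prevalence_forward(sc1, ages, 2003, "male")$p
  expect_equal(got, 1 - exp(-cc * ages), tolerance = 1e-8)
  # monotone increase along a cohort when incidence is positive
  expect_true(all(diff(got) > 0))
})

test_that("general mortality emitted by the solver is the compartment mixture", {
  sc <- make_default_scenario()
  res <- solve_prevalence_forward(sc, 40:70, 2009, "female")
  m0 <- sc$m0(40:70, "female")
  expect_equal(res$m_general,
               m0 * (1 + res$p * (mrr_at(sc$mrr, 40:70) - 1)),
               tolerance = 1e-12)
})

test_that("stationary prevalence balances inflow and excess outflow", {
  # where dp = 0 along the characteristic the equation gives
  # i = m p (MRR-1) / (p (MRR-1) + 1) exactly
  p <- 0.2; m <- 0.03; mrr <- 4
  i_bal <- m * p * (mrr - 1) / (p * (mrr - 1) + 1)
  expect_equal(eval_pde_rhs(p, i_bal, m, mrr), 0, tolerance = 1e-15)
  expect_equal(eval_incidence_equation(p, 0, m, mrr), i_bal, tolerance = 1e-15)
})

test_that("scenario validation rejects inconsistent specifications", {
  m0 <- function(a, s) 0 * a
  expect_error(scenario_spec(function(a, t, s) -0.01 + 0 * a, m0,
                             mrr_profile(8, 2.75), c(2000, 2006)),
               "nonnegative")
  expect_error(scenario_spec(function(a, t, s) 0 * a, m0,
                             mrr_profile(8, 2.75), 2000),
               "at least two")
  expect_error(scenario_spec(function(a, t, s) 0 * a, m0,
                             mrr_profile(8, 2.75), c(2006, 2000)),
               "at least two")
  expect_error(scenario_spec(function(a, t, s) 0 * a, m0,
                             mrr_profile(8, 2.75), c(2000, 2006), p0 = 1),
               "p0")
})
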