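# Shared fixtures. Everything is generated in code; heavier fixtures are
# built once per test run and memoized.

# logit-scale prevalence surface that lies exactly in the pooled model's
# span (linear in age, linear year trend, sex shifts and interactions)
inspan_eta <- function(a, t, s) {
  -6.2 + 0.055 * a + ifelse(s == "female", 0.15 + 0.001 * a, 0) +
    (0.012 + 0.0003 * a + ifelse(s == "female", 0.006, 0)) * (t - 2009)
}
inspan_prevalence <- function(a, t, s) stats::plogis(inspan_eta(a, t, s))

# scenario used for smoother-recovery checks: uniform adult age pyramid so
# every age cell carries data, and survey outcomes drawn from inspan_eta
make_inspan_scenario <- function(n_per_wave = 100000, seed = 20251) {
  scenario_spec(incidence = function(a, t, s) rep(0.01, length(a)),
                m0 = function(a, s) 1e-4 * exp(0.08 * a),
                mrr = mrr_profile(8, 2.75),
                wave_years = c(2000, 2006, 2012, 2018),
                n_per_wave = n_per_wave,
                age_weights = rep(1, 60),
                seed = seed)
}

# polynomial logit surface with closed-form derivatives, exactly
# representable by the cubic stage-2 basis: the zero-residual fit makes the
# surface an exact oracle for the estimation step
poly_eta <- function(a, t, s) {
  -6 + 0.08 * a - 4e-4 * a^2 + ifelse(s == "female", 0.1, 0) +
    (0.01 + 2e-4 * a) * (t - 2009)
}
poly_deta <- function(a, t, s) {          # d/da + d/dt
  (0.08 - 8e-4 * a + 2e-4 * (t - 2009)) + (0.01 + 2e-4 * a)
}
exact_poly_surface <- function(wave_years = c(2000, 2006, 2012, 2018)) {
  d <- expand.grid(age = 20:79 + 0.5, year = wave_years,
                   sex = c("female", "male"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$eta <- poly_eta(d$age, d$year, d$sex)
  pool_logit_data(d, age_domain = c(20, 80))
}

# small default-scenario pipeline shared by pipeline tests
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- make_default_scenario(seed = 42, n_per_wave = 8000)
      waves <- lapply(sc$wave_years, function(y) fit_wave(generate_survey(sc, y)))
      surf <- pool_waves(waves)
      mort <- generate_mortality_schedule(sc, years = 2000:2018)
      std <- default_standard_population(sc)
      res <- resample(surf, mort, resampling_config(repetitions = 100, seed = 9),
                      years = midpoint_years(sc$wave_years), std = std)
      cache <<- list(sc = sc, surf = surf, mort = mort, std = std, res = res)
    }
    cache
  }
})

# true age-standardized incidence of a scenario at one year/sex
true_standardized <- function(sc, std, year, sex) {
  sum(std$weight * sc$incidence(std$midpoint, year, sex))
}
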