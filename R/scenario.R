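#' Synthetic ground-truth scenario for the illness-death model
#'
#' A scenario bundles everything needed to run the forward illness-death
#' model and to simulate survey data from it: the true incidence rate
#' surface, disease-free (background) mortality, the mortality rate ratio
#' profile, the cohort boundary condition, wave years and sampling
#' configuration. It is the ground truth against which the estimation
#' pipeline is validated.
#'
#' The forward model is parameterized by *disease-free* mortality `m0`; the
#' general-population mortality that the estimation equation consumes is
#' derived internally as \eqn{m = m_0 (1 + p(MRR - 1))}, which keeps
#' simulator and estimator mutually consistent.
#'
#' @param incidence function `f(age, year, sex)` returning the true incidence
#'   rate per person-year; must be nonnegative and vectorized in `age`/`year`.
#' @param m0 function `f(age, sex)` returning disease-free mortality per
#'   person-year; nonnegative, vectorized in `age`.
#' @param mrr an [mrr_profile()].
#' @param wave_years strictly increasing integer survey years; at least two
#'   cross-sections are required to identify a temporal trend.
#' @param n_per_wave persons sampled per survey wave.
#' @param age_range ages over which estimation runs (default 20--79; older
#'   ages are excluded as survey samples there are small).
#' @param a0,p0 cohort boundary condition: prevalence `p0` at age `a0`.
#'   The default `p(0) = 0` reflects a disease that is absent at birth.
#' @param sexes labels for the strata simulated.
#' @param age_weights either `NULL` (mildly declining adult age pyramid) or a
#'   vector of positive sampling weights over the integer ages in
#'   `age_range`.
#' @param weight_sdlog log-scale standard deviation of the log-normal survey
#'   weights (unit mean); 0 gives equal weights.
#' @param weight_informativeness amount by which the sampling weight is tilted
#'   by disease status (0 = non-informative design, the default).
#' @param seed integer seed stored with the scenario and used by the
#'   generators.
#' @return An object of class `scenario_spec`.
#' @seealso [make_default_scenario()], [solve_prevalence_forward()],
#'   [generate_survey()]
#' @export
scenario_spec <- function(incidence, m0, mrr, wave_years,
                          n_per_wave = 44000L,
                          age_range = c(20, 79),
                          a0 = 0, p0 = 0,
                          sexes = c("male", "female"),
                          age_weights = NULL,
                          weight_sdlog = 0.5,
                          weight_informativeness = 0,
                          seed = 1L) {
  stopifnot(is.function(incidence), is.function(m0),
            inherits(mrr, "mrr_profile"))
  wave_years <- as.numeric(wave_years)
  if (length(wave_years) < 2L || any(diff(wave_years) <= 0))
    stop("at least two strictly increasing wave years are required: ",
         "the temporal derivative of prevalence needs two cross-sections",
         call. = FALSE)
  if (p0 < 0 || p0 >= 1) stop("p0 must lie in [0, 1)", call. = FALSE)
  if (a0 > age_range[1]) stop("a0 must not exceed the lower age bound",
                              call. = FALSE)
  ages_chk <- seq(age_range[1], age_range[2], by = 2)
  yrs_chk <- seq(min(wave_years), max(wave_years), length.out = 5)
  for (s in sexes) {
    iv <- outer(ages_chk, yrs_chk, function(a, t) incidence(a, t, s))
    if (any(!is.finite(iv)) || any(iv < 0))
      stop("incidence function must be nonnegative and finite over the ",
           "age/year domain (sex = ", s, ")", call. = FALSE)
    mv <- m0(ages_chk, s)
    if (any(!is.finite(mv)) || any(mv < 0))
      stop("m0 must be nonnegative and finite (sex = ", s, ")", call. = FALSE)
  }
  ages_int <- seq(age_range[1], age_range[2])
  if (is.null(age_weights)) {
    age_weights <- exp(-0.03 * (ages_int - age_range[1]))
  }
  if (length(age_weights) != length(ages_int) || any(age_weights <= 0))
    stop("age_weights must be positive, one per integer age in age_range",
         call. = FALSE)
  structure(list(incidence = incidence, m0 = m0, mrr = mrr,
                 wave_years = wave_years,
                 n_per_wave = as.integer(n_per_wave),
                 age_range = age_range, a0 = a0, p0 = p0,
                 sexes = sexes,
                 age_weights = age_weights / sum(age_weights),
                 weight_sdlog = weight_sdlog,
                 weight_informativeness = weight_informativeness,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Illness-death scenario\n")
  cat(sprintf("  waves: %s (n = %d each)\n",
              paste(x$wave_years, collapse = ", "), x$n_per_wave))
  cat(sprintf("  ages: %g-%g, sexes: %s\n", x$age_range[1], x$age_range[2],
              paste(x$sexes, collapse = ", ")))
  print(x$mrr)
  invisible(x)
}

#' Default diabetes-like scenario
#'
#' Emulates the scale and qualitative structure of a national repeated
#' cross-sectional health survey: four waves six years apart with about
#' 44,000 persons each and roughly half women; a self-reported-diagnosis
#' style binary outcome whose true incidence rises steeply with age to a
#' peak near age 65 and then declines, with a mild log-linear calendar
#' trend that is stronger in women; Gompertz disease-free mortality; and a
#' mortality rate ratio falling log-linearly from 8.0 at age 30 to 2.75 at
#' age 80 (midpoints of the plausible anchor ranges used in estimation).
#'
#' @param seed integer seed propagated to the scenario.
#' @param n_per_wave persons per survey wave (default 44,000).
#' @param wave_years survey years (default 2000, 2006, 2012, 2018).
#' @param gompertz_alpha,gompertz_beta disease-free mortality
#'   \eqn{m_0(a) = \alpha e^{\beta a}} (per person-year); women get a 0.75
#'   proportional hazard relative to men.
#' @param incidence_peak_age,incidence_sigma age of peak incidence and
#'   Gaussian width of the age profile, in years.
#' @param incidence_scale named per-sex peak incidence (per person-year) at
#'   the reference year.
#' @param trend named per-sex log-linear annual trend in incidence.
#' @param reference_year calendar year at which `incidence_scale` applies.
#' @return A [scenario_spec()].
#' @export
make_default_scenario <- function(seed = 1L,
                                  n_per_wave = 44000L,
                                  wave_years = c(2000, 2006, 2012, 2018),
                                  gompertz_alpha = 5e-5,
                                  gompertz_beta = 0.09,
                                  incidence_peak_age = 65,
                                  incidence_sigma = 16,
                                  incidence_scale = c(male = 0.019,
                                                      female = 0.022),
                                  trend = c(male = 0.023, female = 0.040),
                                  reference_year = 2009) {
  force(gompertz_alpha); force(gompertz_beta)
  force(incidence_peak_age); force(incidence_sigma)
  force(incidence_scale); force(trend); force(reference_year)
  inc <- function(age, year, sex) {
    incidence_scale[[sex]] *
      exp(-0.5 * ((age - incidence_peak_age) / incidence_sigma)^2) *
      exp(trend[[sex]] * (year - reference_year))
  }
  m0 <- function(age, sex) {
    hr <- if (identical(sex, "female")) 0.75 else 1
    hr * gompertz_alpha * exp(gompertz_beta * age)
  }
  scenario_spec(incidence = inc, m0 = m0,
                mrr = mrr_profile(8.0, 2.75),
                wave_years = wave_years, n_per_wave = n_per_wave,
                seed = seed)
}

#' True prevalence from forward integration along birth cohorts
#'
#' Integrates the illness-death model forward in age along characteristics
#' (lines of constant birth year, \eqn{t - a} fixed), on which the governing
#' partial differential equation reduces to the ordinary differential
#' equation
#' \deqn{dp/da = (1 - p)\,[\,i(a, t_0 + a - a_0) - p\,m_0(a)(MRR(a) - 1)\,]}
#' starting from \eqn{p(a_0) = p_0}. All requested (age, year) pairs are
#' grouped by birth cohort and all cohorts are integrated simultaneously as
#' one vector ODE with an adaptive solver (`deSolve::lsoda`, absolute
#' tolerance 1e-10).
#'
#' @param scenario a [scenario_spec()].
#' @param age,year numeric vectors, recycled to a common length; each pair
#'   identifies one evaluation point.
#' @param sex one sex label present in the scenario.
#' @return A data frame with columns `age`, `year`, `p` (true prevalence) and
#'   `m_general`, the general-population mortality
#'   \eqn{m_0(a)(1 + p(MRR - 1))} that the estimation equation expects.
#' @export
solve_prevalence_forward <- function(scenario, age, year, sex) {
  stopifnot(inherits(scenario, "scenario_spec"),
            sex %in% scenario$sexes)
  n <- max(length(age), length(year))
  age <- rep_len(as.numeric(age), n)
  year <- rep_len(as.numeric(year), n)
  if (any(age < scenario$a0))
    stop("requested ages must not precede the boundary age a0", call. = FALSE)
  birth <- round(year - age, 9)
  cohorts <- sort(unique(birth))
  a0 <- scenario$a0
  times <- sort(unique(c(a0, age)))
  inc <- scenario$incidence; m0f <- scenario$m0; mrr <- scenario$mrr

  deriv <- function(a, p, parms) {
    excess <- p * m0f(a, sex) * (mrr_at(mrr, a) - 1)
    list((1 - p) * (inc(a, cohorts + a, sex) - excess))
  }
  sol <- deSolve::lsoda(y = rep(scenario$p0, length(cohorts)),
                        times = times, func = deriv, parms = NULL,
                        atol = 1e-10, rtol = 1e-8)
  pm <- sol[, -1, drop = FALSE]          # times x cohorts
  if (any(!is.finite(pm)))
    stop("forward integration failed along a characteristic (non-finite ",
         "prevalence); check the scenario's rate functions", call. = FALSE)
  bad <- pm < -1e-8 | pm >= 1
  if (any(bad)) {
    k <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "prevalence left [0, 1) along the characteristic with birth year %g (age %g)",
      cohorts[k[2]], times[k[1]]), call. = FALSE)
  }
  pm[pm < 0] <- 0
  it <- match(age, times)
  ic <- match(birth, cohorts)
  p <- pm[cbind(it, ic)]
  m_gen <- m0f(age, sex) * (1 + p * (mrr_at(mrr, age) - 1))
  data.frame(age = age, year = year, p = p, m_general = m_gen)
}

#' True prevalence on an age-by-year grid
#'
#' Convenience wrapper around [solve_prevalence_forward()] that evaluates the
#' scenario's true prevalence and general-population mortality on the outer
#' grid of `ages` and `years`.
#'
#' @inheritParams solve_prevalence_forward
#' @param ages,years numeric grid vectors.
#' @return A list with matrices `p` and `m_general` (ages in rows, years in
#'   columns, dimnames set accordingly).
#' @export
prevalence_grid <- function(scenario, ages, years, sex) {
  g <- expand.grid(age = ages, year = years)
  res <- solve_prevalence_forward(scenario, g$age, g$year, sex)
  shape <- function(v) matrix(v, nrow = length(ages), ncol = length(years),
                              dimnames = list(ages, years))
  list(p = shape(res$p), m_general = shape(res$m_general))
}
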