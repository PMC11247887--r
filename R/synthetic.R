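# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate one cross-sectional survey wave
#'
#' Draws person-level records from the scenario's true prevalence surface.
#' Ages are sampled as integer years from the scenario's population age
#' distribution; the disease indicator is Bernoulli with success probability
#' equal to the true prevalence evaluated at age + 0.5 (an integer recorded
#' age stands for the interval `[age, age + 1)`, so the model is read at the
#' interval midpoint); sampling weights are log-normal with unit mean to
#' exercise weighted fitting. With a fixed seed the output is reproducible
#' record for record.
#'
#' @param scenario a [scenario_spec()].
#' @param wave_year one of the scenario's wave years.
#' @param n number of persons (default: the scenario's per-wave size).
#' @param seed integer seed; default derives one from the scenario seed and
#'   the wave index so different waves get independent draws.
#' @param prevalence optional override `f(age, year, sex)` returning the true
#'   prevalence; defaults to the scenario's forward-model solution. Useful
#'   for simulating from a surface of known parametric form.
#' @return Data frame with columns `id`, `age`, `sex`, `survey_year`,
#'   `disease`, `weight`.
#' @export
generate_survey <- function(scenario, wave_year, n = scenario$n_per_wave,
                            seed = NULL, prevalence = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (!wave_year %in% scenario$wave_years)
    stop("wave_year ", wave_year, " is not one of the scenario's waves (",
         paste(scenario$wave_years, collapse = ", "), ")", call. = FALSE)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (is.null(seed))
    seed <- scenario$seed + 1000L * match(wave_year, scenario$wave_years)
  ages_int <- seq(scenario$age_range[1], scenario$age_range[2])
  # true prevalence at interval midpoints, one lookup per (age, sex)
  ptab <- lapply(scenario$sexes, function(s) {
    if (is.null(prevalence)) {
      solve_prevalence_forward(scenario, ages_int + 0.5, wave_year, s)$p
    } else {
      prevalence(ages_int + 0.5, wave_year, s)
    }
  })
  names(ptab) <- scenario$sexes
  with_seed(seed, {
    sex <- sample(scenario$sexes, n, replace = TRUE)
    age <- sample(ages_int, n, replace = TRUE, prob = scenario$age_weights)
    p <- numeric(n)
    for (s in scenario$sexes) {
      k <- sex == s
      p[k] <- ptab[[s]][match(age[k], ages_int)]
    }
    disease <- as.integer(stats::runif(n) < p)
    sdl <- scenario$weight_sdlog
    weight <- if (sdl > 0)
      stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
    else rep(1, n)
    if (scenario$weight_informativeness != 0)
      weight <- weight * exp(scenario$weight_informativeness * disease)
    data.frame(id = seq_len(n), age = age, sex = sex,
               survey_year = as.integer(wave_year),
               disease = disease, weight = weight)
  })
}

#' Simulate every wave of a scenario
#'
#' @inheritParams generate_survey
#' @return One data frame with all waves stacked (ids restart per wave).
#' @export
generate_all_waves <- function(scenario, n = scenario$n_per_wave,
                               prevalence = NULL) {
  do.call(rbind, lapply(scenario$wave_years, function(y)
    generate_survey(scenario, y, n = n, prevalence = prevalence)))
}

#' General-population mortality schedule implied by a scenario
#'
#' Evaluates the forward model's general-population mortality
#' \eqn{m_0(a)(1 + p(a,t)(MRR(a) - 1))} — the mixture of diseased and
#' disease-free mortality — on a grid, as the synthetic stand-in for a vital
#' statistics extract.
#'
#' @param scenario a [scenario_spec()].
#' @param ages,years grid vectors (defaults: the scenario's integer age range
#'   and the span of its wave years).
#' @return A [mortality_schedule()].
#' @export
generate_mortality_schedule <- function(scenario,
                                        ages = seq(scenario$age_range[1],
                                                   scenario$age_range[2]),
                                        years = seq(min(scenario$wave_years),
                                                    max(scenario$wave_years))) {
  rows <- lapply(scenario$sexes, function(s) {
    g <- expand.grid(age = ages, year = years)
    res <- solve_prevalence_forward(scenario, g$age, g$year, s)
    data.frame(year = g$year, sex = s, age = g$age, rate = res$m_general)
  })
  mortality_schedule(do.call(rbind, rows))
}

#' Standard population implied by a scenario's age distribution
#'
#' Aggregates the scenario's population age weights into 10-year groups over
#' the estimation age range, yielding the default standard for direct age
#' standardization. Being derived from the sampling distribution itself (not
#' from any one simulated sample), it is deterministic. Any other standard
#' (e.g. a WHO standard) can be supplied via [standard_population()].
#'
#' @param scenario a [scenario_spec()].
#' @param width age-group width in years (default 10).
#' @return A [standard_population()].
#' @export
default_standard_population <- function(scenario, width = 10) {
  lo <- seq(scenario$age_range[1], scenario$age_range[2], by = width)
  hi <- pmin(lo + width - 1, scenario$age_range[2])
  ages_int <- seq(scenario$age_range[1], scenario$age_range[2])
  w <- vapply(seq_along(lo), function(k)
    sum(scenario$age_weights[ages_int >= lo[k] & ages_int <= hi[k]]),
    numeric(1))
  standard_population(lo, hi, w)
}
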