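#' Standard population for direct age standardization
#'
#' @param age_lo,age_hi inclusive integer bounds of the age groups; groups
#'   must tile the age range contiguously and without overlap.
#' @param weight nonnegative group weights, not all zero; normalized to sum
#'   to one before use.
#' @return An object of class `standard_population` (a data frame with
#'   columns `age_lo`, `age_hi`, `weight`, `midpoint`).
#' @export
standard_population <- function(age_lo, age_hi, weight) {
  stopifnot(length(age_lo) == length(age_hi),
            length(age_lo) == length(weight))
  o <- order(age_lo)
  age_lo <- age_lo[o]; age_hi <- age_hi[o]; weight <- weight[o]
  if (any(age_hi < age_lo))
    stop("each age group needs age_lo <= age_hi", call. = FALSE)
  if (length(age_lo) > 1L && any(age_lo[-1] != age_hi[-length(age_hi)] + 1))
    stop("age groups must tile the range contiguously without overlap",
         call. = FALSE)
  if (any(weight < 0) || sum(weight) <= 0)
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  out <- data.frame(age_lo = age_lo, age_hi = age_hi,
                    weight = weight / sum(weight),
                    midpoint = (age_lo + age_hi + 1) / 2)
  class(out) <- c("standard_population", "data.frame")
  out
}

#' Midpoint estimation years between consecutive survey waves
#'
#' The incidence equation uses the prevalence trend between cross-sections,
#' so estimation is anchored midway between consecutive survey years: waves
#' in 2000/2006/2012/2018 give estimation years 2003, 2009 and 2015.
#'
#' @param wave_years at least two strictly increasing survey years.
#' @return Numeric vector of consecutive-pair midpoints.
#' @export
midpoint_years <- function(wave_years) {
  wave_years <- as.numeric(wave_years)
  if (length(wave_years) < 2L || any(diff(wave_years) <= 0))
    stop("need at least two strictly increasing wave years", call. = FALSE)
  (wave_years[-length(wave_years)] + wave_years[-1]) / 2
}

#' Plug-in incidence curve at one year and sex
#'
#' Evaluates the incidence equation age by age: prevalence and its cohort
#' derivative from the smoothed surface, general-population mortality from
#' the schedule (interpolated), and the mortality rate ratio from the
#' profile.
#'
#' @param surface a `prevalence_surface` (see [pool_waves()]).
#' @param mortality a [mortality_schedule()].
#' @param mrr an [mrr_profile()].
#' @param year estimation year (within the surface's year span).
#' @param sex one sex label.
#' @param ages evaluation ages.
#' @param derivative `"analytic"` or `"finite_difference"` cohort derivative.
#' @return Data frame `age`, `rate` (per person-year), `negative` flag.
#' @export
estimate_curve <- function(surface, mortality, mrr, year, sex,
                           ages = 20:79,
                           derivative = c("analytic", "finite_difference")) {
  derivative <- match.arg(derivative)
  p <- predict_surface(surface, ages, year, sex)
  dp <- directional_derivative(surface, ages, year, sex, method = derivative)
  m <- mortality_at(mortality, ages, year, sex)
  i <- eval_incidence_equation(p, dp, m, mrr_at(mrr, ages))
  data.frame(age = ages, rate = i, negative = i < 0)
}

#' Resampling configuration
#'
#' @param repetitions number of resampling repetitions (default 2000).
#' @param mrr_lo_range,mrr_hi_range plausible ranges for the mortality rate
#'   ratio anchors; each repetition draws the two anchors from uniform
#'   distributions over these ranges (defaults 7.5--8.5 at age 30 and
#'   2.5--3.0 at age 80).
#' @param mrr_ages anchor ages (default 30 and 80).
#' @param common_quantile if `TRUE` the two anchors are drawn with a shared
#'   uniform quantile (perfectly rank-correlated) instead of independently.
#' @param seed integer seed for the resampling stream.
#' @return An object of class `resampling_config`.
#' @export
resampling_config <- function(repetitions = 2000L,
                              mrr_lo_range = c(7.5, 8.5),
                              mrr_hi_range = c(2.5, 3.0),
                              mrr_ages = c(30, 80),
                              common_quantile = FALSE,
                              seed = 1L) {
  repetitions <- as.integer(repetitions)
  if (is.na(repetitions) || repetitions < 2L)
    stop("repetitions must be at least 2", call. = FALSE)
  for (r in list(mrr_lo_range, mrr_hi_range))
    if (length(r) != 2L || r[1] > r[2] || any(r <= 0))
      stop("MRR anchor ranges must be positive with lo <= hi", call. = FALSE)
  structure(list(repetitions = repetitions,
                 mrr_lo_range = mrr_lo_range, mrr_hi_range = mrr_hi_range,
                 mrr_ages = mrr_ages, common_quantile = common_quantile,
                 seed = as.integer(seed)),
            class = "resampling_config")
}

#' Resampled incidence estimates with percentile bands
#'
#' Repeats the incidence estimation `repetitions` times. Each repetition
#' draws one surface from the sampling distribution of the pooled prevalence
#' fit ([sample_surface()]) and one mortality-rate-ratio profile with the
#' two anchors drawn from their uniform plausible ranges, then evaluates the
#' incidence equation at every (age, year, sex) cell. Age-group rates (at
#' the group midpoints), the age-standardized rate, and any rate ratios are
#' computed *within* each repetition and summarized afterwards by their
#' 2.5th, 50th and 97.5th percentiles (linear interpolation between order
#' statistics, R quantile type 7). The median is the reported point
#' estimate; a no-noise plug-in curve (mean coefficients, mid-range MRR
#' anchors) is stored alongside.
#'
#' @inheritParams estimate_curve
#' @param config a [resampling_config()].
#' @param years estimation years (typically [midpoint_years()] of the
#'   waves).
#' @param sexes sex labels to estimate.
#' @param std a [standard_population()] for per-repetition age
#'   standardization.
#' @return An object of class `incidence_result` holding, per (sex, year):
#'   the per-age percentile bands, plug-in point curve and negative-value
#'   flags, plus per-repetition age-group and standardized rates (all rates
#'   per person-year; multiply by 1000 only when reporting).
#' @export
resample <- function(surface, mortality, config, years,
                     sexes = surface$basis$sex_levels, ages = 20:79,
                     std = NULL,
                     derivative = c("analytic", "finite_difference")) {
  stopifnot(inherits(config, "resampling_config"))
  derivative <- match.arg(derivative)
  R <- config$repetitions
  cells <- expand.grid(age = ages, year = years, sex = sexes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nc <- nrow(cells)
  X <- .surface_design(surface$basis, cells$age, cells$year, cells$sex)
  Xd <- .surface_design(surface$basis, cells$age, cells$year, cells$sex,
                        d_age = 1L) +
        .surface_design(surface$basis, cells$age, cells$year, cells$sex,
                        d_year = 1L)
  m <- mortality_at(mortality, cells$age, cells$year, sexes[1])
  for (s in sexes) {
    k <- cells$sex == s
    m[k] <- mortality_at(mortality, cells$age[k], cells$year[k], s)
  }
  L <- .surface_chol(surface)
  draws <- with_seed(config$seed, {
    Z <- matrix(stats::rnorm(length(surface$coef) * R),
                nrow = length(surface$coef))
    u1 <- stats::runif(R)
    u2 <- if (config$common_quantile) u1 else stats::runif(R)
    list(B = surface$coef + crossprod(L, Z),
         mrr_lo = config$mrr_lo_range[1] + u1 * diff(config$mrr_lo_range),
         mrr_hi = config$mrr_hi_range[1] + u2 * diff(config$mrr_hi_range))
  })
  eta <- X %*% draws$B                      # cells x R
  if (derivative == "analytic") {
    deta <- Xd %*% draws$B
    P <- stats::plogis(eta)
    DP <- P * (1 - P) * deta
  } else {
    h <- 0.1
    dom <- surface$basis$age_domain
    up <- pmin(cells$age + h, dom[2]); dn <- pmax(cells$age - h, dom[1])
    Xu <- .surface_design(surface$basis, up, cells$year + (up - cells$age),
                          cells$sex)
    Xl <- .surface_design(surface$basis, dn, cells$year - (cells$age - dn),
                          cells$sex)
    P <- stats::plogis(eta)
    DP <- (stats::plogis(Xu %*% draws$B) - stats::plogis(Xl %*% draws$B)) /
      (up - dn)
  }
  # log-linear MRR between the anchor ages, clamped outside
  aw <- (pmin(pmax(cells$age, config$mrr_ages[1]), config$mrr_ages[2]) -
           config$mrr_ages[1]) / diff(config$mrr_ages)
  MRR <- exp(outer(1 - aw, log(draws$mrr_lo)) + outer(aw, log(draws$mrr_hi)))
  denom <- P * (MRR - 1) + 1
  I <- DP / (1 - P) + m * P * (MRR - 1) / denom
  qs <- c(0.025, 0.5, 0.975)
  band <- t(apply(I, 1, stats::quantile, probs = qs, names = FALSE))
  colnames(band) <- c("lo", "median", "hi")

  # plug-in point curve: mean coefficients, mid-range MRR anchors
  mrr_point <- mrr_profile(mean(config$mrr_lo_range),
                           mean(config$mrr_hi_range),
                           config$mrr_ages[1], config$mrr_ages[2])
  point <- unlist(lapply(sexes, function(s) lapply(years, function(y)
    estimate_curve(surface, mortality, mrr_point, y, s, ages,
                   derivative = derivative)$rate)))
  # reorder: cells has age fastest, then year, then sex -- same as above
  point <- as.numeric(point)

  group_rates <- std_rates <- NULL
  if (!is.null(std)) {
    stopifnot(inherits(std, "standard_population"))
    if (any(std$midpoint < min(ages)) || any(std$midpoint > max(ages)))
      stop("standard population group midpoints outside the age grid",
           call. = FALSE)
    gr <- array(NA_real_, c(nrow(std), length(years), length(sexes), R),
                dimnames = list(paste0(std$age_lo, "-", std$age_hi),
                                years, sexes, NULL))
    gp <- array(NA_real_, c(nrow(std), length(years), length(sexes)),
                dimnames = dimnames(gr)[1:3])
    for (si in seq_along(sexes)) for (yi in seq_along(years)) {
      base <- which(cells$sex == sexes[si] & cells$year == years[yi])
      for (gi in seq_len(nrow(std))) {
        row <- .curve_value_rows(ages, std$midpoint[gi], base)
        gr[gi, yi, si, ] <- row$w1 * I[row$i1, ] + row$w2 * I[row$i2, ]
        gp[gi, yi, si] <- row$w1 * point[row$i1] + row$w2 * point[row$i2]
      }
    }
    std_r <- apply(gr, c(2, 3, 4), function(v) sum(v * std$weight))
    std_p <- apply(gp, c(2, 3), function(v) sum(v * std$weight))
    group_rates <- gr
    std_rates <- std_r
    std_point <- std_p
  } else std_point <- NULL

  structure(list(ages = ages, years = years, sexes = sexes,
                 config = config, std = std,
                 cells = cells,
                 point = point, band = band,
                 negative = point < 0,
                 group_rates = group_rates, std_rates = std_rates,
                 std_point = std_point),
            class = "incidence_result")
}

# linear interpolation bracket of `target` age within grid `ages`,
# expressed as row offsets into a cell block
.curve_value_rows <- function(ages, target, base) {
  if (target < min(ages) || target > max(ages))
    stop("age ", target, " outside the curve's age grid", call. = FALSE)
  i1 <- max(which(ages <= target))
  i2 <- min(which(ages >= target))
  w <- if (i1 == i2) 0 else (target - ages[i1]) / (ages[i2] - ages[i1])
  list(i1 = base[i1], i2 = base[i2], w1 = 1 - w, w2 = w)
}

#' @export
print.incidence_result <- function(x, ...) {
  cat(sprintf(
    "Incidence estimates: %d ages x years %s x sexes %s; R = %d repetitions\n",
    length(x$ages), paste(x$years, collapse = "/"),
    paste(x$sexes, collapse = "/"), x$config$repetitions))
  if (any(x$negative))
    cat(sprintf("  %d plug-in cells are negative (flagged, not truncated)\n",
                sum(x$negative)))
  invisible(x)
}

#' Rate of one 10-year age group from an incidence curve
#'
#' The group rate is the curve evaluated at the group midpoint age (e.g. 55
#' for ages 50--59, 25 for 20--29), by linear interpolation on the curve's
#' age grid when the midpoint is not a grid age.
#'
#' @param curve data frame with columns `age` and `rate` (as returned by
#'   [estimate_curve()]).
#' @param group integer vector `c(lo, hi)` of the inclusive group bounds.
#' @return The group rate (same units as the curve).
#' @export
age_group_rate <- function(curve, group) {
  mid <- (group[1] + group[2] + 1) / 2
  if (mid < min(curve$age) || mid > max(curve$age))
    stop("group midpoint ", mid, " outside the curve's age domain",
         call. = FALSE)
  stats::approx(curve$age, curve$rate, xout = mid)$y
}

#' Directly age-standardized rate of an incidence curve
#'
#' Weighted mean of the age-group rates (each group evaluated at its
#' midpoint, see [age_group_rate()]) using the standard population's
#' normalized weights.
#'
#' @inheritParams age_group_rate
#' @param std a [standard_population()].
#' @return The age-standardized rate.
#' @export
age_standardize <- function(curve, std) {
  stopifnot(inherits(std, "standard_population"))
  g <- vapply(seq_len(nrow(std)), function(k)
    age_group_rate(curve, c(std$age_lo[k], std$age_hi[k])), numeric(1))
  sum(g * std$weight)
}

#' Incidence rate ratio between two calendar years
#'
#' The ratio is formed within each resampling repetition (numerator-year
#' summary over denominator-year summary of the same repetition) and then
#' summarized by its median and 2.5th/97.5th percentiles, which correctly
#' carries the strong within-repetition dependence of the two years into
#' the interval. Repetitions with a non-positive denominator are excluded
#' and counted.
#'
#' @param result an [resample()] result built with a standard population.
#' @param year_num,year_den numerator and denominator years.
#' @param sex one sex label.
#' @param level `"standardized"` (age-standardized rates) or `"group"`.
#' @param group for `level = "group"`, the `c(lo, hi)` age group.
#' @return A list with `irr` (median of repetition ratios), `lo`, `hi`
#'   (percentile bounds) and `n_excluded`.
#' @export
incidence_rate_ratio <- function(result, year_num, year_den, sex,
                                 level = c("standardized", "group"),
                                 group = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(result, "incidence_result"))
  if (is.null(result$std_rates))
    stop("result was built without a standard population", call. = FALSE)
  yi_n <- match(year_num, result$years)
  yi_d <- match(year_den, result$years)
  si <- match(sex, result$sexes)
  if (is.na(yi_n) || is.na(yi_d))
    stop("both years must be present in the result", call. = FALSE)
  if (level == "standardized") {
    num <- result$std_rates[yi_n, si, ]
    den <- result$std_rates[yi_d, si, ]
  } else {
    if (is.null(group)) stop("level = 'group' needs a group", call. = FALSE)
    gi <- match(paste0(group[1], "-", group[2]),
                dimnames(result$group_rates)[[1]])
    if (is.na(gi)) stop("group not present in the result", call. = FALSE)
    num <- result$group_rates[gi, yi_n, si, ]
    den <- result$group_rates[gi, yi_d, si, ]
  }
  ok <- den > 0
  ratio <- num[ok] / den[ok]
  q <- stats::quantile(ratio, c(0.025, 0.5, 0.975), names = FALSE)
  list(irr = q[2], lo = q[1], hi = q[3], n_excluded = sum(!ok))
}

#' Summary table of standardized and age-group incidence rates
#'
#' Builds the reporting table: one block per sex with an age-standardized
#' row followed by the 10-year age-group rows; per estimation year the
#' median rate and 2.5th--97.5th percentile band (per 1000 person-years,
#' the only place the 1000x reporting scale is applied), and incidence rate
#' ratio columns comparing each later year to the first.
#'
#' @param result an [resample()] result built with a standard population.
#' @return A data frame of class `incidence_report`; see
#'   [write_results()] for serialization and the `format()` method for an
#'   aligned text rendering.
#' @export
report_table <- function(result) {
  stopifnot(inherits(result, "incidence_result"))
  if (is.null(result$std_rates))
    stop("result was built without a standard population", call. = FALSE)
  std <- result$std
  years <- result$years
  qs <- c(0.025, 0.5, 0.975)
  rows <- list()
  for (s in result$sexes) {
    si <- match(s, result$sexes)
    labs <- c("age-standardized",
              paste0(std$age_lo, "-", std$age_hi))
    for (ri in seq_along(labs)) {
      row <- list(sex = s, group = labs[ri])
      for (yi in seq_along(years)) {
        v <- if (ri == 1L) result$std_rates[yi, si, ]
             else result$group_rates[ri - 1L, yi, si, ]
        q <- stats::quantile(v, qs, names = FALSE) * 1000
        row[[paste0("rate_", years[yi])]] <- q[2]
        row[[paste0("lo_", years[yi])]] <- q[1]
        row[[paste0("hi_", years[yi])]] <- q[3]
      }
      if (length(years) > 1L) for (yi in 2:length(years)) {
        irr <- incidence_rate_ratio(
          result, years[yi], years[1], s,
          level = if (ri == 1L) "standardized" else "group",
          group = if (ri > 1L) c(std$age_lo[ri - 1L], std$age_hi[ri - 1L]))
        tag <- paste0(years[yi], "_vs_", years[1])
        row[[paste0("irr_", tag)]] <- irr$irr
        row[[paste0("irr_lo_", tag)]] <- irr$lo
        row[[paste0("irr_hi_", tag)]] <- irr$hi
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  class(out) <- c("incidence_report", "data.frame")
  out
}

#' @export
format.incidence_report <- function(x, ...) {
  years <- sub("^rate_", "", grep("^rate_", names(x), value = TRUE))
  irr_tags <- sub("^irr_(?!lo_|hi_)", "", grep("^irr_(?!lo_|hi_)",
                                               names(x), value = TRUE,
                                               perl = TRUE), perl = TRUE)
  lines <- c(sprintf("%-8s %-16s %s", "sex", "group",
                     paste(c(sprintf("%-18s", paste0(years, " (95% CI)")),
                             sprintf("%-20s", paste0("IRR ", irr_tags))),
                           collapse = " ")))
  fmt_cell <- function(v, lo, hi)
    if (is.na(lo)) sprintf("%-18s", sprintf("%.1f (—)", v))
    else sprintf("%-18s", sprintf("%.1f (%.1f–%.1f)", v, lo, hi))
  for (r in seq_len(nrow(x))) {
    cells <- vapply(years, function(y)
      fmt_cell(x[r, paste0("rate_", y)], x[r, paste0("lo_", y)],
               x[r, paste0("hi_", y)]), character(1))
    irrs <- vapply(irr_tags, function(tg)
      sprintf("%-20s", sprintf("%.2f (%.2f–%.2f)",
                               x[r, paste0("irr_", tg)],
                               x[r, paste0("irr_lo_", tg)],
                               x[r, paste0("irr_hi_", tg)])), character(1))
    lines <- c(lines, sprintf("%-8s %-16s %s", x$sex[r], x$group[r],
                              paste(c(cells, irrs), collapse = " ")))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.incidence_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
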