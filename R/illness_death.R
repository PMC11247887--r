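#' Incidence rate from the illness-death model relation
#'
#' Evaluates the algebraic relation between the incidence rate of an
#' irreversible chronic disease and the quantities observable without
#' follow-up: prevalence \eqn{p}, its directional derivative along birth
#' cohorts \eqn{(\partial_a + \partial_t)p}, the general-population mortality
#' rate \eqn{m}, and the mortality rate ratio \eqn{MRR} of diseased vs.
#' disease-free persons:
#' \deqn{i = \frac{(\partial_a + \partial_t)p}{1 - p}
#'         + m \frac{p(MRR - 1)}{p(MRR - 1) + 1}.}
#'
#' All arguments are vectorized and recycled to a common length. Negative
#' results are returned as computed (no truncation): truncating at zero would
#' bias resampling percentiles downstream. Use the returned sign to flag
#' implausible cells.
#'
#' @param p prevalence, in \eqn{[0, 1)}.
#' @param dp directional derivative of prevalence per year (may be negative).
#' @param m general-population mortality rate per person-year, \eqn{\ge 0}.
#' @param mrr mortality rate ratio, \eqn{> 0}.
#' @return Incidence rate per person-year (same length as the recycled
#'   inputs).
#' @seealso [eval_pde_rhs()] for the inverse relation, [mrr_profile()] for the
#'   age-dependent mortality rate ratio.
#' @examples
#' eval_incidence_equation(p = 0.1, dp = 0, m = 0.01, mrr = 2)
#' @export
eval_incidence_equation <- function(p, dp, m, mrr) {
  n <- max(length(p), length(dp), length(m), length(mrr))
  p <- rep_len(p, n); dp <- rep_len(dp, n)
  m <- rep_len(m, n); mrr <- rep_len(mrr, n)
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    stop("prevalence 'p' must lie in [0, 1): division by 1 - p", call. = FALSE)
  if (any(m < 0)) stop("mortality 'm' must be nonnegative", call. = FALSE)
  if (any(mrr <= 0)) stop("'mrr' must be positive", call. = FALSE)
  denom <- p * (mrr - 1) + 1
  if (any(denom <= 0))
    stop("p*(MRR - 1) + 1 must be positive; offending term at index ",
         which(denom <= 0)[1], call. = FALSE)
  dp / (1 - p) + m * p * (mrr - 1) / denom
}

#' Cohort-direction prevalence change implied by given rates
#'
#' The illness-death model's governing equation rearranged for the directional
#' derivative of prevalence along a birth cohort:
#' \deqn{(\partial_a + \partial_t)p =
#'   (1 - p)\left[i - m\frac{p(MRR-1)}{p(MRR-1)+1}\right].}
#' This is the exact algebraic inverse of [eval_incidence_equation()]:
#' feeding its output back through that function returns `i` to machine
#' precision.
#'
#' @inheritParams eval_incidence_equation
#' @param i incidence rate per person-year, \eqn{\ge 0}.
#' @return Prevalence change per year.
#' @export
eval_pde_rhs <- function(p, i, m, mrr) {
  n <- max(length(p), length(i), length(m), length(mrr))
  p <- rep_len(p, n); i <- rep_len(i, n)
  m <- rep_len(m, n); mrr <- rep_len(mrr, n)
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    stop("prevalence 'p' must lie in [0, 1)", call. = FALSE)
  if (any(m < 0)) stop("mortality 'm' must be nonnegative", call. = FALSE)
  if (any(mrr <= 0)) stop("'mrr' must be positive", call. = FALSE)
  denom <- p * (mrr - 1) + 1
  if (any(denom <= 0))
    stop("p*(MRR - 1) + 1 must be positive; offending term at index ",
         which(denom <= 0)[1], call. = FALSE)
  (1 - p) * (i - m * p * (mrr - 1) / denom)
}

#' Log-linear mortality rate ratio profile
#'
#' The excess mortality of the diseased relative to the disease-free is
#' specified through two anchor values, and log(MRR) is interpolated linearly
#' in age between the anchor ages. Outside `[age_lo, age_hi]` the profile is
#' clamped to the nearest anchor value rather than extrapolated: extending the
#' log-line below the lower anchor would produce implausibly large ratios at
#' young adult ages.
#'
#' @param mrr_lo ratio at `age_lo` (default anchor age 30), must be positive.
#' @param mrr_hi ratio at `age_hi` (default anchor age 80), must be positive.
#' @param age_lo,age_hi anchor ages in years, `age_lo < age_hi`.
#' @return An object of class `mrr_profile`.
#' @examples
#' prof <- mrr_profile(8.0, 2.75)
#' mrr_at(prof, c(20, 30, 55, 80, 95))
#' @export
mrr_profile <- function(mrr_lo, mrr_hi, age_lo = 30, age_hi = 80) {
  stopifnot(is.numeric(mrr_lo), is.numeric(mrr_hi),
            length(mrr_lo) == 1L, length(mrr_hi) == 1L)
  if (!is.finite(mrr_lo) || !is.finite(mrr_hi) || mrr_lo <= 0 || mrr_hi <= 0)
    stop("MRR anchor values must be positive and finite (log must exist)",
         call. = FALSE)
  if (age_lo >= age_hi) stop("age_lo must be less than age_hi", call. = FALSE)
  structure(list(age_lo = age_lo, mrr_lo = mrr_lo,
                 age_hi = age_hi, mrr_hi = mrr_hi),
            class = "mrr_profile")
}

#' Evaluate a mortality rate ratio profile at given ages
#'
#' @param profile an [mrr_profile()].
#' @param age ages in years (vectorized).
#' @return Mortality rate ratios; exact anchor values at the anchor ages,
#'   clamped outside the anchor interval.
#' @export
mrr_at <- function(profile, age) {
  stopifnot(inherits(profile, "mrr_profile"), is.numeric(age),
            all(is.finite(age)))
  a <- pmin(pmax(age, profile$age_lo), profile$age_hi)
  w <- (a - profile$age_lo) / (profile$age_hi - profile$age_lo)
  out <- exp((1 - w) * log(profile$mrr_lo) + w * log(profile$mrr_hi))
  out[w == 0] <- profile$mrr_lo       # anchors (and clamped tails) exact
  out[w == 1] <- profile$mrr_hi
  out
}

#' @export
print.mrr_profile <- function(x, ...) {
  cat(sprintf("Mortality rate ratio profile: %.3g at age %g -> %.3g at age %g (log-linear, clamped outside)\n",
              x$mrr_lo, x$age_lo, x$mrr_hi, x$age_hi))
  invisible(x)
}
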