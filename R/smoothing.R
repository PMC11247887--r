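#' Survey-weighted spline fit of one cross-sectional wave
#'
#' Stage one of the prevalence model: for each sex separately, the binary
#' disease indicator is regressed on age by maximum weighted Bernoulli
#' likelihood (a logistic model with the survey weights as case weights),
#' with a natural cubic spline in age with five equally spaced interior
#' knots over the configured age range. Integer recorded ages enter the
#' model at age + 0.5 (interval midpoint convention). The fit is returned as
#' logit-scale prevalence evaluated on the integer age grid.
#'
#' Point estimation with case weights matches the survey-weighted estimator;
#' design-based variance (strata/PSU linearization) is out of scope — the
#' pipeline's uncertainty comes from resampling the pooled surface.
#'
#' @param records survey data frame with columns `age`, `sex`,
#'   `survey_year`, `disease`, `weight` (see [generate_survey()] /
#'   [read_survey()]).
#' @param age_range integer age range covered by the fit (default 20--79).
#' @param n_knots number of equally spaced interior knots (default 5).
#' @return An object of class `wave_fit`: the survey year, a grid data frame
#'   (`age`, `sex`, `eta` = fitted logit prevalence), the knot locations and
#'   per-sex effective sample sizes (Kish).
#' @export
fit_wave <- function(records, age_range = c(20, 79), n_knots = 5) {
  .validate_survey(records)
  yr <- unique(records$survey_year)
  if (length(yr) != 1L)
    stop("fit_wave expects records from a single survey year; got ",
         paste(yr, collapse = ", "), call. = FALSE)
  lo <- age_range[1] + 0.5; hi <- age_range[2] + 0.5
  knots <- seq(lo, hi, length.out = n_knots + 2L)[-c(1L, n_knots + 2L)]
  ages_grid <- seq(age_range[1], age_range[2])
  sexes <- sort(unique(records$sex))
  out <- list(); half <- list(); n_eff <- numeric(0)
  for (s in sexes) {
    d <- records[records$sex == s, ]
    if (length(unique(d$age)) < 2L || length(unique(d$disease)) < 2L)
      stop("cannot fit wave ", yr, ", sex ", s,
           ": need >= 2 distinct ages and both outcome classes", call. = FALSE)
    a <- d$age + 0.5
    X <- splines::ns(a, knots = knots, Boundary.knots = c(lo, hi))
    fit <- stats::glm.fit(cbind(1, X), d$disease, weights = d$weight,
                          family = stats::quasibinomial())
    if (!fit$converged || any(!is.finite(fit$coefficients)))
      stop("stage-1 logistic fit failed to converge for wave ", yr,
           ", sex ", s, " (possible separation)", call. = FALSE)
    Xg <- cbind(1, splines::ns(ages_grid + 0.5, knots = knots,
                               Boundary.knots = c(lo, hi)))
    eta <- drop(Xg %*% fit$coefficients)
    if (any(!is.finite(eta)))
      stop("stage-1 fit gives non-finite logit prevalence for wave ", yr,
           ", sex ", s, call. = FALSE)
    # model-based variance of the fitted logit (weights as case weights);
    # normalized so the average weight is 1, which keeps the binomial
    # information scale while respecting relative survey weights
    # sandwich (robust) covariance of the weighted logistic coefficients:
    # with unequal survey weights the model-based information understates
    # the estimator's variance by the design effect, so the score-based
    # meat term uses squared weights
    wn <- d$weight / mean(d$weight)
    Xf <- cbind(1, X)
    mu <- stats::plogis(drop(Xf %*% fit$coefficients))
    Ainv <- chol2inv(chol(crossprod(Xf * sqrt(wn * mu * (1 - mu)))))
    meat <- crossprod(Xf * sqrt(wn^2 * mu * (1 - mu)))
    Vc <- Ainv %*% meat %*% Ainv
    Vc <- (Vc + t(Vc)) / 2
    # grid-level half-covariance: half %*% t(half) is the covariance of the
    # fitted logit curve across the age grid (rank = number of coefficients)
    half[[s]] <- Xg %*% t(chol(Vc))
    se <- sqrt(rowSums((Xg %*% Vc) * Xg))
    out[[s]] <- data.frame(age = ages_grid, sex = s, eta = eta, se = se)
    n_eff[s] <- sum(d$weight)^2 / sum(d$weight^2)
  }
  structure(list(survey_year = as.numeric(yr),
                 grid = do.call(rbind, out),
                 half = half,
                 knots = knots, boundary = c(lo, hi),
                 age_range = age_range, n_eff = n_eff),
            class = "wave_fit")
}

#' @export
print.wave_fit <- function(x, ...) {
  cat(sprintf("Wave fit, year %g: %d grid ages x %d sex(es); n_eff %s\n",
              x$survey_year, length(unique(x$grid$age)),
              length(unique(x$grid$sex)),
              paste(sprintf("%s=%.0f", names(x$n_eff), x$n_eff),
                    collapse = ", ")))
  invisible(x)
}

# cubic B-spline age basis without the redundant first column; the retained
# columns plus an explicit intercept span the full cubic spline space
.age_basis <- function(basis, age, deriv = 0L) {
  kseq <- c(rep(basis$boundary[1], 4), basis$knots, rep(basis$boundary[2], 4))
  B <- splines::splineDesign(kseq, age, ord = 4L,
                             derivs = rep(deriv, length(age)))
  if (deriv == 0L) cbind(1, B[, -1, drop = FALSE])
  else cbind(0, B[, -1, drop = FALSE])
}

# model matrix of the pooled surface: {age basis} x {1, centered year} x
# {1, sex indicator}, i.e. the full three-way interaction structure.
# d_age differentiates the age basis, d_year the year factor.
.surface_design <- function(basis, age, year, sex, d_age = 0L, d_year = 0L) {
  n <- max(length(age), length(year), length(sex))
  age <- rep_len(age, n); year <- rep_len(year, n); sex <- rep_len(sex, n)
  bad <- age < basis$age_domain[1] - 1e-9 | age > basis$age_domain[2] + 1e-9
  if (any(bad))
    stop("age ", age[which(bad)[1]], " outside the surface age domain [",
         basis$age_domain[1], ", ", basis$age_domain[2], "]", call. = FALSE)
  A <- .age_basis(basis, age, deriv = d_age)
  yc <- year - basis$year_center
  if (d_year == 0L) {
    fy <- yc; c1 <- 1
  } else if (d_year == 1L) {
    fy <- rep(1, n); c1 <- 0
  } else stop("d_year must be 0 or 1")
  if (length(basis$sex_levels) < 2L)        # single-sex surface: no sex blocks
    return(cbind(A * c1, A * fy))
  s01 <- as.numeric(sex == basis$sex_levels[2])
  cbind(A * c1, A * fy, A * (c1 * s01), A * (fy * s01))
}

#' Pool per-wave logit prevalences into one smooth surface
#'
#' Stage two of the prevalence model: the logit-scale prevalences fitted per
#' wave and sex are stacked into one data set and regressed (ordinary least
#' squares) on a cubic B-spline in age with three interior knots, a linear
#' term in survey year, a sex indicator, and all interactions up to age
#' \eqn{\times} year \eqn{\times} sex. The linear year term turns discrete
#' cross-sections into a surface differentiable in calendar time; the
#' three-way interaction lets both the age profile and its trend differ by
#' sex. Year is centered at the mid-study year for conditioning (predictions
#' are invariant to this).
#'
#' @param wave_fits list of [fit_wave()] results, one per survey year (at
#'   least two years).
#' @param n_knots number of interior age knots (default 3, placed at the
#'   25th/50th/75th percentiles of the stacked ages).
#' @param weights `"precision"` (default) weights each stacked point by the
#'   inverse variance of its stage-1 logit estimate, so that sparsely
#'   observed cells (very low prevalence at young ages, few respondents near
#'   the upper age boundary) do not dominate the surface; `"uniform"` or a
#'   numeric vector for alternatives.
#' @param covariance how the surface's coefficient covariance is formed.
#'   `"propagated"` (default) propagates the stage-1 fitted-curve
#'   covariances through the stage-2 projection exactly (stage 2 is linear
#'   in the stacked logits), capturing the survey sampling variability that
#'   drives the resampling intervals. `"ols"` uses the stage-2 regression's
#'   own residual-based covariance; because stage-1 noise is smooth in age
#'   and largely absorbed by the stage-2 basis, this variant sees only
#'   lack-of-fit and is far too narrow for inference — it is retained for
#'   comparison.
#' @return A `prevalence_surface`: coefficients, their covariance matrix,
#'   the basis description and the domain.
#' @seealso [predict_surface()], [directional_derivative()],
#'   [sample_surface()], [pool_logit_data()]
#' @export
pool_waves <- function(wave_fits, n_knots = 3, weights = "precision",
                       covariance = c("propagated", "ols")) {
  covariance <- match.arg(covariance)
  if (inherits(wave_fits, "wave_fit")) wave_fits <- list(wave_fits)
  stopifnot(all(vapply(wave_fits, inherits, logical(1), "wave_fit")))
  years <- vapply(wave_fits, `[[`, numeric(1), "survey_year")
  if (length(unique(years)) < 2L)
    stop("at least two survey years are required to pool waves",
         call. = FALSE)
  ar <- wave_fits[[1]]$age_range
  stacked <- do.call(rbind, lapply(wave_fits, function(w)
    data.frame(age = w$grid$age + 0.5, year = w$survey_year,
               sex = w$grid$sex, eta = w$grid$eta, se = w$grid$se)))
  w <- if (identical(weights, "precision")) 1 / stacked$se^2
       else if (identical(weights, "uniform")) NULL
       else weights
  surface <- pool_logit_data(stacked, n_knots = n_knots, weights = w,
                             age_domain = c(ar[1], ar[2] + 1),
                             keep_design = TRUE)
  if (covariance == "propagated") {
    # stage-2 coefficients are linear in the stacked stage-1 logits,
    # beta = H eta with H = (X'WX)^{-1} X'W, so the stage-1 curve
    # covariances (block-diagonal over wave x sex) propagate exactly:
    # Var(beta) = sum_blocks (H_block half_block)(H_block half_block)'
    X <- surface$design$X
    wv <- surface$design$w
    H <- surface$design$XtWX_inv %*% t(X * wv)
    V <- matrix(0, ncol(X), ncol(X))
    row0 <- 0L
    for (wf in wave_fits) {
      for (s in sort(names(wf$half))) {
        nb <- sum(wf$grid$sex == s)
        G <- H[, row0 + seq_len(nb), drop = FALSE] %*% wf$half[[s]]
        V <- V + tcrossprod(G)
        row0 <- row0 + nb
      }
    }
    surface$vcov <- (V + t(V)) / 2
  }
  surface$design <- NULL
  surface
}

#' Fit the pooled surface directly from logit-prevalence points
#'
#' The regression behind [pool_waves()], exposed so that exact (noise-free)
#' logit prevalences can be fed straight into the pipeline, separating
#' survey sampling noise from smoothing bias in validation studies.
#'
#' @param data data frame with columns `age` (continuous), `year`, `sex`,
#'   `eta` (logit prevalence).
#' @param n_knots interior age knots (default 3).
#' @param weights optional regression weights.
#' @param age_domain age interval the surface is defined on (also the
#'   B-spline boundary knots); default: range of the data.
#' @return A `prevalence_surface`.
#' @export
pool_logit_data <- function(data, n_knots = 3, weights = NULL,
                            age_domain = range(data$age),
                            keep_design = FALSE) {
  stopifnot(all(c("age", "year", "sex", "eta") %in% names(data)))
  years <- sort(unique(data$year))
  if (length(years) < 2L)
    stop("at least two survey years are required", call. = FALSE)
  sex_levels <- sort(unique(as.character(data$sex)))
  basis <- list(
    knots = as.numeric(stats::quantile(
      data$age, probs = seq_len(n_knots) / (n_knots + 1))),
    boundary = age_domain,
    age_domain = age_domain,
    year_center = mean(range(years)),
    sex_levels = sex_levels)
  X <- .surface_design(basis, data$age, data$year, as.character(data$sex))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("stage-2 design is rank deficient; aliased column(s): ",
         paste(qrX$pivot[(qrX$rank + 1):ncol(X)], collapse = ", "),
         call. = FALSE)
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights
  fit <- stats::lm.wfit(X, data$eta, w)
  beta <- unname(fit$coefficients)
  rss <- sum(w * fit$residuals^2)
  dfres <- nrow(X) - ncol(X)
  sigma2 <- if (dfres > 0) rss / dfres else 0
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  V <- sigma2 * XtWX_inv
  V <- (V + t(V)) / 2
  out <- list(coef = beta, vcov = V, basis = basis,
              years = years, sigma2 = sigma2, df_residual = dfres,
              year_domain = range(years))
  if (keep_design)
    out$design <- list(X = X, w = w, XtWX_inv = XtWX_inv)
  structure(out, class = "prevalence_surface")
}

#' @export
print.prevalence_surface <- function(x, ...) {
  cat(sprintf(
    "Smoothed prevalence surface: %d coefficients; ages [%g, %g], years %s; sexes: %s\n",
    length(x$coef), x$basis$age_domain[1], x$basis$age_domain[2],
    paste(x$years, collapse = "/"), paste(x$basis$sex_levels, collapse = ", ")))
  invisible(x)
}

#' Predict prevalence from a pooled surface
#'
#' @param surface a `prevalence_surface`.
#' @param age,year,sex evaluation points (recycled to a common length).
#' @param type `"response"` for prevalence in (0, 1), `"link"` for the logit.
#' @return Numeric vector of predictions.
#' @export
predict_surface <- function(surface, age, year, sex,
                            type = c("response", "link")) {
  type <- match.arg(type)
  X <- .surface_design(surface$basis, age, year, as.character(sex))
  eta <- drop(X %*% surface$coef)
  if (type == "link") eta else stats::plogis(eta)
}

#' Directional derivative of prevalence along birth cohorts
#'
#' The cohort-direction derivative \eqn{(\partial_a + \partial_t)p} required
#' by the incidence equation. The analytic form differentiates the linear
#' predictor exactly — the age part from the B-spline basis derivative, the
#' calendar part from the linear year terms — and applies the chain rule,
#' \eqn{p(1-p)(\partial_a \eta + \partial_t \eta)}. The finite-difference
#' form steps along the cohort diagonal, \eqn{[p(a+h, t+h) - p(a-h, t-h)]/2h},
#' switching to a one-sided step at the age-domain boundary; it exists as an
#' independent numerical check on the analytic derivative.
#'
#' @inheritParams predict_surface
#' @param method `"analytic"` (default) or `"finite_difference"`.
#' @param h step in years for the finite difference (default 0.1).
#' @return Prevalence change per year.
#' @export
directional_derivative <- function(surface, age, year, sex,
                                   method = c("analytic",
                                              "finite_difference"),
                                   h = 0.1) {
  method <- match.arg(method)
  n <- max(length(age), length(year), length(sex))
  age <- rep_len(age, n); year <- rep_len(year, n); sex <- rep_len(sex, n)
  if (method == "analytic") {
    Xa <- .surface_design(surface$basis, age, year, as.character(sex),
                          d_age = 1L)
    Xt <- .surface_design(surface$basis, age, year, as.character(sex),
                          d_year = 1L)
    eta <- drop(.surface_design(surface$basis, age, year,
                                as.character(sex)) %*% surface$coef)
    deta <- drop((Xa + Xt) %*% surface$coef)
    p <- stats::plogis(eta)
    p * (1 - p) * deta
  } else {
    dom <- surface$basis$age_domain
    up <- pmin(age + h, dom[2])
    dn <- pmax(age - h, dom[1])
    p_up <- predict_surface(surface, up, year + (up - age), sex)
    p_dn <- predict_surface(surface, dn, year - (age - dn), sex)
    (p_up - p_dn) / (up - dn)
  }
}

#' Draw one surface from the sampling distribution of the fit
#'
#' Returns a copy of the surface whose coefficient vector is a single
#' multivariate-normal draw centered at the estimates with the stored
#' coefficient covariance — the resampling primitive behind the pipeline's
#' percentile confidence intervals.
#'
#' @param surface a `prevalence_surface`.
#' @param seed optional integer; if supplied the draw is made with a private
#'   RNG stream seeded with it (same seed, same draw), otherwise the current
#'   RNG stream is advanced.
#' @return A `prevalence_surface` with perturbed coefficients and zero
#'   covariance.
#' @export
sample_surface <- function(surface, seed = NULL) {
  L <- .surface_chol(surface)
  draw <- function() {
    z <- stats::rnorm(ncol(L))
    out <- surface
    out$coef <- surface$coef + drop(crossprod(L, z))
    out$vcov <- matrix(0, length(out$coef), length(out$coef))
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# upper-triangular pivoted Cholesky factor of the coefficient covariance,
# unpivoted, cached on the surface object; PSD (rank-deficient) accepted
.surface_chol <- function(surface) {
  if (!is.null(surface$chol)) return(surface$chol)
  V <- surface$vcov
  if (is.null(V)) stop("surface carries no covariance", call. = FALSE)
  if (all(V == 0)) return(matrix(0, nrow(V), ncol(V)))
  R <- suppressWarnings(chol(V, pivot = TRUE))
  rk <- attr(R, "rank")
  piv <- attr(R, "pivot")
  if (rk < nrow(V)) R[(rk + 1):nrow(R), ] <- 0
  L <- matrix(0, nrow(V), ncol(V))
  L[, piv] <- R
  err <- max(abs(crossprod(L) - V))
  if (err > 1e-6 * max(1, max(abs(V))))
    stop("coefficient covariance is not positive semi-definite", call. = FALSE)
  L
}

.validate_survey <- function(records) {
  req <- c("age", "sex", "survey_year", "disease", "weight")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("survey records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  if (any(!records$disease %in% c(0L, 1L)))
    stop("disease must be a 0/1 indicator; first bad row: ",
         which(!records$disease %in% c(0L, 1L))[1], call. = FALSE)
  if (any(!is.finite(records$weight)) || any(records$weight <= 0))
    stop("weights must be positive; first bad row: ",
         which(!is.finite(records$weight) | records$weight <= 0)[1],
         call. = FALSE)
  invisible(records)
}
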