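---
title: "Estimating chronic-disease incidence from repeated prevalence surveys"
author: "idmrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating chronic-disease incidence from repeated prevalence surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idmrates)
```

## The model

`idmrates` estimates the age- and sex-specific incidence rate of an
irreversible chronic disease — diagnosed diabetes is the motivating case —
without any follow-up data. The three-state illness-death model (healthy →
diseased → dead, healthy → dead, no recovery) links the quantities that
repeated cross-sectional surveys *can* observe to the incidence rate they
cannot. Writing $p(a, t)$ for prevalence at age $a$ and calendar time $t$,
$m$ for the mortality rate of the general population, and $MRR$ for the
ratio of mortality among the diseased to mortality among the disease-free,
the governing partial differential equation can be solved for the incidence
rate $i$:

$$
i \;=\; \frac{(\partial_a + \partial_t)\,p}{1 - p}
\;+\; m\,\frac{p\,(MRR - 1)}{p\,(MRR - 1) + 1}.
$$

The derivative is taken along birth cohorts (simultaneously in age and
calendar time); estimating it requires age-specific prevalence from at
least two survey years. With four waves six years apart, incidence is
estimated midway between consecutive waves, where the linear-in-time
prevalence trend is most trustworthy.

Assumptions worth keeping in view: the disease is irreversible (no
remission transition); migration is ignored; the general-population
mortality schedule and the MRR profile are externally supplied inputs, not
estimated from the survey data.

## Two-stage prevalence smoothing

The incidence equation needs a prevalence surface that is smooth in age
*and* differentiable in calendar time. The package builds it in two
stages.

**Stage 1** (`fit_wave`): for each survey wave and sex separately, the
binary disease indicator is regressed on age by weighted maximum Bernoulli
likelihood — a logistic model with the survey weights as case weights — on
a natural cubic spline in age with five equally spaced interior knots over
the estimation range (ages 20–79; older ages are excluded because survey
samples there are too small to support the fit). Integer recorded ages are
interpreted as the interval $[a, a+1)$ and enter the model at $a + 0.5$,
which avoids a systematic half-year offset between the discrete records
and the continuous model. The fitted logit prevalence is evaluated on the
integer age grid, together with its sampling covariance. The coefficient
covariance uses the sandwich (design-robust) form: with unequal survey
weights the model-based information matrix understates the estimator's
variance by the design effect of the weights.

**Stage 2** (`pool_waves`): the per-wave logit prevalences are stacked and
regressed on a cubic B-spline in age with three interior knots (placed at
the quartiles of the stacked ages), a linear term in survey year, a sex
indicator, and all interactions up to age × year × sex, so both the age
profile and its time trend may differ by sex. Two choices here were
genuinely open and are worth recording:

* *Weighting.* Stage-2 points are weighted by the inverse variance of
  their stage-1 logit estimates (configurable; `weights = "uniform"`
  recovers plain least squares). At young ages the prevalence is a few per
  mille, so a single age cell may contain a handful of cases and its logit
  carries a standard error near 0.5; giving such cells the same influence
  as well-estimated cells is statistically indefensible.
* *Coefficient covariance.* Because stage 2 is linear in the stacked
  logits, the stage-1 sampling covariances propagate exactly into the
  stage-2 coefficients ($\beta = H\hat\eta$ gives
  $\mathrm{Var}(\beta) = H\Sigma H'$ with $\Sigma$ block-diagonal over
  wave × sex). This propagated covariance is the default. The alternative
  — the stage-2 regression's own residual-based covariance — is retained
  as an option but is unsuitable for inference here: stage-1 noise is
  smooth in age and almost entirely absorbed by the stage-2 basis, so the
  residuals see only lack of fit and the implied intervals collapse far
  below their nominal level. The coverage experiment in the validation
  suite (100 independent replications of the full pipeline) checks that
  the propagated form attains its nominal 95% level.

Year is centered at the mid-study year before fitting (pure conditioning;
predictions are invariant). The cohort-direction derivative
$(\partial_a + \partial_t)p = p(1-p)(\partial_a\eta + \partial_t\eta)$ is
analytic — the age part from the exact B-spline basis derivative, the
calendar part from the linear year terms — with a central finite-difference
fallback along the cohort diagonal (step 0.1 years) kept as an independent
numerical check; the two agree to $10^{-6}$ on random surfaces.

## Mortality and the MRR profile

General-population mortality is a grid of rates per person-year by age,
year and sex, interpolated bilinearly inside the grid and held constant
beyond its edges; lookup at a grid node returns the stored value exactly.

No representative MRR data exist for the target population, so the MRR is
specified by two anchors: plausible ranges 7.5–8.5 at age 30 and 2.5–3.0
at age 80, with $\log MRR$ linear in age between the anchors. Outside
30–80 the profile is clamped to the nearest anchor rather than
extrapolated — extending the log-line below age 30 would produce
implausibly large ratios at age 20. Each resampling repetition draws the
two anchors independently from uniform distributions over their ranges
(a common-quantile mode, drawing both anchors with the same rank, is
available as a sensitivity switch).

## Uncertainty by resampling

`resample` repeats the estimation (default 2,000 times): each repetition
draws one coefficient vector from the surface's sampling distribution and
one MRR profile, then evaluates the incidence equation at every (age,
year, sex) cell. Every derived quantity — the 10-year age-group rates
(each group evaluated at its midpoint age, e.g. 55 for ages 50–59), the
directly age-standardized rate, and the incidence rate ratios between
calendar years — is computed *within* each repetition and only then
summarized by its 2.5th, 50th and 97.5th percentiles (linear interpolation
between order statistics; R quantile type 7, pinned for reproducibility).
Computing ratios within repetitions carries the strong dependence between
years into the interval; forming them from the marginal bands would not.
The median is the reported point estimate; a plug-in curve (mean
coefficients, mid-range MRR anchors) is stored alongside.

Negative incidence estimates can arise when the fitted prevalence declines
faster along a cohort than excess mortality explains. They are returned as
computed and flagged, never truncated: truncation would bias the
percentile bands upward. Repetitions whose denominator-year summary is
non-positive are excluded from a ratio and counted (`n_excluded`).

The default standard population aggregates the synthetic population's own
age distribution into 10-year groups; any standard (e.g. a WHO standard)
can be supplied as a CSV with columns `age_lo,age_hi,weight`. Weights are
normalized before use. All rates are stored per person-year internally;
the ×1000 reporting scale is applied only in `report_table` and the
serialized outputs.

## The synthetic-data generator

Because the real survey microdata and vital statistics are external
downloads, validation runs entirely on a forward simulator that is itself
first-class, tested code. A `scenario_spec` fixes the true incidence
surface $i(a, t)$, disease-free mortality $m_0(a)$, the MRR profile, the
cohort boundary condition $p(a_0) = p_0$ (default $p(0) = 0$: the disease
is absent at birth), wave years and sampling design. Along a birth cohort
the model reduces to an ordinary differential equation,

$$
\frac{dp}{da} = (1 - p)\,\bigl[\,i(a, t_0 + a - a_0)
  - p\,m_0(a)\,(MRR(a) - 1)\,\bigr],
$$

integrated for all requested cohorts simultaneously with an adaptive
solver (`deSolve::lsoda`, absolute tolerance $10^{-10}$). Parameterizing
the simulator by *disease-free* mortality and deriving the
general-population mixture $m = m_0(1 + p(MRR-1))$ keeps simulator and
estimator mutually consistent: the estimator consumes exactly the $m$ the
equation expects.

The default scenario emulates the scale of a national repeated
cross-sectional health survey: four waves (2000, 2006, 2012, 2018) of
44,000 persons each, roughly half women; a Gaussian-in-age incidence
profile peaking at age 65 (peak 19 and 22 per 1,000 person-years for men
and women at the 2009 reference year) with log-linear calendar trends of
2.3%/year (men) and 4.0%/year (women); Gompertz disease-free mortality
$m_0 = 5\times10^{-5} e^{0.09a}$ with a 0.75 proportional hazard for
women; MRR anchors 8.0 and 2.75 (the midpoints of the plausible ranges);
a mildly declining adult age pyramid; and log-normal unit-mean survey
weights (log-sd 0.5) that are independent of disease status by default —
an informativeness knob exists to study weight-outcome dependence. These
magnitudes were chosen once, from the published scale of diabetes rates in
the emulated setting, and are not revisited.

What the simulator deliberately does *not* emulate: cluster/stratum
survey design (uncertainty is propagated through the fitted prevalence
distribution, not by design-based replication), non-response,
misclassification of self-report against biomarker status, type 1 vs
type 2 distinction, migration, and realistic national demography. Passing
validation therefore demonstrates the estimation chain is correct under
its own assumptions, not that those assumptions hold in any particular
survey.

## Numerical choices

* Characteristic integration: `lsoda`, `atol` $10^{-10}$, `rtol`
  $10^{-8}$; prevalence leaving $[0, 1)$ beyond tolerance aborts with the
  offending cohort named.
* Stage-1 knots: five equally spaced interior knots on the (midpoint
  shifted) age range; stage-2 B-spline: three interior knots at the
  quartiles, boundary knots at ages 20 and 80. "Knots" counts interior
  knots in both stages; both counts are arguments.
* Derivatives at the age-domain boundary are one-sided (the spline
  derivative is right/left-continuous there); the finite-difference
  fallback shortens its step rather than stepping outside the domain.
* Percentiles: linear interpolation between order statistics (type 7).
* Ages in files are integers meaning $[a, a+1)$, modeled at $a + 0.5$;
  the reporting grid (integer ages, group midpoints 25…75) addresses the
  continuous surface directly.
* Degenerate inputs: single-sex data drop the sex blocks from the stage-2
  design; a single-year mortality grid is treated as constant in time;
  rank deficiency in stage 2 is an error naming the aliased columns, not
  a silent drop.

## Validation problem sizes

The test suite validates each stage at sizes chosen to make Monte-Carlo
noise negligible relative to the tolerance being asserted: the
forward-then-invert identity on a 0.25-year cohort grid (relative error
$<10^{-4}$); the constant-incidence closed form $p = 1 - e^{-c(a-a_0)}$
(absolute error $<10^{-8}$); smoother recovery of an in-model-span
surface with four waves of 100,000; end-to-end recovery of the true
age-standardized rate on the default scenario (four waves × 44,000,
500 repetitions); and interval coverage over 100 independent replications
of the full pipeline (20,000 per wave, 200 repetitions each). The same
quantities are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

Point-estimation honors survey weights, but variances carry no
stratum/PSU design correction — in strongly clustered designs the
intervals will be anti-conservative. The incidence estimate inherits any
trend in diagnosis behaviour: a rising diagnosed fraction is
indistinguishable from rising incidence using cross-sectional prevalence
alone. Near the age boundaries the stage-2 surface is supported by less
data and single-cohort noise; group rates at ages 20–29 and 70–79 are
visibly the least stable, matching the wide intervals typical of this
method. The two-stage smoother is a smoothing device, not a generative
model: its span restriction is what turns four cross-sections into a
differentiable surface, and misspecification of that span is a source of
bias the resampling bands do not see.
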