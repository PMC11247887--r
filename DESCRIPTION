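Package: idmrates
Title: Incidence Rates from Repeated Prevalence Surveys via the Illness-Death Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age- and sex-specific incidence rates of an irreversible
    chronic disease (such as diagnosed diabetes) from repeated cross-sectional
    prevalence surveys, general-population mortality rates and a mortality rate
    ratio profile, using the partial differential equation that governs the
    illness-death model. Provides survey-weighted two-stage spline smoothing of
    prevalence on the logit scale, analytic directional derivatives along birth
    cohorts, resampling-based percentile confidence intervals, direct age
    standardization, incidence rate ratios between calendar years, and a forward
    illness-death simulator that generates synthetic survey microdata and
    mortality schedules for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
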