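# Pipeline defaults: four survey waves six years apart, estimation at the
# midpoint years, 2000 resampling repetitions, MRR anchors drawn uniformly
# from their plausible ranges. Rates are per person-year internally and
# per 1000 person-years in reports.
wave_years: [2000, 2006, 2012, 2018]
n_per_wave: 44000
age_range: [20, 79]
mrr_lo_range: [7.5, 8.5]
mrr_hi_range: [2.5, 3.0]
repetitions: 2000
seed: 1
# "scenario" derives 10-year-group weights from the synthetic population's
# age distribution; otherwise a path to a standard-population CSV
standard_population: scenario
derivative_method: analytic
output_dir: idmrates_output
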