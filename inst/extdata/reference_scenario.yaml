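# Reference scenario: every tunable of the evaluation in one place.
# Cohort totals and stratum prevalences are read from the packaged
# cohort_prevalence_{women,men}.tsv tables.
demography:
  max_age: 105
  life_tables:
    women: {makeham_a: 3.0e-4, gompertz_b: 1.2e-3, gompertz_c: 0.115}
    men: {makeham_a: 7.0e-4, gompertz_b: 2.0e-3, gompertz_c: 0.110}
risk:
  hip_anchors:
    # annual hip-fracture probability at 50, doubling every few years of age
    women: {rate_at_50: 3.0e-4, doubling_time: 6.0, anchor_ages: [50, 60, 70, 80, 90]}
    men: {rate_at_50: 2.0e-4, doubling_time: 7.0, anchor_ages: [50, 60, 70, 80, 90]}
  ratio_bands:
    # site-to-hip incidence ratios by age band (50-64, 65-74, 75+)
    band_start: [50, 65, 75]
    vertebral: [3.0, 1.8, 1.1]
    wrist: [4.5, 1.8, 0.6]
    other: [4.0, 2.0, 1.2]
  prior_fx_rr: {hip: 2.3, vertebral: 4.4, wrist: 3.3, other: 1.9}
  osteoporosis_rr: 2.0
  prevalent_fracture_rr: 2.0
  efficacy_rr: {hip: 0.82, vertebral: 0.87, wrist: 0.80, other: 0.80}
  pf_history_split: {hip: 0.5, vertebral: 0.5}
economics:
  hip_cost_anchors:
    ages: [50, 60, 70, 80, 90]
    costs: [8000.0, 9177.4, 10288.7, 11349.0, 12368.5]
  hip_extra_first_year: 12000
  nonhip_relative: {vertebral: 0.25, wrist: 0.12, other: 0.20}
  supplement_annual_price: 250
  discount_rate_costs: 0.03
  discount_rate_effects: 0.03
  cost_curve_family: power
  hip_longterm_annual: 0
run:
  prices: [150, 250, 350]
  fracture_prob_cap: 0.999
  excess_mort_multiplier: 5.5
  excess_attributable_fraction: 1.0
  headline_discounted: true
  seed: 1
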