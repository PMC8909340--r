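# Published model inputs, transcribed from the source tables (2020 USD).
# Age schedules are annual probabilities; bands are closed below, open above,
# terminal band open-ended. Relative risks are per `per_increment` ug/m3 of
# PM2.5 with 95% confidence bounds.
settings:
  start_age: 40
  horizon: 60
  cycle_length: 1
  cost_discount: 0.05
  qaly_discount: 0.0
  half_cycle_correction: false
  cohort_size: 10000
  convert_rates: false
scenarios:
  standard:
    label: standard
    concentration: 15.0
    reference_concentration: 15.0
  increased:
    label: increased
    concentration: 25.0
    reference_concentration: 15.0
diseases:
  lung_cancer:
    incidence:
      age_lower: [40, 50, 60, 70]
      value: [0.0001, 0.0003, 0.0007, 0.0014]
    mortality:
      age_lower: [40]
      value: [0.2109]
    rr_incidence: {point: 1.42, ci_low: 1.02, ci_high: 1.98, per_increment: 10}
    rr_mortality: {point: 1.27, ci_low: 1.03, ci_high: 1.56, per_increment: 10}
  mi:
    incidence:
      age_lower: [40, 50, 60, 70, 80]
      value: [0.0004, 0.0013, 0.0033, 0.006, 0.0085]
    mortality:
      age_lower: [40, 50, 60, 70, 80]
      value: [0.0168, 0.0324, 0.0618, 0.1152, 0.2076]
    rr_incidence: {point: 1.22, ci_low: 1.04, ci_high: 1.44, per_increment: 10}
    rr_mortality: {point: 1.20, ci_low: 1.02, ci_high: 1.41, per_increment: 10}
  stroke:
    incidence:
      age_lower: [40, 50, 60, 70, 80]
      value: [0.0011, 0.0029, 0.0076, 0.0158, 0.025]
    mortality:
      age_lower: [40, 50, 60, 70, 80]
      value: [0.0046, 0.0112, 0.0263, 0.0604, 0.1295]
    rr_incidence: {point: 1.28, ci_low: 1.02, ci_high: 1.61, per_increment: 10}
    rr_mortality: {point: 1.34, ci_low: 0.94, ci_high: 1.91, per_increment: 10}
  copd:
    incidence:
      age_lower: [40, 50, 60, 70]
      value: [0.008, 0.024, 0.114, 0.136]
    mortality:
      # listed only for ages 75 and 85 in the source; zero before 70
      age_lower: [40, 70, 80]
      value: [0.0, 0.0002, 0.0009]
    rr_incidence: {point: 1.08, ci_low: 1.04, ci_high: 1.11, per_increment: 10}
    rr_mortality: {point: 1.169, ci_low: 1.136, ci_high: 1.203, per_increment: 10}
rewards:
  state_costs:
    event_free: 0
    lc_y1: 19495
    lc_later: 6180
    mi_y1: 7026
    mi_post: 1156
    stroke_y1: 7260
    stroke_post: 941
    copd: 809
  death_costs:
    dead_lc: 17089
    dead_chd: 1494
    dead_cvd: 2062
    dead_copd: 2577
    dead_other: 0
  state_utilities:
    lc_y1: 0.61
    lc_later: 0.50
    mi_y1: 0.71
    mi_post: 0.75
    stroke_y1: 0.63
    stroke_post: 0.72
    copd: 0.8
  baseline_utility:
    # declining event-free utility template by decade of age; the absolute
    # level is set by the QALY calibration (utility_scale)
    age_lower: [40, 50, 60, 70, 80]
    value: [0.96, 0.94, 0.92, 0.88, 0.82]
background:
  mode: gompertz_makeham
  makeham_c: 0.0005
  gompertz_a: null   # derived from calibration.lifetable_le when null
  gompertz_b: 0.09
  calibration_scale: 1.0
  utility_scale: 1.0
  includes_modelled_causes: true
  table: null
calibration:
  scenario: standard
  target_ly: 41.34
  target_qaly: 32.08
  lifetable_le: 47.3
psa:
  utility_cv: 0.1
  cost_cv: 0.2
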