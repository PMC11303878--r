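# Default model inputs: four-arm hypertension-care cost-effectiveness model,
# rural Kenya. Costs in 2020 US$ per person; risks in QRISK3 percent;
# disability weights dimensionless annual decrements.
arms:
  usual_care:
    year1_cost: 87
    subsequent_year_cost: 67
    qrisk_change_population: 0.0
    qrisk_change_men: 0.0
    qrisk_change_women: 0.0
  group_medical_visits:
    year1_cost: 99
    subsequent_year_cost: 71
    qrisk_change_population: -0.33
    qrisk_change_men: 0.40
    qrisk_change_women: -0.60
  microfinance:
    year1_cost: 120
    subsequent_year_cost: 67
    qrisk_change_population: -0.41
    qrisk_change_men: -0.12
    qrisk_change_women: -0.52
  gmv_mf:
    year1_cost: 139
    subsequent_year_cost: 72
    qrisk_change_population: -0.93
    qrisk_change_men: -0.70
    qrisk_change_women: -1.00
clinical_costs:
  htn_management: 68
  chronic_cvd_management: 125
  mi_hospitalisation: 1996
  stroke_hospitalisation: 1874
disability_weights:
  no_cvd: 0.06
  chronic_one_mi: 0.08
  chronic_one_stroke: 0.14
  chronic_two_mi: 0.17
  chronic_two_stroke: 0.49
  chronic_mi_and_stroke: 0.33
  acute_mi_disutility: 0.01
  acute_stroke_disutility: 0.01
hazard_ratios:
  mi_after_mi: 1.42
  stroke_after_stroke: 2.89
  mi_after_stroke: 1.00
  stroke_after_mi: 1.00
  mi_after_both: 1.95
  stroke_after_both: 3.13
  fatal_mi_after_mi: 1.22
  fatal_mi_after_stroke: 1.00
  fatal_stroke_after_mi: 1.22
  fatal_stroke_after_stroke: 1.00
  allcause_after_event: 1.00
life_table:
  # annual all-cause mortality probability by age band; the 70-74 band is
  # zero in the source life table (flagged at load time, see ?read_cea_parameters)
  - lower: 60
    upper: 64
    prob: 0.02
  - lower: 65
    upper: 69
    prob: 0.03
  - lower: 70
    upper: 74
    prob: 0.0
  - lower: 75
    upper: 79
    prob: 0.07
  - lower: 80
    upper: 84
    prob: 0.11
  - lower: 85
    upper: .inf
    prob: 0.20
epi:
  stroke_fraction: 0.60
  fatal_mi_fraction: 0.45
  fatal_stroke_fraction: 0.45
  baseline_qrisk_population: 11.5
  baseline_qrisk_men: 11.9
  baseline_qrisk_women: 11.3
settings:
  start_age: 61
  horizon: 10
  discount_rate: 0.03
  half_cycle_correction: true
  cycle0_accrual: true
  fatal_event_accrual: false
  recurrent_intervention_costs: false
  stratum: population
  wtp: 3360
  wtp_grid: [0, 250, 500, 750, 1000, 1250, 1500, 1750, 2000, 2500, 3000,
             3500, 4000, 4500, 5000, 6000, 7000, 8000, 9000, 10000]
# one-way deterministic sensitivity ranges (low, high); parameters without a
# published range (baseline risk, mortality, sex-stratified effects) are absent
dsa_ranges:
  qrisk_change_microfinance: [-1.4, 0.5]
  qrisk_change_group_medical_visits: [-4.4, 0.7]
  qrisk_change_gmv_mf: [-4.9, 0.0]
  cost_usual_care: [78.3, 95.7]
  cost_microfinance: [108.0, 132.0]
  cost_group_medical_visits: [89.1, 108.9]
  cost_gmv_mf: [125.1, 152.9]
  cost_htn_management: [61.2, 74.8]
  cost_chronic_cvd_management: [112.5, 137.5]
  cost_mi_hospitalisation: [1796.4, 2195.6]
  cost_stroke_hospitalisation: [1686.6, 2061.4]
  dw_no_cvd: [0.054, 0.066]
  dw_chronic_one_mi: [0.072, 0.088]
  dw_chronic_one_stroke: [0.126, 0.154]
  dw_chronic_two_mi: [0.153, 0.187]
  dw_chronic_two_stroke: [0.441, 0.539]
  dw_chronic_mi_and_stroke: [0.297, 0.363]
  dw_acute_mi_disutility: [0.009, 0.011]
  dw_acute_stroke_disutility: [0.009, 0.011]
  hr_mi_after_mi: [1.20, 1.69]
  hr_stroke_after_stroke: [2.37, 3.53]
  hr_mi_after_stroke: [1.00, 1.32]
  hr_stroke_after_mi: [1.00, 1.23]
  hr_mi_after_both: [1.37, 2.80]
  hr_stroke_after_both: [2.22, 4.43]
  hr_fatal_mi_after_mi: [1.00, 1.43]
  hr_fatal_mi_after_stroke: [1.03, 1.43]
  hr_fatal_stroke_after_mi: [1.00, 1.35]
  hr_fatal_stroke_after_stroke: [1.00, 1.35]
  hr_allcause_after_event: [1.00, 1.50]
  stroke_fraction: [0.5, 0.7]
  fatal_mi_fraction: [0.405, 0.495]
  fatal_stroke_fraction: [0.405, 0.495]
  discount_rate: [0.00, 0.07]
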