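# Base-case model configuration: adjuvant olaparib vs no olaparib for
# gBRCAm early breast cancer. Money in 2021 US dollars, times in months,
# ages in years.
scenario: base_case
life_table: bundled            # packaged synthetic 2018 US female table
starting_age: 42               # trial median; scenarios use 50 and 60
horizon_age: 110
annual_discount_rate: 0.03
treatment_duration: 12
imaging_fraction: 0.535        # fraction with >= 1 breast (annual imaging)

costs:
  monthly_drug_cost: 14523
  oncologist_visit_cost: 867
  imaging_cost: 540            # diagnostic mammogram + breast MRI
  monthly_metastatic_cost: 23599

utilities:
  utility_no_recurrence: 0.98
  utility_metastatic: 0.55
  olaparib_utility_multiplier: 0.9

transitions:
  hazard_ratio: {point: 0.61, ci_low: 0.48, ci_high: 0.77}
  annual_prob_y5_9: 0.0156     # not varied in sensitivity analysis
  annual_prob_y10p: 0.0078     # not varied in sensitivity analysis
  monthly_metastatic_death_rate: 0.052   # from 13.3-month median survival

targets:                       # trial DDFS/OS at months 12/24/36/48
  placebo:
    ddfs: [0.903, 0.840, 0.810, 0.791]
    os:   [0.969, 0.928, 0.891, 0.864]
  olaparib:
    ddfs: [0.944, 0.906, 0.880, 0.865]
    os:   [0.980, 0.950, 0.928, 0.898]

sensitivity:
  n_draws: 10000
  seed: 1
  wtp_max: 300000
  wtp_step: 5000
  ranges:
    - {parameter: utility_no_recurrence, base: 0.98, low: 0.735, high: 1, distribution: beta}
    - {parameter: utility_metastatic, base: 0.55, low: 0.413, high: 0.688, distribution: beta}
    - {parameter: olaparib_utility_multiplier, base: 0.9, low: 0.80, high: 1, distribution: beta_scaled}
    - {parameter: monthly_drug_cost, base: 14523, low: 10892, high: 18154, distribution: gamma}
    - {parameter: oncologist_visit_cost, base: 867, low: 650, high: 1084, distribution: gamma}
    - {parameter: imaging_cost, base: 540, low: 405, high: 675, distribution: gamma}
    - {parameter: monthly_metastatic_cost, base: 23599, low: 17699, high: 29499, distribution: gamma}
    - {parameter: hazard_ratio, base: 0.61, low: 0.48, high: 0.77, distribution: lognormal}
    - {parameter: monthly_metastatic_death_rate, base: 0.052, low: 0.039, high: 0.065, distribution: beta}
    - {parameter: annual_discount_rate, base: 0.03, low: 0.0225, high: 0.0375}
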