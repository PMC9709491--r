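# Default model inputs for the early-stage Dupuytren's disease (DD)
# microsimulation of intranodular adalimumab versus standard care.
#
# Provenance tags:
#   trial_estimate        - regression / bootstrap estimate on trial data
#                           (69-70 participants per arm, 18-month follow-up)
#   structural_assumption - structural modelling assumption
#   trial_costing         - unit cost applied in the trial costing
#   placeholder_literature- not reported in the primary source; synthetic
#                           placeholder shipped in late_stage_defaults.yaml
#
# `ci` entries are 95% intervals (bootstrap percentiles for trial estimates)
# and drive both probabilistic sampling and one-way sensitivity ranges.
# `dist` names the sampling family used in probabilistic sensitivity
# analysis; omitted or `fixed` means the value is not sampled.

# 18-month outcome probabilities (three-category: late-stage / quiescent /
# still-progressive). Sampled jointly per arm from a Dirichlet whose
# concentration is matched to the printed interval widths.
p_late_placebo:
  value: 0.2149
  ci: [0.1286, 0.3143]
  dist: dirichlet
  provenance: trial_estimate
p_quiescent_placebo:
  value: 0.2209
  ci: [0.1286, 0.3429]
  dist: dirichlet
  provenance: trial_estimate
p_late_ada:
  value: 0.1800
  ci: [0.1000, 0.2857]
  dist: dirichlet
  provenance: trial_estimate
p_quiescent_ada:
  value: 0.3696
  ci: [0.2571, 0.4857]
  dist: dirichlet
  provenance: trial_estimate

# Linear regression predicting QALYs accrued between 6 and 18 months.
qaly_gain_quiescence:
  value: 0.0395
  ci: [0.0079, 0.0704]
  dist: normal
  provenance: trial_estimate
qaly_reg_baseline_utility_coef:
  value: 0.5410
  ci: [0.4015, 0.6887]
  dist: normal
  provenance: trial_estimate
qaly_reg_constant:
  value: 0.3847
  ci: [0.2581, 0.5161]
  dist: normal
  provenance: trial_estimate

# Linear regression predicting the 18-month change in flexion deformity
# among untreated (placebo-arm) patients, degrees.
fd_change_constant:
  value: 0.8631
  ci: [-2.0005, 4.1074]
  dist: normal
  provenance: trial_estimate
fd_change_ectopic_coef:
  value: 8.5189
  ci: [2.1683, 15.3596]
  dist: normal
  provenance: trial_estimate
fd_change_rmse:
  value: 12.6079
  dist: fixed
  provenance: trial_estimate

# Structural assumptions.
quiescence_duration:
  value: 3.0
  ci: [1.5, 5.0]
  dist: uniform
  provenance: structural_assumption
cycle_length:
  value: 0.5
  provenance: structural_assumption
horizon:
  value: 55
  provenance: structural_assumption
trial_period:
  value: 1.5
  provenance: structural_assumption
discount_rate:
  value: 0.035
  provenance: structural_assumption
late_stage_threshold:
  value: 30
  provenance: structural_assumption

# Treatment costing (2018-19 GBP).
cost_per_dose:
  value: 475
  provenance: trial_costing
doses_per_course:
  value: 4
  provenance: trial_costing

# Mean non-intervention NHS cost accrued per patient over the 18-month
# trial period (GBP; occasional GP visits, physiotherapy and early surgery).
trial_other_cost:
  value: 307
  ci: [134, 514]
  dist: gamma
  provenance: trial_estimate

# Value-of-information population scaling and willingness-to-pay grid.
uk_prevalent_cases:
  value: 2584411
  provenance: trial_estimate
wtp_grid:
  value: [0, 5000, 10000, 15000, 20000, 25000, 30000, 35000, 40000, 45000, 50000]
  provenance: structural_assumption
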