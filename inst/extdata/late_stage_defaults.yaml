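# SYNTHETIC PLACEHOLDER inputs for the late-stage surgical pathway and
# mortality. None of these values are reported in the primary trial source;
# they stand in for literature-derived inputs (late-stage Markov transition
# evidence and a population data-linkage mortality study) that are not
# publicly printed. Every value is an ordinary editable input, tagged
# placeholder_literature, and was calibrated once so that the base-case
# standard-care arm reproduces a plausible lifetime surgical workload
# (about 1.4 operations per patient) and life expectancy (about 22.6 years
# from randomization). Replace with study-specific estimates when available.

late_stage_params:
  # Probability that an eligible late-stage patient elects surgery in a
  # six-month cycle.
  p_elect_surgery:
    value: 0.25
    ci: [0.15, 0.35]
    dist: beta
    provenance: placeholder_literature
  # Probability that a percutaneous needle fasciotomy (PNF) initially
  # succeeds (post-operative flexion deformity <= 5 degrees).
  p_pnf_success:
    value: 0.80
    ci: [0.65, 0.90]
    dist: beta
    provenance: placeholder_literature
  # Per-cycle relapse probabilities after an initially successful procedure.
  p_relapse_pnf:
    value: 0.032
    ci: [0.020, 0.050]
    dist: beta
    provenance: placeholder_literature
  p_relapse_fasciectomy:
    value: 0.014
    ci: [0.007, 0.025]
    dist: beta
    provenance: placeholder_literature
  p_relapse_dermofasciectomy:
    value: 0.006
    ci: [0.003, 0.011]
    dist: beta
    provenance: placeholder_literature
  # Procedure costs (2018-19 GBP), inclusive of associated outpatient and
  # physiotherapy visits.
  cost_pnf:
    value: 1200
    ci: [900, 1550]
    dist: gamma
    provenance: placeholder_literature
  cost_fasciectomy:
    value: 2600
    ci: [2000, 3300]
    dist: gamma
    provenance: placeholder_literature
  cost_dermofasciectomy:
    value: 3600
    ci: [2800, 4500]
    dist: gamma
    provenance: placeholder_literature
  # Annualized EQ-5D utility decrements relative to progressive early-stage
  # disease, by late-stage state.
  disutility_untreated:
    value: 0.10
    ci: [0.06, 0.15]
    dist: beta
    provenance: placeholder_literature
  disutility_pnf_success:
    value: 0.035
    ci: [0.018, 0.060]
    dist: beta
    provenance: placeholder_literature
  disutility_pnf_failed:
    value: 0.085
    ci: [0.050, 0.130]
    dist: beta
    provenance: placeholder_literature
  disutility_fasciectomy:
    value: 0.045
    ci: [0.018, 0.072]
    dist: beta
    provenance: placeholder_literature
  disutility_dermofasciectomy:
    value: 0.050
    ci: [0.025, 0.075]
    dist: beta
    provenance: placeholder_literature

mortality_params:
  # Synthetic Gompertz life table approximating UK adult mortality:
  # annual hazard h(age) = a_sex * exp(b * age). A user-supplied life-table
  # CSV (columns age, sex, hazard) overrides the Gompertz form.
  gompertz_a_male:
    value: 2.17e-05
    provenance: placeholder_literature
  gompertz_a_female:
    value: 1.22e-05
    provenance: placeholder_literature
  gompertz_b:
    value: 0.097
    provenance: placeholder_literature
  max_age:
    value: 110
    provenance: placeholder_literature
  # All-cause mortality hazard ratio for patients with Dupuytren's disease
  # relative to the general population (applies in every disease state).
  hazard_ratio:
    value: 1.10
    ci: [1.00, 1.25]
    dist: lognormal
    provenance: placeholder_literature
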