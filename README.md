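# dupasim

Health-economic evaluation of intranodular adalimumab (an anti-TNF
biologic) versus standard care for **progressive early-stage Dupuytren's
disease (DD)**, from a UK NHS perspective.

Early-stage DD presents as palmar nodules that may stay quiescent or
progress to the cords and finger contractures (flexion deformity, FD) of
late-stage disease, which is treated surgically. A course of four
intranodular adalimumab injections (£475 per dose including
administration) can induce nodule quiescence. Whether that is worth
paying for depends on events far beyond an 18-month trial: delayed
late-stage disease, avoided operations, and quality-of-life gains over a
lifetime. `dupasim` implements:

- a **patient-level discrete-time simulation** (6-month cycles, 55-year
  horizon): each patient's 18-month outcome (quiescent / still
  progressive / late-stage) is sampled per treatment arm; progressive
  patients follow a stochastic FD random walk calibrated to a linear
  regression of 18-month FD change (constant 0.8631°, ectopic-disease
  coefficient 8.5189°, residual SD 12.6079°); FD > 30° defines permanent
  late-stage disease with a surgical pathway (up to three percutaneous
  needle fasciotomies, at most one limited fasciectomy, at most one
  dermofasciectomy); Gompertz mortality with a DD hazard ratio applies in
  every state;
- three strategies: **standard care**, **one course of adalimumab**, and
  **repeated courses** (retreatment each time the nodule reactivates, in
  patients quiescent after the initial course);
- discounted (3.5%/year beyond the 18-month trial period) cost and QALY
  accrual, incremental cost-effectiveness analysis with dominance and
  extended dominance on the efficiency frontier;
- **probabilistic sensitivity analysis** (Dirichlet outcome
  probabilities, Normal regression coefficients, Uniform quiescence
  duration), cost-effectiveness acceptability curves, per-patient and
  population **EVPI/EVPPI** (single-loop GAM regression estimator), and
  one-way (tornado) sensitivity analysis;
- a **within-trial bootstrap cost-utility analysis** (12-month QALYs by
  trapezoidal area under the EQ-5D-5L curve, OLS adjustment for site, age
  and baseline utility, within-arm bootstrap) on a synthetic trial
  dataset calibrated to the reported trial marginals.

No individual-patient trial data are public: the package ships a
synthetic cohort generator and a synthetic trial-data generator, plus a
clearly labelled placeholder configuration
(`inst/extdata/late_stage_defaults.yaml`) for the late-stage and
mortality inputs that the primary source draws from supplementary
material and cited literature. Every input is an editable YAML value with
a provenance tag.

## Worked example

```r
library(dupasim)
params <- load_parameters()                       # packaged defaults
cohort <- generate_cohort(cohort_spec(), seed = 1)  # 69 synthetic patients
res <- simulate_strategies(cohort, params, n_reps = 200, seed = 2)
res[, c("strategy", "qaly_total", "cost_total", "early_years",
        "courses", "operations")]
#>            strategy qaly_total cost_total early_years courses operations
#> 1     standard_care      12.70       1943       7.683   0.000      1.566
#> 2   adalimumab_once      12.74       3762       8.304   1.000      1.516
#> 3 adalimumab_repeat      13.02       6171      12.538   3.364      1.037

incremental_analysis(data.frame(strategy = res$strategy,
                                cost = res$cost_total,
                                qaly = res$qaly_total))
#>            strategy cost  qaly dominated extended_dominated icer_frontier icer_vs_ref
#> 1     standard_care 1943 12.70     FALSE              FALSE            NA          NA
#> 2   adalimumab_once 3762 12.74     FALSE               TRUE            NA       38456
#> 3 adalimumab_repeat 6171 13.02     FALSE              FALSE         12980       12980
```

Reading the output: relative to standard care, repeated courses keep
patients free of late-stage disease for ~4.8 extra years, avert ~0.5
operations, and cost ~£4,200 more (mostly 3.4 courses of injections),
buying QALYs at ~£13,000 each — under the £20,000/QALY threshold the UK
NHS conventionally applies. The single-course strategy is
extended-dominated: a mix of the other two strategies delivers its QALYs
more cheaply. The full probabilistic pipeline (acceptability curves,
EVPI/EVPPI, tornado) runs through one call:

```r
bundle <- run_base_case(scale = "desk", seed = 1)   # 200 draws x 20 reps
bundle$ceac; bundle$evpi; bundle$tornado
```

The within-trial analysis on synthetic trial data:

```r
print(run_within_trial(seed = 1, n_boot = 1000))
#> <dd_cua_result>
#>   adjusted QALY difference: 0.0034 (95% CI -0.0054 to 0.0119)
#>   adjusted cost difference: 1979 (95% CI 1864 to 2091) GBP
#>   ICER: 579,494 GBP/QALY
#>   P(cost-effective at 20,000 GBP/QALY): 0.00
```

Over a 12-month horizon the drug cost dominates a tiny QALY gain —
adalimumab only becomes good value once lifetime progression is
modelled.

## Package layout

| Area | Functions |
|---|---|
| Parameters | `load_parameters`, `validate_parameters`, `sample_psa`, `realize_draw` |
| Synthetic cohort | `cohort_spec`, `generate_cohort`, `assign_initial_outcomes` |
| Engine | `simulate_patient`, `progress_flexion`, `next_surgical_event`, `cycle_mortality_prob`, `life_expectancy` |
| Economics | `discount_factor`, `cycle_utility`, `accrue`, `simulate_strategies`, `incremental_analysis` |
| PSA / value of information | `run_psa`, `ceac`, `evpi_per_patient`, `evppi`, `population_value`, `one_way_sa` |
| Within-trial CUA | `trial_spec`, `generate_trial_dataset`, `qalys_auc`, `adjusted_difference`, `bootstrap_cua` |
| Orchestration | `run_base_case`, `run_within_trial`, `write_report_bundle` |

See the methods vignette (`vignettes/lifetime-model.Rmd`) for the model's
assumptions, parameterization and limitations.
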