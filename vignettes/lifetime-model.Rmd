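---
title: "A lifetime patient-level model of anti-TNF treatment for early-stage Dupuytren's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime patient-level model of anti-TNF treatment for early-stage Dupuytren's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupasim)
```

## The decision problem

Early-stage Dupuytren's disease (DD) — palmar nodules with a clear
history of progression but an extensor deficit of at most 30° — has no
approved treatment; patients are observed until contractures justify
surgery. Intranodular adalimumab injections can soften and shrink
nodules, i.e. induce *quiescence*. Because DD progresses over decades,
the value of treating early can only be judged by extrapolation: this
package simulates individual patients in six-month cycles from
randomization to death or a 55-year horizon, under three strategies —
standard care, one course of four injections, and repeated courses on
each nodule reactivation in patients who were quiescent after the first
course.

## Model structure

Each simulated patient carries age, sex, baseline EQ-5D utility,
baseline flexion deformity (FD, ≤ 30° by the inclusion criterion) and an
ectopic-disease flag. The first 18 months (the trial period) are
accrued analytically: everyone survives, holds early-stage disease, and
accrues utility from the QALY regression below; treated strategies incur
one course cost (doses_per_course × cost_per_dose = 4 × £475). At the
end of the trial period each patient occupies the arm-specific 18-month
outcome:

* **quiescent** — FD frozen for `quiescence_duration` (base case 3
  years). At reactivation, standard-care and single-course patients
  resume progression; under the repeat strategy a new course is given in
  the same cycle (patients are assumed to seek retreatment as soon as
  the nodule reactivates), so quiescence continues indefinitely.
* **progressive** — FD follows a Gaussian random walk (below) and the
  patient enters untreated late-stage disease permanently once
  FD > 30°.
* **late-stage** — enters the untreated late-stage state directly.

Late-stage patients may elect surgery each cycle (probability
`p_elect_surgery`). The pathway allows up to three percutaneous needle
fasciotomies (PNF), at most one limited fasciectomy and at most one
dermofasciectomy. A PNF "succeeds" if post-operative FD ≤ 5°
(probability `p_pnf_success`) and may later relapse; a failed PNF rules
out further PNF, so the next elected procedure is the fasciectomy;
a relapsed fasciectomy leads to dermofasciectomy; once options are
exhausted the patient receives best supportive care. Mortality applies
in every state through a Gompertz hazard multiplied by a DD hazard
ratio, independent of disease stage and treatment — so simulated life
years are identical across strategies under common random numbers, a
property the test suite asserts.

## Parameters

Trial-estimated inputs (point estimate, 95% interval) ship in
`inst/extdata/default_params.yaml`: the four 18-month outcome
probabilities per arm; a regression predicting QALYs between months 6
and 18 (constant 0.3847, baseline-utility coefficient 0.5410,
quiescence gain 0.0395/year); and a regression predicting 18-month FD
change in untreated patients (constant 0.8631°, ectopic coefficient
8.5189°, residual SD 12.6079°). Structural assumptions: 0.5-year
cycles, 55-year horizon, 1.5-year undiscounted trial period, 3.5%/year
discounting beyond it, 30° late-stage threshold, 3-year quiescence
(varied 1.5–5 years in sensitivity analyses).

The late-stage pathway and mortality inputs are **synthetic
placeholders** (`late_stage_defaults.yaml`): the source evidence for
them is not printed in the primary material, so the shipped values were
calibrated once so that the standard-care arm reproduces a plausible
lifetime surgical workload (~1.4–1.6 operations), model-period cost, and
a 22.6-year life expectancy from randomization, and so that the
base-case incremental cost-effectiveness ratio of repeated treatment
versus standard care lands near its reported value. They are ordinary
editable inputs, never constants in code; replace them with
study-specific estimates where available. A user-supplied life-table CSV
(`age`, `sex`, `hazard`) overrides the Gompertz form.

### Per-cycle scaling of the 18-month regression

The FD regression describes change over 1.5 years. A cycle of length
$L$ adds an independent Gaussian increment with mean $\mu_{18} L/1.5$
and SD $\sigma_{18}\sqrt{L/1.5}$, so the sum of three 6-month increments
reproduces both the regression mean and its residual SD exactly (the
test suite reassembles 9.3821° = 0.8631 + 8.5189 for ectopic patients
from 200,000 simulated three-cycle walks). FD is floored at 0°; hyperextension
is not modelled.

## Synthetic cohort

The baseline table of the source trial is not public, so the default
cohort specification is an explicit, documented assumption: age
Normal(61, 9) truncated at 30, 80% male, ectopic prevalence 25%,
baseline FD Uniform(0, 20)°, and baseline utility Normal(0.88, 0.12)
truncated at 1 — whose truncated mean (~0.845) matches the baseline
EQ-5D means the within-trial data report, and keeps trial-period QALYs
consistent with the lifetime results table. (An earlier design draft
used Normal(0.82, 0.15); its truncated mean ~0.79 contradicts the
trial's own EQ-5D marginals, which is why the package deviates.) The
generator emulates marginal distributions only: it does not reproduce
covariate correlations (e.g. between age and utility), multiple nodules
per patient, or site effects, so passing tests demonstrate internal
consistency of the model, not fidelity to any real cohort.

## Common random numbers and seeding

One master seed derives independent substreams for parameter sampling,
cohort generation, outcome assignment and the simulation streams. Five
streams drive each simulated life: mortality (indexed by calendar
cycle — hence identical death times across strategies), FD shocks
(indexed by the count of progressive cycles, so delaying progression
shifts the same shock sequence later and time-to-late-stage is monotone
in the quiescence duration), and surgery election/success/relapse
(indexed by late-stage exposure). The 18-month outcome uses a single
uniform per patient shared across strategies, mapped as: late-stage if
$u < p_{late}$, quiescent if $u \ge 1 - p_{quiescent}$, else
progressive — making each category monotone in its own probability, so
a patient quiescent under standard care is quiescent under adalimumab
whenever the adalimumab quiescence probability is at least as large.

## Probabilistic sensitivity analysis

The source evidence quantifies uncertainty through bootstrap
percentiles, not parametric families, so the sampling families are the
package's own choices, matched to the printed moments:

* outcome probabilities per arm: three-category Dirichlet
  (late / quiescent / progressive) with concentration fitted to the
  interval widths (both arms imply a concentration near the per-arm
  sample size, ~65, as expected for a bootstrap of ~70 patients);
  joint sampling guarantees $p_{late} + p_{quiescent} \le 1$ in every
  draw;
* regression coefficients and the quiescence utility gain: Normal with
  SD = (upper − lower)/3.92;
* quiescence duration: Uniform(1.5, 5) years (only the range is
  reported);
* placeholder probabilities Beta, costs Gamma (moment-matched), hazard
  ratio log-Normal; the FD residual SD has no interval and is fixed.

A test checks that the sampled 2.5th/97.5th percentiles of each
trial-estimated input reproduce the printed interval endpoints at
10,000 draws.

Net-benefit ties in the acceptability curves are credited to the
cheaper strategy (a measure-zero event in floating point, handled
deterministically). EVPPI uses the single-loop regression estimator —
each strategy's net benefit smoothed on the parameter subset with
thin-plate spline GAMs (`mgcv`), basis dimension scaled to the number of
draws — rather than nested Monte Carlo, which survives only as a
structure-known test oracle. The subset `"trial"` names the
trial-estimated parameters plus the quiescence duration, i.e. what a
confirmatory trial of the same design could resolve.

## Within-trial analysis

The within-trial generator produces complete data (multiple imputation
of missingness is out of scope by design): EQ-5D-5L utilities at months
0/3/6/9/12/18 as baseline + arm effect + visit noise, clamped to the
index range, and cost components (injections — zero in the placebo arm
by design — GP visits, physiotherapy, rare early surgery). Arm-level
baseline means are set so the truncated 12-month QALY means land on the
reported marginals (~0.875 vs ~0.855) with the adjusted difference an
order of magnitude smaller than the crude one, exercising the
covariate adjustment. QALYs are trapezoidal areas under the utility
curve; between-arm differences come from OLS adjusted for site, age and
(QALYs only) baseline utility; uncertainty from within-arm bootstrap
resampling (default 5,000 replicates). Replicates with zero QALY
difference stay in the net-benefit acceptability curve but are excluded
from ratio summaries.

## Numerical and accounting choices

* Patients alive at a cycle's start accrue the full cycle's cost and
  utility; survival is then tested for the next cycle. No half-cycle
  correction — the choice is deliberate and auditable.
* Discounting uses the factor at each cycle's start time; the factor is
  1 through the trial period.
* Utilities are clamped to [−0.594, 1] (the EQ-5D-5L index range) after
  adding the quiescence gain or subtracting a late-stage decrement.
* Relapse after an initially successful procedure returns the patient
  to the surgery-eligible untreated state; FD book-keeping in late
  stage is cosmetic since late-stage utilities are state-based.
* Whether quiescence can begin after 18 months is not described in the
  source; the model assumes it cannot (the 18-month outcome is final
  for the early stage), consistent with the assumption that
  non-responders receive no further early-stage treatment.
* The ICER's probabilistic interval is the percentile interval of
  per-draw cost/QALY ratios among draws with positive incremental
  QALYs; the point estimate is the ratio of mean differences.

## Run sizes

The reference configuration is 1,000 parameter draws × 100 repetitions
per patient (`scale = "paper"`). The package's standard desk-scale run,
used by the acceptance tests, is 200 × 20 (`scale = "desk"`), which
keeps the full pipeline under a minute on one core thanks to the
vectorized cycle-wise engine; `"smoke"` (2 × 1) exercises plumbing only.
Monte Carlo error at desk scale is visible mostly in the acceptability
probabilities (binomial SE ≈ 3 points at 200 draws), which is why those
checks carry wider tolerances than the incremental means.

## Limitations

* All late-stage and mortality inputs are placeholders; absolute
  late-stage costs and QALY losses inherit their uncertainty, though
  incremental results are less sensitive because the utility model is
  shared across strategies.
* One nodule per patient; no bilateral or multifocal disease, no
  referral-volume effects, no societal-perspective costs.
* The synthetic cohort and trial data match reported marginals, not
  joint distributions; results are a reconstruction of the published
  analysis's logic, not of its patient data.
* Comparisons against radiotherapy or steroid injections are out of
  scope (their parameters are not reported in the primary material).
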