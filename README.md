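# dmpkit

A desk-scale R implementation of the computational core of a national
chronic-disease management platform, of the kind operated for Turkish
primary care: structured **screening** encounters for citizens without a
diagnosis and recurring **monitoring** encounters for diagnosed patients,
driven by declarative national care-pathway rules, clinical decision
support, and population-level coverage statistics.

It is written for health-informatics researchers and engineers who want to
study, test or extend this machinery without access to a real electronic
health record. The package provides:

* an **HL7 FHIR R4-aligned patient data model** with exact bundle
  round-tripping, incremental-sync merge, validity-aware observation
  lookup, and `CarePlan` export;
* a **declarative module registry** (YAML-round-tripping): per-disease
  eligibility predicates, recall intervals in months (keyed by risk
  category with a default), parameter validity periods, page flows and CDS
  rules — with built-in defaults encoding the platform's stated rules
  (diabetes screening over age 40 without a diagnosis every 36 months,
  hypertension monitoring every 3 months on diagnosis plus medication,
  cardiovascular screening every 24/12 months by risk, ...);
* a **care-pathway state machine**: validated page flows (reachability,
  termination, catch-all transitions), prefilled sessions, first-match
  transitions over entered values, and care-plan assembly from accepted
  cards;
* the **nine CDS rule families** (risk scoring, diagnosis suggestions, lab
  panels, lab-driven referrals, treatment goals, medication advice with
  contraindication screening, preventive referrals, follow-up scheduling,
  module transitions), each a pure function, also exposed behind the CDS
  Hooks request/response document contract;
* a **SCORE-family cardiovascular risk score**: the Weibull
  survival functional form
  `S0(a) = exp(-exp(α)·(a-20)^p)`, per-sex coronary and non-coronary
  strata, proportional hazards `exp(w)` in smoking, systolic pressure and
  total cholesterol, 10-year risk `Σ (1 - S(a+10)/S(a))` — with the
  coefficient table as replaceable data (the shipped table is a clearly
  labelled demonstration calibration);
* **population statistics** with the platform's rounding convention
  (half-up, 1 decimal for rates, 2 for the per-patient mean): coverage,
  monthly achievement, encounter shares, treatment-goal achievement,
  practitioner panel views; and
* a **seeded synthetic cohort generator** (byte-identical regeneration)
  plus an encounter-log simulator, so every layer is testable end to end.

## Worked example

Reproducing the published per-module encounter shares and per-patient mean
from the shipped national counts:

```r
library(dmpkit)
summ <- encounter_summary_from_counts(reported_counts("encounters"),
                                      unique_patients = 16058904)
summ$table[, c("module", "total", "total_share")]
#>         module    total total_share
#> 1 hypertension 25904043        35.1
#> 2      obesity 18830474        25.5
#> 3     diabetes 13985839        19.0
#> 4     cvd_risk 13547569        18.4
#> 5  older_adult  1447344         2.0
summ$mean_encounters_per_patient
#> [1] 4.59
```

The shares are each module's percentage of the 73,715,269 total
encounters; 4.59 is the mean number of encounters per unique patient,
rounded half-up to two decimals.

Scoring a 60-year-old male smoker with systolic pressure 160 mmHg and
total cholesterol 6.5 mmol/L:

```r
cvd_risk_score(60, "male", smoker = TRUE, sbp = 160, total_cholesterol = 6.5)
#> 10-year fatal cardiovascular risk: 10.60% (very_high)
#>   calibration: demonstration: published SCORE low-risk-region coefficients (not a national calibration)
```

Running a full screening encounter on a synthetic patient:

```r
reg <- builtin_defaults()
ds  <- generate_population(cohort_config(n = 25, seed = 11))[[2]]
evaluate_eligibility(ds, reg$modules$diabetes, as.Date("2023-06-01"))$track
#> [1] "screening"
res <- run_encounter(ds, reg$modules$hypertension, reg, "screening",
                     as.Date("2023-06-01"),
                     answers = list(sbp = 150, dbp = 95, fpg = 120, bmi = 28))
```

`res` holds the assembled FHIR-exportable care plan, the recorded
encounter, the updated record, and the schedule updates (here the entered
glucose of 120 mg/dL exceeds the 110 mg/dL threshold, so an accepted
diabetes-screening prompt puts the patient's diabetes schedule at
`due_now`).

A command-line interface wrapping these functions ships as
`inst/cli/dmp` (`generate-population`, `target-lists`, `run-encounter`,
`serve-cds`, `stats`, `export-careplan`, `validate-registry`).

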