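---
title: "Methods: disease screening and monitoring machinery in dmpkit"
author: "dmpkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease screening and monitoring machinery in dmpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmpkit)
```

## What this package models

dmpkit is a desk-scale implementation of the computational core of a
national chronic-disease management platform of the kind deployed in
Turkish primary care: family medicine practitioners (FMPs) perform
structured *screening* encounters on citizens without a diagnosis and
recurring *monitoring* encounters on diagnosed patients, guided page by
page through national care pathways, with clinical decision support (CDS)
generating patient-specific suggestions and population-level statistics
tracking coverage and goal achievement. The package implements the data
model (HL7 FHIR R4), the declarative rule layer, the encounter state
machine, the nine CDS rule families, the aggregate statistics, and a
seeded synthetic cohort generator so that every layer is testable without
any real patient data.

## The data model and its conventions

Patient records are FHIR R4-aligned: `Patient`, `Condition` (ICD-10),
`Observation` (LOINC-coded quantitative parameters), `MedicationStatement`
(with therapeutic-class tags), `Encounter`, `Goal` and `CarePlan` map onto
the package's record types, and `read_bundle()`/`write_bundle()` are exact
inverses on the supported fields. Three conventions run through everything:

* **Dates are calendar days.** No clinical rule in this domain needs
  time-of-day, so all arithmetic is day-granular. Intervals and validity
  periods are whole calendar months with day clamping (`add_months()`:
  Jan 31 + 1 month = Feb 28/29), and an age in "completed months" or
  "completed years" increments on the anniversary day itself.
* **Validity-aware lookup.** `latest_observation()` returns the newest
  observation not after the reference date together with a freshness flag;
  a value is `expired` when its age *strictly exceeds* the parameter's
  validity period in months. Expired values are still prefilled on pathway
  pages but flagged for renewal, which is how the operational system
  treats parameter recency.
* **Incremental merge identity.** A national EHR syncs incrementally, so
  `merge_incremental()` needs a record identity; observations are keyed by
  (code system, code, effective date, origin), conditions by (code, onset
  date), and so on. The delta's version wins on collision, making the
  merge idempotent and order-insensitive for disjoint deltas.

## Declarative module definitions

Each disease module is configuration, not code: eligibility predicates
(a small expression language over age, active conditions, ongoing
medication classes, fresh observation comparisons, prior encounters and
the risk category), recall-interval rules keyed by context with a
mandatory `default`, per-parameter validity periods, a page flow, and CDS
rule descriptors. Definitions round-trip through YAML and are fully
validated on load: dangling flow references, non-positive intervals,
unresolvable predicate atoms and non-terminating flows are reported
together, and a sampling check rejects modules whose screening and
monitoring predicates can hold simultaneously.

The built-in defaults encode every rule the platform's public
documentation states:

| module | rule | source |
|---|---|---|
| diabetes | screening from age strictly over 40 without an active E10–E14 diagnosis, every 36 months | stated |
| hypertension | monitoring every 3 months for active I10–I15 plus ongoing antihypertensive medication | stated |
| cardiovascular risk | screening recall 24 months at low risk, 12 months at high risk | stated |
| obesity | primary-care monitoring excludes BMI > 40, and BMI in (30, 40] with a configured comorbidity (default E10–E14, I10–I15) | stated (comorbidity list is config) |

Where the documentation states no number we chose one conventional value
per slot and fixed it: hypertension and obesity screening recur every 12
months, diabetes and older-adult monitoring every 6 months, obesity
monitoring every 3 months, and older-adult monitoring starts at 65 with
no screening track. "Aged over 40" is read strictly (completed age > 40);
all stated thresholds ("exceeds 110 mg/dL", "below 60 mL/min/1.73m2") are
strict inequalities, each with a boundary unit test. Patients whose risk
score reaches the *very high* category move to the cardiovascular
monitoring track; *high*-risk patients stay in screening at the
intensified 12-month recall, which is the only reading consistent with a
stated per-risk screening interval.

## Eligibility and scheduling

`evaluate_eligibility()` gives monitoring precedence over screening — a
diagnosed patient is never re-screened for the same disease — and returns
a reason line per predicate so target-list membership is explainable.
`next_due()` adds the applicable interval (risk-keyed intervals fall back
to `default` when no risk has been computed) to the last completed
encounter of the track; a patient with no prior encounter is due
immediately, is `due_now` on the due date itself and `overdue` strictly
after — an arbitrary but unambiguous boundary that the tests pin down.
Target lists sort overdue first, then by due date, then by patient id for
determinism.

## The encounter state machine

A page flow is a set of pages (one per common care-pathway step: physical
examination, history, lab review, diagnosis, goal setting, treatment
planning, scaled assessment) plus an ordered transition list evaluated
first-match-wins over the values entered so far; every page must end with
an unconditional catch-all, so execution is total and deterministic, and
`validate_flow()` proves reachability and termination (the page graph
must be acyclic). Sessions are immutable values: each `submit_page()`
returns the updated session, which makes scripted replay
(`run_encounter()`) and bulk simulation trivial. Prefills come from
`latest_observation()` with freshness flags and are never allowed to
shadow a value the physician entered in-session. Completion assembles the
care plan from *accepted* cards only (the physician can reject any card),
always appends the follow-up appointment dated by the interval rule,
persists entered values as `encounter_entry` observations, and recomputes
the schedules of every module an accepted transition prompt touches.

The shipped hypertension screening flow encodes only the elements the
pathway documentation guarantees — office blood pressure with a
confirmation measurement, the fasting-glucose check whose value above 110
mg/dL prompts a diabetes screening, a diagnosis step on confirmed
elevation, goal setting and lifestyle planning; the page ordering beyond
that is illustrative configuration, not a claim about the operational
system.

## Decision support

Each of the nine rule families is a pure function from patient context to
cards, and the CDS Hooks layer is a thin serialisation of exactly those
functions: discovery lists nine services, invocation parses the prefetch
bundle with `read_bundle()` and emits cards in CDS Hooks card shape. The
tests assert byte-identity between service-layer and library-layer output,
so transport demonstrably adds nothing. No long-running HTTP server is
shipped: the contract is request-document-in / cards-document-out, which
is what the specification of CDS Hooks constrains and what an offline
test can verify; the CLI `serve-cds` subcommand processes request files
one-shot.

The cardiovascular risk score implements the published SCORE functional
form: per-sex Weibull baseline survivals `S0(a) = exp(-exp(alpha) (a-20)^p)`
for the coronary and non-coronary fatal-event strata, proportional hazards
`exp(w)` in current smoking, systolic pressure (centred at 120 mmHg) and
total cholesterol (centred at 6 mmol/L), stratum risks
`1 - S(a+10)/S(a)` summed and capped at 100%. The *functional form* is the
tested contract (against an independent step-by-step derivation, at 1e-9
relative tolerance, plus monotonicity in every risk factor); the shipped
coefficient table uses the published low-risk-region SCORE coefficients
and is labelled a demonstration calibration throughout — the national
calibration is not public and nothing here claims to reproduce it. Risk
categories default to the conventional 1/5/10 percent banding.
Glucose is handled in mg/dL and cholesterol in mmol/L internally, with
declared conversion helpers (factors 18.018 and 38.67).

Structural validators for FHIR R4 CarePlan documents, CDS Hooks requests
and card responses are hand-written against the published resource
definitions and operate on re-parsed JSON, independent of the writers, so
round-trip tests are genuinely two-sided.

## Population statistics

All rates use one rounding convention: percentages half-up to 1 decimal,
the per-patient encounter mean half-up to 2 (`percent()`,
`round_half_up()`); a zero denominator is an undefined rate rendered as
absent, never as 0. Aggregate rates always recombine summed counts, never
averaged percentages. Under this convention the package reproduces, from
the published national counts shipped in `inst/extdata/`, every published
per-module encounter share, coverage rate, monthly achievement rate, the
23.1% overall achievement rate and the 4.59 encounters-per-patient mean —
the acceptance script recomputes all of them at run time.

For goal achievement we had to fix an operational definition of
"assessed": a goal enters the denominator when an observation of its
parameter dated strictly after the goal was set (and not after the
reference date) exists — i.e. the parameter was re-measured at a
subsequent encounter — and it is achieved when the latest such observation
satisfies the goal comparator. This is a declared choice, not an assertion
about the ministry's definition. Coverage counts a patient once per
(module, track) however many encounters they had, and a patient appearing
in both tracks over time counts in each track separately, because the
published coverage tables report tracks independently.

## The synthetic cohort generator

The generator emulates what an EHR sync would deliver for a primary-care
panel; its defaults are the study conditions used by every test: sex ratio
56.2% female (the platform's reported patient population), ages
normal(52, 16) truncated to 18–95 — echoing the middle-aged concentration
of the reported age histograms without claiming to match them — age-banded
prevalence (hypertension 8/25/45%, diabetes 3/12/22%, obesity 15/25/28%
in the 18–39/40–59/60+ bands), medication-given-diagnosis probabilities
0.85/0.80, two observation waves (14 and 2 months before the reference
date) with truncated-normal noise whose means shift with disease status,
and recall adherence 0.7. All randomness flows from one integer seed
through R's Mersenne-Twister stream with inversion for normals, so
regeneration is byte-identical across platforms, and both generator entry
points save and restore the caller's RNG state.

What the generator does **not** emulate — real national demography,
geographic structure, care-seeking behaviour, measurement error structure,
comorbidity correlation — bounds what passing tests show: they verify the
machinery (rules, state machine, arithmetic) under controlled conditions,
not the platform's operational results. The large published operational
aggregates (tens of millions of encounters) are reproduced only at the
level of their *arithmetic* from published counts, which is all a desk
build can honestly claim.

The encounter-log simulator walks month by month (first-of-month
eligibility evaluation), appends attended encounters to each record so
recall scheduling compounds, and derives monthly targets from the due
counts before the adherence draw. In the limit case adherence = 1 every
eligible patient is covered within one recall cycle, which the tests
assert as an exact 100.0%.

## Numerical and size choices

Half-up rounding strips binary representation noise (a 9-decimal
pre-round) before applying the floor(x + 0.5) rule, so printed-table
reproductions are exact. Test problem sizes were chosen as the smallest
that exercise each property convincingly: 1000 patients for rule-fidelity
brute-force agreement, 1000 randomized scripted encounters for flow
safety, a 100-point grid for the risk-score oracle, 100 seeded contexts
for service/library byte-identity, and a 10,000-patient cohort for the
prevalence check (3 binomial standard deviations). The shared test cohort
is cached per run.

## Known limitations

* The full national eligibility criteria are not public; the defaults
  encode the stated rules and the YAML format carries the rest.
* The medication knowledge base is demonstration content; only the
  contraindication *mechanism* (comorbidity-keyed filtering with named
  conflicts) is fixed.
* FHIR conformance is base R4 structural, not a national implementation
  guide, and the validators are structural, not full profile validation.
* Scaled assessments (e.g. nutritional screening instruments) are
  supported generically as a page kind; no instrument content is shipped.
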