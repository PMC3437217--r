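---
title: "Measuring quality of type 2 diabetes care from EHR extracts"
author: "diabqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring quality of type 2 diabetes care from EHR extracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabqc)
```

## The problem

Large public health systems increasingly hold routine electronic health
records (EHR) that could, in principle, answer a simple question: *is the
care delivered to patients with type 2 diabetes (T2DM) any good?* Answering
it takes three distinct steps, and `diabqc` implements each as a separate,
testable module:

1. **Deciding what to measure.** A candidate quality-of-care indicator
   (QCI) is only useful if experts judge it clinically *valid* and
   *feasible* to compute from the records at hand. The package implements
   the RAND/UCLA-style aggregation used for this: each panelist scores each
   candidate 1–9 on both domains, candidates are accepted when the mean
   score is at least 7 on *each* domain, and accepted candidates are
   further flagged by whether they are programmable from structured EHR
   fields (free-text-only candidates cannot be computed reliably).
2. **Building an analyzable cohort.** Adults (completed age ≥ 20 at the
   start of the observation year) carrying a T2DM diagnosis code
   (ICD-10 E111–E119, E140–E149, E14X, matched after uppercasing and dot
   removal, in any of three diagnosis fields) with at least one
   family-doctor visit inside the observation window form the cohort.
   Routine vitals are noisy, so predefined biological-plausibility bounds
   are applied before any measurement is used: systolic pressure outside
   [50, 250] mmHg, diastolic outside [40, 200] mmHg, height outside
   [130, 250] cm, weight outside [30, 200] kg, HbA1c below 3%, fasting
   glucose below 37 mg/dl and total cholesterol below 100 mg/dl are
   treated as data errors and excluded (bounds themselves are retained;
   exclusion is strict). Missing data are excluded, never imputed.
3. **Computing the indicators.** Each of the 14 active indicators is a
   denominator rule (eligibility) and a numerator rule (criterion met)
   over a patient's cleaned, date-ordered timeline. Results are reported
   per clinic and pooled as `100 × Σ numerators / Σ denominators` — a
   patient-weighted rate, deliberately not the unweighted mean of clinic
   rates.

## The indicator catalog

The shipped catalog (`indicator_catalog()`) holds all 23 candidates with
their panel means and status. The 14 active entries:

| id | family | denominator | numerator |
|----|--------|-------------|-----------|
| P1 | detection | all cohort | ≥ 1 resulted HbA1c in the year |
| P2 | detection | all cohort | ≥ 1 comprehensive foot exam |
| P3 | detection | all cohort | ≥ 1 ophthalmology referral |
| P4 | detection | no dyslipidemia diagnosis before the window | ≥ 1 resulted total cholesterol |
| P5 | non-pharmacological | all cohort | ≥ 1 nutrition-service visit |
| P6 | pharmacological | first in-window BMI ≥ 25, no contraindication | metformin at ≥ 1 of the last 3 visits |
| P7 | pharmacological | hypertension, no contraindication | ACE inhibitor or ARB at ≥ 1 of the last 3 visits |
| P8 | pharmacological | age > 40 with smoking/hypertension/dyslipidemia, no contraindication | 75–150 mg/day acetylsalicylic acid at ≥ 1 of the last 3 visits |
| P9 | pharmacological | last total cholesterol > 200 mg/dl, no contraindication | statin at ≥ 1 of the last 3 visits |
| O1 | outcome | ≥ 1 resulted HbA1c or fasting glucose | all of the last 3 HbA1c < 7% *or* all of the last 3 glucose ≤ 130 mg/dl |
| O2 | outcome | ≥ 1 resulted total cholesterol | last value < 200 mg/dl |
| O3 | outcome | ≥ 1 cleaned BP pair | all of the last 3 pairs < 130/80 mmHg |
| O4 | outcome | P6 denominator with ≥ 2 dated weights | ≥ 5% weight loss first-to-last |
| O5 | outcome | intersection of O1, O2 and O3 denominators | O1 and O3 criteria plus cholesterol < 200 |

### Interpretation decisions that were genuinely open

Several rules required a reading the source material does not pin down;
these are the package's choices, each made once and kept configurable
where it matters:

* **"Last 3 measurements" with fewer than 3 available** is evaluated over
  all available measurements (`min(3, n)`), with the denominator requiring
  only a non-empty series. This is the weakest consistent reading: outcome
  denominators in practice sit far below the cohort size but well above
  any plausible count of patients with three or more results, given that
  only around 60% of patients have any resulted test.
* **"Received drug X in the last three visits"** is satisfied by at least
  one prescription of the drug dated at any of the patient's last three
  family-doctor visits inside the window.
* **Contraindications exclude from the denominator** rather than counting
  as numerator successes — standard quality-measure practice for "unless
  contraindicated" clauses.
* **"Older than 19 years"** is completed age ≥ 20 at the window start.
  Whether age should be evaluated at the visit, at year start or year end
  is unstated in the source; year start was chosen and is flagged here.
* **Comorbidity lookback is unlimited**: these are medical-history flags,
  so any qualifying diagnosis on or before the window end counts. Only the
  dyslipidemia-*screening* denominator (P4) looks strictly before the
  window start.
* **Clinics without HbA1c testing** keep their full denominator for P1
  with numerator zero; their clinic-level cell is rendered "Not available"
  while their counts still enter the pooled total. This is the only rule
  under which the pooled HbA1c-measurement rate implied by the per-clinic
  values is reproducible.
* **Same-day duplicate measurements** keep the last record in file order
  and log the drop — deterministic and auditable.
* **Foot exams and ophthalmology referrals** are modelled as explicit
  structured care-event records, since their encoding in the source EHR is
  unspecified; **smoking** is modelled as a diagnosis-code flag
  (Z72.0/F17).
* **Upper bounds for the laboratory analytes** are absent by default (the
  plausibility rules state only lower bounds for them) but configurable in
  `plausibility_bounds()`.
* **Panel classification uses the 1-decimal rounded means**, matching the
  precision at which panel results are tabulated; rounding is half-up
  (`round_half_up()`), as is all report formatting, applied only at render
  time.

## The synthetic generator

No patient-level data are distributable, so the package ships a seeded
generator whose defaults are the study-like conditions the analysis
assumes:

* 14.4% T2DM prevalence among adult clinic attendees; T2DM ages
  N(62.3, 12.9²) truncated to adults; 58.5% female.
* Comorbidity prevalences: hypertension 0.604, dyslipidemia 0.416, other
  cardiovascular disease 0.092, chronic complication 0.317 (type split by
  the published relative frequencies). Comorbidities are drawn
  *independently* — no joint distribution is available, so simulated joint
  prevalences must not be read as reproducing the study.
* Family-doctor visit counts: negative binomial matched to mean 8.8 and
  sd 4.6, truncated at one visit (attendees attend); visit dates are
  distinct days of the year.
* Field-level missingness applied by `inject_data_defects()`: schooling
  0.287, marital status 0.310, employment 0.426, diabetes-onset year
  0.645, BMI 0.143 (patient-level, blanking weight and height).
* Implausible-vitals contamination inside the reported 5–24% band
  (defaults: weight 0.05, height 0.08, systolic 0.12, diastolic 0.12),
  injected strictly *outside* the plausibility bounds so that cleaning
  removes exactly the injected set — this makes the cleaning stage exactly
  testable against the defect log.
* Per-indicator adherence probabilities defaulting to the published pooled
  rates (e.g. metformin 0.632, nutrition counseling 0.039).

Where the study reports nothing, values were chosen once as realistic for
an urban Mexican primary-care population and not revisited: smoking-flag
prevalence 0.15, per-drug contraindication rate 0.02, fasting-glucose
result availability 0.62 (the reported share of patients with registered
results), cholesterol availability 0.65 for patients already diagnosed
with dyslipidemia, a 0.16 rate of laboratory orders without results, and
background prescribing rates for hypoglycemics.

Generation is *eligibility-first*: comorbidity, BMI category and
contraindications are drawn before numerator events, and numerator events
are emitted with the configured adherence probability conditional on
eligibility. Outcome states are generated coherently — a "controlled"
patient's values are all inside the target, an "uncontrolled" patient's
are all outside — so that the cleaning of individual measurements cannot
flip a patient's outcome state, only move them out of a denominator. That
keeps observed rates unbiased for the configured adherence even under
defect injection. A ground-truth sidecar (attribute `"truth"`) records
each patient's true eligibility and numerator status per indicator, and on
defect-free bundles the engine's counts equal the sidecar exactly.

### What the generator does not emulate

Disease progression, multi-year trajectories, correlated comorbidities,
clinic-level practice styles beyond HbA1c availability, and free-text
notes. Passing tests on synthetic data therefore demonstrate that the
*logic* of cohort selection, cleaning and indicator computation is
correct under the assumed data-generating structure — not that the
package reproduces the study's patient-level table cells, which would
require the original records.

## Verification strategy and problem sizes

* **Printed-table reproduction**: the threshold rule applied to the 23
  shipped candidate means reproduces the printed accepted/discarded
  status row for row (18 accepted, 5 discarded); denominator-weighted
  pooling of the printed per-clinic rates reproduces the printed totals
  (e.g. ophthalmology referral 13.0%, metformin 63.2%, HbA1c measured
  7.1%) to within 0.1 percentage points, the slack implied by rounded
  per-clinic rates.
* **Parameter recovery**: an 8,000-patient all-T2DM configuration (so
  every denominator clears 2,000 eligible patients) recovers each
  configured adherence within 3 binomial standard errors at a fixed seed,
  with study-like defect rates left on.
* **Oracle equivalence**: on 100 seeded bundles of ≤ 50 patients, cohort
  selection and all indicator counts match independent brute-force
  implementations written directly from the rules as per-patient loops.
* **Cleaning exactness**: on a 2,000-patient defected bundle, the pooled
  cleaning log equals the injected defect log as a set.

These sizes keep the default suite under a minute while leaving the
binomial bounds tight enough to detect rule errors of a fraction of a
standard error.

## Worked example

```{r example, eval = FALSE}
library(diabqc)

cfg <- sim_config(n_clinics = 4, members_per_clinic = 2000,
                  attendance_probability = 0.6, seed = 1)
bundle <- inject_data_defects(generate_population(cfg), cfg)
cohort <- select_cohort(bundle)
results <- evaluate_all(cohort)
print(results[results$clinic_id == "Total", ])
describe_cohort(cohort)$nutritional_status
```

## Known limitations

* The engine evaluates one observation year; longitudinal trends, risk
  adjustment and physician-level attribution are out of scope.
* Patients appearing in two clinics are not deduplicated or linked.
* The four accepted-but-not-programmable candidates (smoking counseling,
  exercise advice, two adherence-registration indicators) and the five
  discarded candidates are represented in the catalog as inactive entries
  only; asking the engine to evaluate them is an error by design.
* The published pooled ACEi/ARB denominator does not equal the sum of its
  printed clinic denominators (a likely typo in the source table); the
  engine always sums clinic counts.
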