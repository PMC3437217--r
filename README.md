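# diabqc

Quality-of-care indicators for type 2 diabetes (T2DM) computed from
routine electronic health record (EHR) extracts.

Public health systems that run large-scale EHRs can in principle monitor
chronic-disease care continuously, but doing so takes three separate
pieces of machinery, and `diabqc` provides all three for T2DM primary
care:

1. **Panel aggregation** (RAND/UCLA-style): panelists score candidate
   indicators 1–9 on clinical *validity* and *feasibility*; a candidate is
   accepted when its mean score is ≥ 7 on each domain
   (`mean_scores()`, `classify_candidate()`). The shipped catalog
   (`indicator_catalog()`) holds 23 candidates, of which 18 are accepted
   and 14 are programmable from structured fields — these 14 are the
   active indicators.
2. **Cohort construction**: adults (age ≥ 20 at the window start)
   carrying an ICD-10 T2DM code (E111–E119, E140–E149, E14X) in any of
   three diagnosis fields, with ≥ 1 family-doctor visit in the
   observation year (`select_cohort()`). Measurements pass predefined
   biological-plausibility bounds before use (e.g. systolic pressure
   retained only in [50, 250] mmHg, weight in [30, 200] kg;
   `plausibility_bounds()`, `clean_measurements()`); implausible values
   are excluded and logged, missing values are excluded, never imputed.
3. **Indicator evaluation**: each active indicator is a denominator
   (eligibility) rule and a numerator (criterion-met) rule over a
   patient's cleaned timeline — e.g. *metformin at one of the last three
   visits for overweight/obese patients unless contraindicated*, or
   *HbA1c < 7% or fasting glucose ≤ 130 mg/dl in the last three
   measurements*. For indicator *i*, clinic *c*:

   rate(i, c) = 100 · numerator(i, c) / denominator(i, c),
   pooled rate(i) = 100 · Σ_c numerator(i, c) / Σ_c denominator(i, c)

   — a patient-weighted rate, not the mean of clinic rates
   (`evaluate_all()`, `pooled_from_rates()`).

Because patient-level records cannot be distributed, the package includes
a seeded synthetic EHR generator (`sim_config()`, `generate_population()`,
`inject_data_defects()`) that emulates the multi-clinic population
structure the analysis assumes — prevalences, visit frequencies,
missingness and implausible-value contamination, with configurable
per-indicator adherence and a ground-truth sidecar — so the whole pipeline
is testable end to end. See the methods vignette
(`vignettes/diabetes-qc-methods.Rmd`) for the model, parameter defaults
and design decisions.

## Worked example

```r
library(diabqc)

cfg <- sim_config(n_clinics = 4, members_per_clinic = 2000,
                  attendance_probability = 0.6, seed = 1)
bundle <- inject_data_defects(generate_population(cfg), cfg)
cohort <- select_cohort(bundle)
cohort
#> <t2dm_cohort> 730 patients in 4 clinic(s); 27 excluded
#>   window: 2009-01-01 to 2009-12-31

results <- evaluate_all(cohort)
results[results$clinic_id %in% c("FMC01", "Total") &
          results$indicator %in% c("P3", "P6", "O1"), ]
#>  indicator clinic_id numerator denominator percentage
#>         P3     FMC01        26         185       14.1
#>         P3     Total       101         730       13.8
#>         P6     FMC01        88         129       68.2
#>         P6     Total       299         472       63.3
#>         O1     FMC01        28         127       22.0
#>         O1     Total       110         483       22.8
```

Reading the output: of the 730 synthetic cohort patients, 13.8% were
referred to an ophthalmologist (P3, denominator = whole cohort); 63.3% of
the 472 overweight/obese patients without a metformin contraindication
received metformin at one of their last three visits (P6); and 22.8% of
the 483 patients with any resulted glycemic test met the glycemic-control
target (O1). Excluded T2DM-coded patients (here 27) carry a logged reason
(under-age, or no in-window visit). `describe_cohort(cohort)` produces the
per-clinic descriptive tables; `render_report(results, path, "csv")`
writes the indicator table with "Not available" cells for clinics lacking
the measurement source.

The panel stage on the shipped catalog:

```r
cat23 <- indicator_catalog()
table(classify_candidate(cat23$validity, cat23$feasibility))
#> accepted discarded
#>       18         5
```

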