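# pmews

Scoring, evaluation and cohort simulation for the **physiological-social
modified early warning score (PMEWS)** — a prehospital triage instrument
that combines six banded physiological parameters with social risk items to
support the decision whether a non-trauma adult patient needs an emergency
medical service (EMS) response.

The package is for researchers evaluating early-warning instruments:
it provides the deterministic banded scoring engine, the diagnostic
evaluation stack used to validate such instruments against a gold-standard
disposition, and a calibrated synthetic cohort generator for method work
when patient-level data are unavailable.

## The score

For patient *i* with physiological sub-scores
*s<sub>ij</sub>* (respiratory rate, SpO2, heart rate, systolic BP,
temperature, consciousness; each 0–3, temperature 0–2, from ordered band
tables) and social items:

```
physiological_i = Σ_j s_ij                                   (0–17)
social_i        = 1{age_i > 65} + 1{isolated_i} + 1{chronic_i} + PS_i   (0–7)
PMEWS_i         = physiological_i + social_i                 (0–24)
```

where PS is the 0–4 performance status. The published decision rule flags
a patient when PMEWS ≥ 4. Evaluation against a binary gold-standard label
uses the score ≥ threshold rule: ROC curve, AUROC by the tie-corrected
Mann–Whitney identity, DeLong or stratified-bootstrap 95% CIs, confusion
matrices at any cutoff, and the Youden-optimal cutpoint.

Two conventions are fixed by the package (and unit-tested): measurements
are rounded **half-up** to the band tables' printed precision before
lookup, and values the printed grid leaves uncovered (e.g. SpO2 89)
escalate to the adjacent band with the **higher** sub-score. See the
methods vignette (`vignettes/pmews-methods.Rmd`) for rationale.

## Worked example

```r
library(pmews)

patient <- data.frame(
  patient_id = "example", respiratory_rate = 20, spo2 = 92,
  heart_rate = 105, systolic_bp = 95, temperature_c = 38.2,
  consciousness = "confused", age_years = 65, socially_isolated = 0,
  chronic_disease = 1, performance_status = 2
)
score_cohort(patient)[, c("physiological_score", "social_score", "total_pmews")]
#>   physiological_score social_score total_pmews
#> 1                   7            3          10
```

Each physiological reading sits one or two bands from normal (respiratory
rate 20 → 1, SpO2 92 → 2, heart rate 105 → 1, systolic BP 95 → 1,
temperature 38.2 → 1, confused → 1, total 7); age exactly 65 scores 0 (the
criterion is *strictly* over 65), chronic disease adds 1 and performance
status 2 adds 2. Total 10 ≥ 4, so this patient would be flagged as needing
an EMS response.

The full study-replication pipeline — simulate a labeled cohort from the
shipped calibrated generator, score it, summarise it, and evaluate the
three scores as discriminators — is one call:

```r
res <- run_study("study_out", n = 2157, seed = 1)
#> simulate: 2157 records (seed 1)
#> score: 2157 records scored
#> summarize: cohort of 2157
#> analyze: AUROC total 0.729 / physiological 0.713 / social 0.706
res$summary
#> Cohort summary (n = 2157)
#>   characteristic                    n      %
#>   age > 65                        602   27.9
#>   social isolation                330   15.3
#>   chronic disease                 702   32.5
#>   needed EMS response            1468   68.1
#>   did not need EMS response       689   31.9
#>   measure                        mean     sd
#>   age (years)                   51.00  22.02
#>   physiological score            2.07   2.95
#>   social score                   0.80   1.04
#>   total PMEWS                    2.87   3.81
```

(Exact numbers vary with the seed; the same command is bit-reproducible.)
The same pipeline runs from a shell via the thin CLI in
`inst/scripts/pmews` (`simulate | score | summarize | analyze | calibrate |
run`).

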