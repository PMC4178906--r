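---
title: "PMEWS: the scoring instrument, its evaluation, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PMEWS: the scoring instrument, its evaluation, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmews)
```

## The instrument

The physiological-social modified early warning score (PMEWS) is a triage
aid for prehospital emergency services: a single number, computable at the
bedside from routine observations, intended to support the decision whether
a non-trauma adult patient needs an emergency medical service (EMS)
response. It extends the familiar physiological track-and-trigger scores
(MEWS-style instruments) with social risk items, on the argument that the
need for an ambulance response depends not only on physiology but on
whether the patient can safely be left at home.

The score has two components:

* **Physiological component (0-17).** Six parameters - respiratory rate,
  oxygen saturation, heart rate, systolic blood pressure, temperature, and
  consciousness - each mapped to a sub-score through an ordered band table
  (0-3 for all except temperature, whose printed grid peaks at 2).
  Consciousness uses a four-level scale (alert 0; confused/agitated 1;
  responds to voice 2; responds only to pain or unresponsive 3) - an AVPU
  scale with an added confused/agitated level; where an accompanying
  narrative describes plain AVPU, the printed scoring grid is what the
  instrument scores, so the grid governs here.
* **Social component (0-7).** One point each for age strictly over 65,
  social isolation (living alone or of no fixed abode) and chronic disease
  (respiratory, cardiac, renal, immunosuppression, diabetes), plus the 0-4
  WHO/ECOG-style performance-status scale (0 = normal activity, 4 =
  confined to bed or chair with no self-care). "Strictly over 65" is taken
  at its printed word: a 65-year-old scores 0. That the social component
  includes performance status is an inference from the published component
  means (physiological 1.97 + social 0.75 matching the total 2.71); it is
  the only composition consistent with additivity.

The total PMEWS is the sum, 0-24, and the published decision rule flags a
patient as needing an EMS response when the total is at least 4.

```{r example}
patient <- data.frame(
  patient_id = "example", respiratory_rate = 20, spo2 = 92,
  heart_rate = 105, systolic_bp = 95, temperature_c = 38.2,
  consciousness = "confused", age_years = 65, socially_isolated = 0,
  chronic_disease = 1, performance_status = 2
)
score_cohort(patient)[, c("physiological_score", "social_score", "total_pmews")]
```

### Rounding and band gaps

Two details of the band tables are underdetermined by the printed form and
are fixed here as package conventions:

* **Rounding.** The grid is printed at integer precision for rates,
  saturation and pressure and at one decimal for temperature. Measurements
  are rounded *half-up* to that precision before lookup (18.5
  breaths/min falls in the 19-25 band). Half-up rather than R's default
  half-to-even because that is how a human reads a measurement against a
  printed grid.
* **Gap closure.** The printed grid leaves a handful of values uncovered -
  most prominently SpO2 89%, which falls between "<89" and "90-93"; the
  temperature grid has sub-0.1-degree gaps that rounding already closes.
  After rounding, any residual uncovered value is assigned to the adjacent
  band with the **higher** sub-score. The rationale is fail-safe triage: an
  ambiguous reading should escalate, not reassure. So SpO2 89 scores 3,
  not 2. The rule lives in the band-table loader, is unit-tested, and the
  tables themselves ship as a versioned JSON resource
  (`inst/extdata/pmews_bands.json`) so the instrument is auditable and
  replaceable without touching code.

Missing data are strict by default: the instrument's source cohort excluded
incompletely filled forms, so an incomplete record is an error. An explicit
`missing = "zero"` opt-in scores an absent physiological measurement as
normal and logs which patients were affected.

## Evaluation against a gold standard

The evaluation module treats any integer score as a diagnostic test for a
binary gold-standard label (here: a specialist's judgment that the patient
needed the EMS response). The positivity convention is fixed throughout:
**score >= threshold flags the patient**.

* The ROC curve sweeps every integer threshold from one below the minimum
  to one above the maximum score, so the trivial operating points
  (sensitivity 1, specificity 0) and (0, 1) are always present.
* AUROC is computed by the rank (Mann-Whitney) identity - the probability
  that a random positive outranks a random negative, ties counting one
  half - which equals the trapezoidal area under the empirical curve. The
  test suite checks this against an O(n^2) brute-force pair count and
  against an independent implementation.
* The 95% CI uses the DeLong placement-variance estimator by default; the
  source study does not state its CI method, and DeLong is the standard
  non-parametric choice. A stratified percentile bootstrap is available as
  a cross-check; the two agree closely on cohorts of a few hundred.
* Cutoff analysis reports the full confusion matrix with sensitivity,
  specificity, PPV and NPV at any cutoff, a sweep over all cutoffs, the
  score-by-disposal distribution, and the Youden-optimal cutpoint
  (maximum sensitivity + specificity - 1, ties broken towards the higher,
  more specific cutoff - fewer false positives at equal J).

One reporting note: the source study quotes "97.6" both as the proportion
of high-scoring patients who needed transport (a PPV) and, elsewhere, as a
"sensitivity" at cutoff 4; the two are different quantities, and this
package computes and reports both without privileging either. Likewise a
"0.767" quoted for the discrimination in one passage is the upper CI bound
of the 0.738 AUROC; 0.738 is treated as the study value.

## The synthetic cohort generator

Patient-level data for the instrument's source cohort (2157 prehospital
internal-medicine patients, Tehran, 2012) are not available; what is
published is a summary: needs-EMS prevalence 68.4%, total score
2.71 +/- 3.55, physiological 1.97 +/- 2.86, social 0.75 +/- 1.16, age
50.58 +/- 22.15, characteristic rates (age > 65: 32.2%, isolation: 14.3%,
chronic disease: 52.5%), AUROCs 0.738 / 0.692 / 0.667 (total /
physiological / social), and PPV 97.6% at cutoff 4. The generator's job is
the inverse problem: a distribution over *raw measurements* whose scored
summary matches those numbers, so that the scorer and ROC stack are
genuinely exercised end-to-end.

### Generative model

For each patient:

1. label `y ~ Bernoulli(prevalence)`;
2. latent severity `z`: negatives draw `Normal(0, 1)` (fixed, for
   identifiability). Positives draw from a **two-component mixture**: with
   probability `q2` a clearly-critical mode `Normal(mu2, sigma2)`, otherwise
   a mildly-shifted non-critical bulk `Normal(mu1, sigma1)`. The mixture is
   forced by the published numbers, not a stylistic choice: the AUROC/SD
   pattern (components at 0.692 and 0.667 combining to 0.738 with the
   printed SDs) implies the two components are nearly independent *within*
   class, while a 97.6% PPV at cutoff 4 under 68.4% prevalence requires the
   upper tail of the positive class to be nearly deterministic relative to
   negatives. A single class-conditional normal can provide one or the
   other but not both (heavy-tailed positives couple the components through
   the latent axis; a plain mean shift overshoots every AUROC), and a pure
   critical-vs-indistinguishable two-point mixture caps every AUROC at
   `0.5 + q2/2`, below 0.738 for plausible critical fractions. Clinically
   the mixture reads
   naturally: specialists judged many physiologically unremarkable patients
   to need transport (the bulk), alongside a genuinely critical minority.
   Setting `q2 = 0` recovers the single-normal model;
3. each banded physiological parameter picks its severity *level* through
   a cumulative-logit link `P(level >= k | z) = plogis(slope * (z - c_k))`,
   then - where the instrument has abnormal bands on both sides (e.g.
   bradycardia vs tachycardia) - a side with a fixed side probability, then
   a raw value uniform on the band's measurement grid. Open-ended bands are
   truncated at documented physiological caps (respiratory rate 2-60 /min,
   heart rate 20-200 /min, systolic BP 40-250 mmHg, SpO2 60-100%,
   temperature 30-42 C);
4. social isolation and chronic disease are Bernoulli with logistic links
   on `z`; performance status uses its own cumulative-logit link;
5. age is Normal(mean + slope * z, sd) truncated to 12-100 years (the
   source cohort excluded children), drawn by inverse CDF; the age > 65
   flag is *derived from the simulated age*, not drawn separately, so a
   record can never contradict itself.

The label influences measurements only through `z` (no leakage; a
zero-slope configuration is tested to give AUROC 0.5 and vanishing
label-measurement correlations). All draws happen in a fixed order and
fixed count, so a seed fully determines the cohort and the same seed acts
as common random numbers across configurations during calibration.

Side probabilities are structural constants (hypoventilation, bradycardia
and hypothermia are the rarer presentation in a medical cohort:
low-side probability 0.15 for respiratory and heart rate, 0.25 for
temperature), not calibration parameters.

### What the generator does and does not emulate

It reproduces the marginal scored-summary behaviour of a two-class
prehospital cohort. It does **not** model inter-vital correlation beyond
the single shared severity axis, temporal trajectories, measurement error,
digit preference, or trauma/paediatric/pregnant presentations (excluded
from the source cohort). Passing the reproduction tests therefore shows the
instrument + evaluation chain is faithful and the published summary is
jointly achievable by a one-latent-factor cohort; it does not validate the
instrument on real patients.

### Calibration

`calibrate_generator()` minimises the weighted mean of squared *relative*
deviations between achieved and target constraints by Nelder-Mead over a
transformed parameter vector (logit for prevalence, logs for scales and
threshold gaps, so every visited point is a valid configuration). Achieved
values are always measured through the real simulate -> score -> ROC
chain - never a score-space shortcut - on a fixed set of seeds, making the
objective a deterministic function of the parameters. Gradients are
unavailable and the objective is a simulation output, hence the
derivative-free choice. The `free` argument restricts the search to named
parameter blocks, which is how the shipped configuration was produced:
alternating physiological-link and social-link stages, then a joint polish
(cohorts of 6000, 3 seeds per evaluation, a few thousand evaluations
total).

### An internal inconsistency in the published constraints

The published constraint set is not jointly attainable under the
instrument's own arithmetic: the three characteristic rates alone
(0.322 + 0.143 + 0.525 = 0.99) already exceed the published social-score
mean of 0.75, before performance status contributes anything. (The same
table also swaps the needs/does-not-need EMS counts; its percentage column,
which matches the running text, is taken as authoritative.) The package
resolves the conflict the way the published text itself resolves its table:
the narrative summary statistics govern. The shipped reference
configuration was calibrated with the three characteristic-rate constraints
down-weighted (weight 0.1 vs 1.0), and its calibration report - shipped
alongside the configuration as `pmews_reference_calibration.json` - records
the residual deviations honestly: the simulated rates of isolation and
chronic disease sit below the published rates so that the social-score
mean, SD and AUROC can be met. `default_constraints()` still returns unit
weights for every entry, so a user re-running calibration sees the conflict
rather than a silent resolution.

The reference configuration is one member of the family of generators
consistent with the printed constraints; with only ~16 summary targets the
patient-level distribution is underdetermined, and no claim is made that it
matches the unpublished cohort beyond those targets.

## Numerical and design choices

* Sample SD (n-1) throughout; unstated in the source, standard for cohort
  description, and negligible at n = 2157.
* Display rounding is half-up: 1 decimal for percentages, 2 for means/SDs,
  matching the published precision; stored values keep full precision.
* Reproduction protocol sizes: 20 cohorts of n = 2157 (the source cohort
  size) for the stochastic reproduction checks; 1000 random cohorts of
  n <= 50 for the AUROC oracle equivalence; 10,000 patients for the
  no-signal and slope-monotonicity checks. Chosen so Monte-Carlo error is
  well inside each check's tolerance.
* PPV is undefined when no patient reaches the cutoff; inside the
  calibration objective (only) it counts as 0 so a degenerate region is
  penalised rather than fatal.
* Ties in the Youden criterion break towards the higher cutoff; ROC
  thresholds are integers because the score is.
* Raising all severity slopes raises the simulated AUROC while the links
  are noisy (the tested regime), but the relation saturates: once a link is
  nearly deterministic given severity, further steepening only reshuffles
  the tie structure of the discrete score and the AUROC can wiggle by a few
  thousandths. The same tie arithmetic explains why a component score with
  a large floor (many patients at 0 in both classes) can post a slightly
  higher AUROC than a finer-grained score: ties earn half credit where a
  noisy refinement would lose whole pairs.

## Known limitations

* The evaluation module requires integer-valued scores (the instrument's
  range is 0-24); it is not a general continuous-marker ROC toolkit.
* DeLong CIs are asymptotic; with a single-digit number of positives or
  negatives the bootstrap option is the safer choice.
* The generator's single latent factor cannot represent, e.g., febrile
  tachycardia beyond what the shared severity induces; if you need
  correlated vital-sign structure, fit your own `generator_config()` and
  calibrate against your own constraint set.
* Calibration is a local search; starting far from a feasible region may
  need staged `free` blocks, as used for the shipped configuration.
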