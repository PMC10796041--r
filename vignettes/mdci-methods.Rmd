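---
title: "Methods: a multidimensional diagnosis-based comorbidity index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multidimensional diagnosis-based comorbidity index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Register-based epidemiological studies need a single comorbidity summary per
subject — to predict mortality, to adjust for confounding, or to define
population strata. The workhorse, the Charlson comorbidity index (CCI), is a
weighted count of a small, pre-specified list of conditions, scored from the
mere occurrence of diagnosis codes. In elderly cohorts a majority of subjects
score CCI = 0, yet their mortality risks differ widely: occurrence of a short
condition list simply discards most of the information a patient register
contains.

`mdci` implements a data-driven alternative: a multidimensional
diagnosis-based comorbidity index (MDCI) that uses *all* ICD-10 codes
registered for a subject in hospital and specialist outpatient care during a
lookback window (default 10 years before an index date), and that encodes not
just occurrence but also frequency, recency, and the total duration of the
associated hospital admissions.

## The predictor scheme

Every raw code is normalized (uppercase, punctuation stripped, truncated to
five characters) and expanded to four granularity levels: two, three, four
and five characters. Levels below the recorded length are prefixes; levels
above it are padded with trailing `9`s, ICD-10's "unspecified" convention, so
`I731` contributes `I7`, `I73`, `I731` and `I7319`. Variants seen in at least
0.01% of the development cohort (subject-counting, boundary inclusive) form
the vocabulary.

Each vocabulary variant then generates ten binary predictors per subject:

| dimension | definition |
|---|---|
| `occ_primary` | ≥ 1 event with the variant as primary diagnosis |
| `occ_any` | ≥ 1 event in primary or secondary position |
| `freq_ge2/3/4` | primary events on ≥ 2, 3, 4 distinct dates |
| `rec_90/180/365` | a primary event within 90/180/365 days of the index date |
| `dur_gt7/14` | > 7 / > 14 total days in hospital with the variant primary |

Frequency, recency and duration use primary diagnoses only; occurrence also
has the any-position variant. The thresholds are fixed, clinically motivated
dichotomizations: they separate short diagnostic contacts from recurring or
severe disease. The column count is therefore always `10 × |vocabulary|`.

Conventions the scheme needs but the dimension list does not determine —
each is a package-level decision, tested as stated:

* **Stay length** is `discharge − admission` in days with a one-day minimum
  (a same-day admission counts as one day), clipped to the lookback window
  when a stay straddles its start.
* **Recency** is measured from the diagnosis (event) date, not the discharge
  date, and the boundary is inclusive: exactly 90 days before the index date
  counts as within 90 days.
* **Unique dates** pool inpatient and outpatient primary events.
* Events dated on or after the index date are rejected at load time — the
  index must never see follow-up information.

## Model fitting

All candidate predictors enter one Cox proportional hazards model for
all-cause mortality within the development horizon (default 10 years, with
1- and 5-year variants available through `horizon_censor()`). The model is
penalized with the elastic net, which performs variable selection (the lasso
part) while keeping the heavily collinear granularity/dimension families
stable (the ridge part). Specifics:

* **Mixing weight** `alpha = 0.5` by default, exposed as a parameter. The
  method needs a strict mix: pure lasso picks one member of a collinear
  family arbitrarily, pure ridge selects nothing.
* **Penalty grid**: 100 log-spaced values from `lambda_max` (the smallest
  penalty with the all-zero solution) down to `lambda_max / 100`.
* **Selection criterion**: 10-fold cross-validation, folds stratified on the
  event indicator and deterministic given the seed. For each penalty the
  held-out linear predictors are scored with Harrell's concordance index per
  fold and averaged with event-count weights; the penalty with the highest
  cross-validated c-index wins, ties going to the larger penalty (the
  sparser model). Averaging fold-wise c-indices (rather than pooling held-out
  predictions) keeps fold predictions on their own scales from being
  compared with each other.
* **Ties**: Breslow approximation throughout, in the penalized fits, the
  partial-likelihood oracle (`cox_partial_loglik()`), and every unpenalized
  `survival::coxph()` call.
* **Standardization**: binary dummies are standardized internally for
  penalization and coefficients returned on the 0/1 scale (the convention of
  penalized-regression software); configurable off. Whether to standardize
  binary indicators is genuinely open — standardization penalizes rare codes
  less per unit of prevalence, which suits a scheme built around rare but
  informative codes.
* **Solver**: coordinate descent via glmnet with convergence threshold
  `1e-7`; fold fits, which only *rank* penalties, use `1e-5`. Solutions are
  verifiable against the elastic-net KKT subgradient conditions with
  `kkt_check()`, which computes the Breslow score vector independently of
  the solver.
* **Degenerate columns**: a predictor with fewer than two positive subjects
  in the data a given fit sees (possible inside cross-validation folds, or
  at small cohort sizes where the prevalence filter admits single-carrier
  variants) is excluded from that fit — its coefficient is zero. Such a
  column is unidentifiable anyway, and once standardized its huge scale
  destabilizes coordinate descent.

The subject's index value (`mdci_score()`) is the Cox linear predictor: the
sum of selected coefficients over the predictors the subject is positive on.
Scores are categorized at the development cohort's 25/50/75% quantiles
(`categorize_index()`, boundaries inclusive downward); the cutoffs are frozen
and reused unchanged on validation cohorts. With heavily zero-inflated score
distributions quantile cutoffs can tie; tied cutoffs simply leave the
squeezed category empty rather than failing.

## Validation toolkit

* `harrell_cindex()`: concordance over usable pairs under right censoring
  (the earlier observed time must be an event; tied times are usable only
  when exactly one is an event), score ties counting 0.5. Implemented as an
  O(n²) pair scan in C++ and tested against an exhaustive R enumeration and
  against `survival::concordance()`.
* `bootstrap_ci()`: percentile intervals over subject-level resamples
  (default 1000 replications), deterministic given the seed; undefined
  resamples are redrawn and counted.
* `calibration_curve()`: fits a one-covariate Cox model on the evaluation
  cohort with the score as predictor, computes each subject's predicted
  survival at the horizon from the Breslow baseline cumulative hazard, bins
  subjects at fixed predicted-survival cutoffs (default 0, 50, 55, …, 90,
  100%), and compares the per-bin mean prediction with the Kaplan–Meier
  estimate inside the bin. Empty bins are omitted; bins whose KM curve is
  undefined at the horizon (censored tail) report `NA`.
* `stratified_hazard_ratios()`: per-stratum unpenalized Cox fits of the
  category indicators against the lowest category, Wald 95% intervals,
  follow-up censored at one year by default. A contrast needs at least five
  events in each arm, otherwise it is reported `NA` — a minimum-events rule
  standing in for the (unstated) convention that small strata are
  inestimable.
* `index_correlation()`: Spearman by default, because index scores are used
  ordinally; Pearson available.
* `charlson_index()`: the occurrence-only comparator — distinct mapped
  conditions, each counted once, weights summed; primary or secondary
  position, any setting, same lookback. The shipped mapping is the Quan et
  al. (2005) ICD-10 enumeration with the original Charlson weights, as an
  editable CSV; no supersession hierarchy is applied (a plain weighted sum).
  For cancer cohorts `apply_outcome_exclusion()` first removes the index
  cancer's codes, and metastasis codes (C77–C80) in subjects carrying the
  index cancer code.

## The synthetic register

No patient-register data can ship with a package like this, so `mdci`
includes a generator whose *hazard acts through the same feature space the
index models*. That makes parameter recovery a meaningful test: if the
pipeline works, it must find the planted effects and approach the oracle
discrimination of the true linear predictor.

Per subject: active conditions are Bernoulli draws from per-condition
prevalences (default declining geometrically 0.25 → 0.0125 over 50
conditions); each active condition carries a Gamma(2, 2) severity factor and
emits a Poisson number of care episodes (default rate 0.5/year over a
10-year lookback, scaled by severity). Severity also lengthens inpatient
stays (`1 + Poisson(3 × severity)` days) and biases episode timing toward
the final pre-index year — so duration, frequency and recency signals are
correlated, as they are clinically, but not collinear. Episodes are
inpatient with probability 0.3, and with probability 0.2 an episode also
codes one of the subject's other conditions as secondary. Codes come from a
deterministic synthetic table with valid ICD-10 shapes spread across
chapters and recorded at 3–5 characters, so granularity expansion is
exercised; 3-character bases are unique, so each condition's own variant is
identifiable.

The true linear predictor evaluates a configurable effect list —
(condition, dimension, log hazard ratio) triples — against the subject's
realized features; the default plants 12 effects of |log HR| ≥ 0.5 across
all four dimension families. Survival is exponential with per-year hazard
`0.0143 × exp(eta)` (calibrated once so the default cohort shows ≈30%
10-year mortality, a realism guide for an elderly male cohort), with
exponential dropout (0.01/year) and administrative censoring at 10 years.
Index dates are uniform over 2008–2014 so temporal development/validation
splits (default 85/15 by index date) are meaningful.

What the generator does **not** emulate: chapter-level code frequencies of
any real register, ICD coding-practice drift over time, competing causes of
death, emigration, or primary-care contacts. Passing tests on this generator
therefore demonstrate that the machinery is correct and that the index
recovers multidimensional signal *when it exists* — they do not reproduce, or
claim to reproduce, any real-register performance figure.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full pipeline at
n = 20,000 subjects / 50 conditions (development) with an independent
4,000-subject validation cohort — large enough that concordance estimates
are stable to well under 0.01 — plus a 50,000-subject calibration
self-consistency check and a 5,000-subject end-to-end determinism check.
Cross-validation keeps the full 10 × 100 fold-penalty grid at these sizes.

Degenerate inputs are handled explicitly: all-censored outcomes, folds
without events, constant scores (calibration falls back to the null model;
correlation is refused as undefined), empty cohorts (0-row design with the
full column set), tied quantile cutoffs, malformed codes (dropped and
counted at load), and stays straddling the lookback boundary (clipped).

## Known limitations

* The prevalence filter counts subjects, not events; an event-counting
  register convention would shift the vocabulary slightly.
* The vocabulary's optional pruning rule (dropping a child variant whose
  supporting subject set equals its parent's) is a conservative dialect of
  "pruning of unnecessary codes"; it is off by default.
* The elastic-net mixing weight is a default, not an estimate; sensitivity
  to `alpha` should be checked per application.
* Charlson scoring omits the condition-hierarchy refinements some
  implementations apply (e.g. severe liver disease superseding mild); with
  the original weights this biases the comparator upward slightly in
  subjects coded at multiple severities.
* The bootstrap resamples the evaluation step only; the index itself is
  frozen at validation time, matching a temporal-split design, so the
  intervals do not propagate model-selection variability.
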