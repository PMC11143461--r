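---
title: "Methods: externally validating an ED six-month mortality screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: externally validating an ED six-month mortality screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestval)
```

## The problem

Emergency departments see most older adults in their last six months of
life, yet have few pragmatic ways to recognise them. Two screens compete:
a binary *serious illness* flag (any life-limiting ICD-10 diagnosis in the
past year, often extended by an age ≥ 80 criterion) and an EHR-computable
logistic risk score of the GEST family, which estimates each encounter's
6-month mortality probability from demographics, early-visit vitals and
labs, utilization and diagnosis history. `gestval` implements the whole
machinery needed to validate such a score at a new institution and to
compare it with the diagnosis-based screen.

## The risk model as data

The model is a *specification*, not code: per covariate an imputation
value, a standardization mean/SD (raw clinical units) and a log-odds
coefficient, plus an intercept. Scoring is impute → standardize →
linear predictor → logistic. This keeps the engine independent of any
particular coefficient set: transcribing a published model, or fitting a
synthetic stand-in, are both just JSON files (`read_gest_model()`,
written with full double precision so a round trip is bit-exact).

Three conventions had to be pinned where the field leaves them open:

* **Binary covariates** carry an explicit per-entry `standardize` flag.
  Both conventions (z-scoring 0/1 flags or passing them through) exist in
  practice; the shipped specification passes flags through, and the flag
  makes either behaviour testable.
* **Imputation neutrality**: when a covariate's imputation value equals
  its standardization mean, a missing value scores exactly as the mean
  would. This is asserted as an identity in the tests.
* **No probability clipping**: full-precision probabilities are reported;
  rounding is a display concern.

The derivation-study coefficient/imputation/standardization values are not
redistributed here; the shipped `gest_model_synthetic()` is a synthetic
placeholder with clinically plausible directions of effect (risk rises
with age, BUN, RDW, heart rate, oxygen use, admissions and the cancer
flags; falls with hemoglobin, systolic pressure and lymphocyte count).
Outpatient cardiovascular medication data is typically unavailable on
external validation; the covariate then scores through its imputation
value for every record — and, being constant, is held at its original
coefficient during refitting rather than estimated.

## Feature extraction rules

* **Vitals**: only observations within the first 240 minutes of the visit
  (configurable) — mean heart rate, minimum systolic pressure, and any
  non-room-air oxygen-device observation. Absent kinds yield absent
  covariates; negative offsets are an error, since they can only be an
  upstream timestamp bug.
* **Labs**: the earliest resulted value per analyte, mirroring
  screening-at-presentation; ties on result time break to the lower row
  index and are noted. "Red cell distribution width" is taken as the
  standard CBC analyte (RDW).
* **Admissions**: count in `[arrival - 365 d, arrival)` — closed on the
  left (an admission exactly a year before counts), open at arrival.
  The bound had to be fixed somewhere for reproducibility.
* **Diagnosis-history flags** match ICD-10 codes by prefix, strictly
  before arrival, by default over all available history (the 1-year
  lookback is a property of the serious-illness screen, not of the model
  covariates); the syncope/cerebrovascular flag comes only from codes
  attached to the index encounter.

The serious-illness screen uses a *closed* 1-year window
`[arrival - 365 d, arrival]` — index-day codes count — and a single
qualifying category suffices. Its catalog is a YAML file of prefix lists
(a transcription at code-family level of the commonly used
life-limiting-illness definitions) and is deliberately overridable,
because institutional code lists differ and that variation is itself a
known limitation of diagnosis-based screening.

## Statistical components

**Discrimination.** AUROC via midranks (ties credit ½), variance by the
DeLong placement-value estimator, CI = estimate ± 1.96·SE truncated to
[0, 1]. The tests require exact equality with a brute-force pairwise
oracle on all small inputs and 93–97% empirical coverage over 1000
simulated binormal cohorts of n = 2000. Strata missing an outcome class
are reported as skipped rather than failing the whole analysis.

**Calibration.** Risk groups are score deciles by default (the published
analyses say "risk groups" without a count; ten is the field's default)
or fixed edges, in which case empty groups stay visible with count 0 and
an undefined rate.

**Updating.** Recalibration fits only an intercept shift `delta` by
offset logistic regression — by construction it cannot change
discrimination, which the tests assert as an identity. A slope variant
exists behind a flag, off by default. Refitting is IRLS on the
standardized covariates, converged when the largest coefficient change
falls below 1e-8 (or 100 iterations); coefficients diverging past ±15 on
the standardized scale are reported as separation, naming the covariate.
The refit's training log-likelihood must dominate the original
specification's (MLE dominance), another tested identity.

**Screening characteristics.** Strict ">" thresholding (a "> 5%" rule is
literally `score > 0.05`). Proportion CIs use the Wilson score interval,
likelihood-ratio CIs the standard log method; the method is recorded in
the output and configurable, since published tables rarely state theirs.
Ratios with zero denominators are `NA`, never fabricated. The Bayes
identities (`PPV = sens·prev/frac_pos`, `NPV = spec·(1-prev)/(1-frac_pos)`)
are exposed as `reconstruct_characteristics()` — they are what makes a
printed screening table internally consistent, and the acceptance tests
verify a published table cell-by-cell this way, excluding the few cells
where 3-digit input rounding moves the identity by more than one unit in
the last printed digit.

**Decision curves.** Net benefit `TP/n − (FP/n)·p_t/(1−p_t)` on a default
grid of 0.01–0.50 by 0.01; `p_t ≥ 1` is rejected (undefined exchange
rate). The binary screen keeps its fixed classification at every
threshold; treat-all and treat-none are the reference strategies, and
treat-none is identically zero.

**Survival.** Kaplan-Meier on first encounters per patient (ties on the
arrival timestamp break to the lower encounter id), delegated to
`survival::survfit` behind `km_estimate()`, with the standard convention
that records censored at *t* remain at risk for deaths at *t*. "Six
months" is 183 days, configurable, since the day count is conventional.
With complete follow-up, `1 − S(183)` equals the binary 6-month outcome
exactly — a cross-module consistency the tests enforce.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions the analysis assumes:
ages from a truncated normal (65–105, mean 77, SD 8, ~38% aged 80+),
~13.8% first-visit 6-month mortality (the outcome-model intercept is
tuned to the target by bisection on [-30, 30]; an unreachable target is
an explicit error naming those bounds), a 2017–2021 arrival window with
mortality ascertained through 2022-12-31, geometric repeat visits
averaging ~2 per patient, and per-covariate missingness at placeholder
rates of 2–10% (institution-specific values are not public; replace them
when known).

Dependence among covariates comes from a single latent severity factor
(loading 0.45 by default) rather than a full copula: each continuous
covariate mixes the factor with independent noise in the clinically
harmful direction, and diagnosis carriage, oxygen use and admission
intensity tilt on it too — enough correlation structure to exercise
discrimination and calibration realistically, at minimal complexity.
Diagnosis category base rates were set to plausible elderly-ED
prevalences, rise with age, and code dates are spread so that a fraction
falls outside the 1-year lookback. Deaths within six months get a date
uniform on 1–183 days after first arrival; a configurable quarter of
survivors die later, exercising right-censoring. Visits after death are
removed.

Because outcomes are Bernoulli draws from the true model applied to the
*extracted* first-visit features, the loop closes: refitting on a large
self-generated cohort must recover every estimable coefficient within
3 SE, and recalibration must drift to ~0 — both are acceptance tests, run
on a 20 000-patient cohort generated without missingness so the recovery
problem is correctly specified.

What it does *not* emulate: realistic ICD code frequencies and coding
practice, calendar-time shifts (the COVID-era mortality bump), informative
missingness, measurement error structure beyond independent noise, and
patient-level correlation richer than one severity factor. Passing tests
therefore show the *machinery* is correct under the stated mechanism, not
that any particular institution's data behaves this way.

## Problem sizes and runtime choices

The test suite uses a shared 20 000-patient cohort (≈36 000 encounters)
for parameter recovery and stratum nesting, 1000 × 2000 simulations for
interval coverage, 300 random small inputs for the AUROC oracle, and
1500-patient cohorts for structural checks; the acceptance script runs
the full pipeline on a fresh 20 000-patient cohort. These sizes keep every
Monte-Carlo check comfortably concentrated (binomial SEs well inside the
asserted bands) while the whole suite runs in about a minute.

## Known limitations

* The shipped model specification is synthetic; conclusions about the
  real score require transcribing its published values.
* The serious-illness catalog is a prefix-level transcription of common
  code families, not an institution's vetted list.
* Net-benefit curves are reported without bootstrap uncertainty.
* No paired test between two correlated AUROCs is provided (validation
  reports CIs, not contrasts).
* The generator's covariate marginals are plausible but not fitted to any
  real ED population.
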