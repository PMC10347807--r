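---
title: "Methods: medication reviews and prescribing change in primary-care records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: medication reviews and prescribing change in primary-care records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(medrev)
```

# Overview

`medrev` implements a reproducible pipeline for studying medication reviews
in UK-style primary-care electronic health records of people aged 65 and
over. Starting from four flat tables (patients, practices, clinical events,
issued prescriptions), it answers two questions for a single study year:

1. **Who receives a medication review, and how quickly?** A closed cohort is
   followed from the start of the year until the first review (the event) or
   censoring; a Cox model with practice-clustered robust variance relates
   the hazard of review to baseline characteristics.
2. **What changes around the review?** For each reviewed patient, the set of
   repeat medicines covering a window before the review is compared with the
   set covering a window after it, giving stopped / started / continued
   medicines and the change in the maximum concurrent prescription count,
   modelled by cluster-robust linear regression.

Because licensed record data cannot be redistributed, the package also ships
a synthetic-data generator that emulates the source tables with *planted*,
exactly recoverable effects. Every pipeline stage is validated against this
ground truth in the test suite.

# Data model

`read_table()` parses the four tables against a fixed data dictionary
(`mr_schemas`): typed columns, ISO dates, explicit `"missing"` levels for
enum fields whose values can be absent or out of vocabulary, and `NA` as the
universal missing sentinel. Duplicate patient or practice identifiers are
integrity errors. Clinical code lists (`load_codelist()`) are two- or
three-column files (`code`, `label`, optional `flags`); a code repeated with
conflicting flags is rejected.

A medicine is identified by the pair (drug substance, formulation), folded
to lower case and whitespace-normalised (`medicine_key()`): the same
substance in two formulations counts as two medicines, while cosmetic
spelling differences do not split one medicine into several.
`filter_medicinal()` removes rows that never enter exposure computation:
immunological products (BNF chapter 14), anaesthesia (chapter 15), rows with
no BNF chapter, and products matching a bundled non-medicinal term list
(dressings, devices, test strips).

# Exposure: coverage intervals and overlap counts

Each prescription issue covers the closed day interval
`[issue_date, issue_date + duration - 1]`. The duration is
`round(quantity / daily_dose)`, clamped to 1–183 days; when quantity or dose
is missing or non-positive, the fallback is the median computable duration
of the same medicine, then a formulation-class default (28 days for all
bundled classes). The 183-day cap keeps implausible entries (for example a
quantity entered as a pack count) from fabricating year-long exposure.

Per patient and medicine, overlapping *or adjacent* intervals are merged
(`build_coverage()`), so chained refills form one continuous episode; a gap
of one or more uncovered days splits episodes. The *prescription count* on a
day is the number of distinct medicines whose coverage contains that day,
and the count for a window is the maximum over its days, computed by an
endpoint sweep (`max_overlap_count()`): clip intervals to the window,
re-merge per medicine, then scan sorted endpoints with a running counter.
The test suite proves the sweep equal to brute-force day-by-day counting on
1,000 random instances. Counts are banded as 0, 1, 2–4, 5–9, 10–14, 15–19,
20+ (`count_band()`) for description and modelling.

# Cohort and time-to-first-review

Eligibility at baseline (1 January of the study year, configurable):

* aged 65+ in the study year (by birth year),
* recorded sex male or female,
* at least one year of research-quality follow-up before baseline — both the
  registration date and the practice's up-to-standard date at or before
  baseline minus 365 days,
* active at baseline: no earlier death or transfer-out, and the practice
  still collecting data,
* for the incidence analysis only: at least one medicine with coverage
  spanning the baseline date.

Follow-up runs to the earliest of death, transfer-out, the practice's last
collection date, the first review, and 31 December. The first review is an
event; everything else censors. A review on the same day as death or
transfer still counts as an event; a review on day 0 is shifted to 0.5 days
in the Cox fit to avoid a degenerate risk set.

Baseline covariates: 10-year age band, sex, Townsend deprivation quintile
(person-level where available, otherwise practice-level), region, care-home
flag, a review in the previous calendar year, the baseline prescription
count band, diagnosis flags (any matching code ever recorded on or before
baseline) and drug-group flags (any matching prescription in the 183 days up
to baseline).

Reviews are clinical events whose code is in the review code list
(`find_reviews()`). The *conservative* definition keeps only reviews
recorded during face-to-face or telephone consultations and drops codes
flagged as reviews of a specific medicine or condition (warfarin, asthma,
lithium); it always yields a review proportion less than or equal to the
main definition's.

# Before/after comparison

Windows are fixed day counts relative to the review date R, with the review
day belonging to the *after* window (prescriptions issued at the review
consultation are consequences of it): `3m3m` = [R−91, R−1] vs [R, R+91]
(primary), `6m6m` (183 days), `3m1to4m` = [R−91, R−1] vs [R+30, R+121], and
`1m1m` (30 days). Calendar months are deliberately not used: fixed integers
make windows reproducible and symmetric. A medicine is "in a window" when
one of its coverage intervals intersects it, so a long prescription issued
earlier still counts. By default only repeat-flagged coverage enters,
suppressing short-course noise.

Patients whose follow-up ends before the after window closes are flagged
`insufficient_followup` and excluded from summaries. The change in count
(`delta = count_after - count_before`) is summarised after two further
exclusions, applied in order and exactly once (`delta_counts()`): records
with `count_before == 0`, then records more than 3 SDs from the mean delta
of the remainder. `rank_top_changed()` counts, per medicine, the people who
stopped or started it and returns the top 20 by stopped + started.

# Models

* `fit_cox()` — proportional-hazards partial likelihood with the **Efron**
  tie approximation (day-granular data guarantee ties; Breslow is available
  for cross-checks) and a cluster-grouped sandwich variance over practices.
  Reference levels: age 65–74, male, Townsend quintile 1, Scotland, count
  band "1". Three specifications: unadjusted (per covariate), age–sex
  adjusted, fully adjusted. Separation (|log HR| > 15) and single-level
  covariates are reported explicitly.
* `check_ph()` — scaled-Schoenfeld score test (`survival::cox.zph`,
  Kaplan–Meier time transform), flagging terms at p < 0.01, skipped with a
  warning below 10 events; `loglog_curves()` exports log(−log S(t)) curves
  for visual audit.
* `fit_linear_change()` — least squares for delta with CL/HC1 cluster-robust
  standard errors (with one observation per cluster these equal the HC1
  heteroskedasticity-robust errors exactly, a property the tests check to
  1e-8). Reference levels: count band before review "5-9", face-to-face,
  GP. The overall mean delta and its cluster-robust CI come from an
  intercept-only fit.

All confidence intervals are estimate ± 1.96 SE on the estimation scale;
p-values display as three decimals with "<0.001" flooring.

# The synthetic generator

`simulate_ehr()` draws a population whose demographic mix (sex, age bands,
ethnicity missingness, regions, deprivation, 1.9% care-home prevalence,
55.4% prior-year review) matches published descriptions of this population,
then gives each patient a persistent portfolio of medicines whose size
follows the configured count-band distribution. Portfolio medicines refill
on a 28-day cycle with up to 3 days of *early-only* jitter, so coverage
chains without gaps; short 7-day non-repeat courses and occasional
non-medicinal products (dressings, vaccines) are injected to exercise the
filters.

Review timing is exponential: patient *i* has hazard
`r0 * exp(lp_i)`, where `lp_i` adds the planted log hazard ratios
(care home log 1.5, prior review log 1.83, and a count-band gradient up to
log 1.64) and `r0` is solved numerically so the *expected* within-year
review fraction among the eligible prescribed population equals a target
(0.516 by default). Because real follow-up is censored by deaths and
transfers, the observed fraction sits slightly below the target.

At the review, each portfolio medicine stops independently with probability
`p_stop` (all its issues are truncated to end before the review day) and a
Poisson number of new medicines starts on the review day, with the
per-patient rate chosen as `delta + n_i * p_stop` so the expected change in
count equals the planted `delta` (0.13 by default) *for every patient* —
which also makes the stopped/started sets in the truth sidecar exactly
recoverable by the pipeline. A per-band override (`delta_by_band`) plants
count-dependent effects, e.g. negative change for people on 10+ medicines.

Scope and limits: one study year; no dose changes or within-class switches;
no seasonality; portfolios are static apart from the review perturbation;
missingness is planted only where the pipeline consumes it (sex, Townsend,
dates, vaccine/dressing rows). The generator is a validation instrument,
not a population model.

# Validation design and problem sizes

The acceptance tests (in `tests/testthat/test-acceptance.R`) fix sizes and
tolerances a priori:

* **Oracle equivalence** — 1,000 random instances, exact match between
  sweep and brute force.
* **Hand-computed fixture** — a bundled 10-patient toy dataset
  (`mr_extdata("toy")`) with worked-by-hand golden files for coverage,
  cohort, first reviews, change sets and the exclusion tally.
* **Cox recovery** — 20 seeds at n = 20,000 patients / 100 practices; each
  planted HR within 10% relative error in ≥ 90% of seeds; pooled 95% CI
  coverage of truth 90–100%. The recovery configuration raises care-home
  prevalence to 10%: at the natural 1.9% (~300 patients, ~150 events) the
  asymptotic SE of the log HR is about 0.09, so a 10% relative-error
  criterion would fail by design in roughly a third of seeds even with a
  perfect estimator; at 10% prevalence the SE is ~0.04 and the criterion is
  a genuine test of the pipeline rather than of sampling noise.
* **Null calibration** — 100 replicates at n = 5,000 with all planted
  effects zero; per-term CI coverage of HR = 1 and of delta = 0 within
  exact binomial 99% bounds (89–100 of 100).
* **Mean-change recovery** — n = 32,000 patients, giving over 10,000
  reviewed patients in the change analysis; pipeline mean delta within 3
  Monte-Carlo SEs of the planted 0.13; planted negative per-band effects
  recover their signs in the band coefficients.
* **Flow integrity and variance properties** — manifest counts reconcile
  exactly at every stage; conservative ≤ main review proportion;
  cluster-robust = heteroskedasticity-robust with singleton clusters;
  robust ≥ naive SE under cluster correlation.

# Worked example

```{r example}
sim <- simulate_ehr(sim_config(n_patients = 2000, n_practices = 20), seed = 1)
rx  <- filter_medicinal(sim$prescriptions)
cov <- build_coverage(rx)
rcl <- mr_review_codelist()
reviews <- find_reviews(sim$events, rcl)
ch <- build_cohort(sim$patients, sim$practices, sim$events, rx, cov, reviews,
                   codelists = mr_default_codelists(), review_codelist = rcl)
ch$counts
```

```{r cox}
fit <- fit_cox(ch$cohort,
               c("age_band", "sex", "baseline_count_band",
                 "prior_year_review", "care_home"))
fit$table[, c("term", "hr", "hr_low", "hr_high")]
```

```{r change}
sel <- select_population(sim$patients, sim$practices)
rec <- change_records(cov, first_review(reviews), sel$eligible,
                      window_spec("3m3m"))
rec <- merge(rec, sel$eligible[, c("patient_id", "practice_id")],
             by = "patient_id")
dc <- delta_counts(rec)
dc$tally
fit_linear_change(dc$retained)$mean_delta
rank_top_changed(rec, k = 5)
```

The orchestrated form of the same run is `run_all()`, which writes every
stage output plus a manifest (seed, configuration hash, row counts at every
stage) to a directory; identical configuration and seed give identical
outputs. A thin command-line wrapper lives at
`system.file("cli", "medrev.R", package = "medrev")`.

# Limitations

The pipeline analyses a single study year with a closed cohort; it does not
model repeated reviews beyond the first, dose or within-class changes,
competing risks (death censors rather than competes), or multiple
imputation of missing covariates. Counts are based on issued prescriptions,
which overstate consumption when patients do not take what is issued. The
before/after comparison is descriptive: changes around a review are not
causally attributed to it.
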