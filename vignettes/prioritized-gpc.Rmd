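---
title: "Prioritized generalized pairwise comparisons: model, scoring rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritized generalized pairwise comparisons: model, scoring rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbenefit)
```

## The estimand

A prioritized generalized pairwise comparison (GPC) summarises a two-arm
trial with several outcomes of different types — here overall survival,
locoregional recurrence, distant metastasis, complete remission,
change in global health-related quality of life, and maximum toxicity
grade — into one patient-centred contrast. Every arm-A patient is compared
with every arm-B patient on the highest-priority endpoint first; a pair with
no decidable difference there moves down the ranked list until one patient
wins or the list is exhausted. Writing $W_B$ and $W_A$ for the total winners
over all $N = n_A n_B$ pairs, the package reports

* the **net treatment benefit** $\mathrm{NTB} = (W_B - W_A)/N$, an estimate
  of $P(\text{B better}) - P(\text{A better})$ under the stated priorities,
  in $[-1, 1]$ with 0 under no effect; and
* the **win ratio** $W_B / W_A$, 1 under no effect.

All $n_A n_B$ ordered pairs are evaluated deterministically. Descriptions of
the method sometimes speak of patients "paired at random"; the all-pairs
U-statistic is the standard estimator of the same pair-level probabilities
and removes the sampling noise a random pairing would add.

## Pair-scoring rules

**Time-to-event with a clinical-relevance margin.** For survival (higher
better) a patient wins when their *observed* time — event or censoring —
exceeds the other patient's observed *event* time by at least the margin
$\tau$ (default 1 month). This is Gehan scoring: a censored winner is
legitimate because their survival beyond the loser's death was actually
observed. Two events less than $\tau$ apart (including exact ties) are
*neutral*; configurations whose ordering would depend on what happened after
a censoring time are *uninformative*. For incidence endpoints (lower
better), the same rule applies with the roles of "later event" and "longer
event-free observation" exchanged, with one addition: a pair in which both
patients remained event-free throughout observation is neutral, not
uninformative — both experienced the same (favourable) outcome.

The phrase "pairs of patients with censoring … were considered neutral" can
also be read more strictly as discarding every pair containing a censored
observation. That reading would make essentially all survival pairs
non-contributory in a cohort with ~85% five-year survival, so Gehan scoring
is the default; the strict variant is available everywhere via
`censoring = "neutral"` and both are covered by the test suite. Which
variant the original analysis used is not decidable from the published
description.

Neutral and uninformative verdicts are tallied separately at every level but
cascade identically (both are "ties" for the purpose of moving down the
hierarchy). A win requires a difference of *at least* $\tau$: differences of
exactly one month are decisive, because neutrality is defined by a
strictly-smaller-than-$\tau$ difference. With $\tau = 0$ and no censoring
the survival rule reduces to the strict Mann–Whitney kernel, a property the
tests exercise.

**Binary.** Response beats non-response; equal values are neutral; a missing
value on either side is uninformative.

**Ordinal.** Strict inequality in the favourable direction wins; used for
maximum CTCAE grade (lower better, grade 0 allowed) and quality-of-life
change scores (higher better).

**Competing risks in pair scoring.** For recurrence/metastasis levels, death
without the event ends observation: the patient is treated as event-free
censored at the death time. A joint model of death and recurrence is *not*
imposed at the pair level; the descriptive cumulative-incidence summaries do
account for death as a competing risk (below).

## The default hierarchy

`cao_aro_aio12_hierarchy()` ranks: overall survival ($\tau = 1$ month),
locoregional recurrence ($\tau = 1$), distant metastasis ($\tau = 1$),
complete remission (binary), global-health change (ordinal), maximum
toxicity grade (ordinal, lower better).

The quality-of-life level uses the *change* in the transformed QLQ-C30
global-health scale (mean of the two 7-point items, linearly transformed to
0–100) from baseline to the latest complete follow-up at $\ge 24$ months.
Published analyses do not state whether the hierarchy level used item 29,
item 30, their combined scale, or absolute rather than change scores; the
combined change score is the package's choice because it matches the scored
scale convention and the change-from-baseline framing of the
quality-of-life tables, and item-level contrasts remain available through
`per_endpoint_delta()` on an ordinal endpoint. Patients without an eligible
baseline/follow-up pair are uninformative at that level and simply cascade.

`decompose_conditional()` reports each level's wins both as a fraction of
all pairs and as a fraction of pairs reaching the level, because published
summaries of "the probability of remission after eliminating pairs decided
on oncological outcome" do not state which denominator they use.

## EORTC scoring

Raw item responses are transformed by the standard linear rule: with
$RS$ the mean of a scale's items and $r$ the item range,
functional scales score $(1 - (RS-1)/r) \times 100$ and symptom/global
scales $((RS-1)/r) \times 100$. A scale is scored only when *all* its items
were answered, separately at baseline and follow-up; eligibility requires a
complete baseline and a complete follow-up at $\ge 24$ months, taking the
latest such visit. Any nonzero change counts as improvement or worsening
according to polarity — no minimally-important-difference threshold is
applied. Between-arm comparisons of the raw change scores use the Welch
t-test by sex (`pooled = TRUE` switches to the equal-variance test; the
published tables say only "t-test"), unadjusted for multiplicity. Whether
the original tests used change scores or baseline-adjusted follow-up scores
is not stated; change scores are assumed. Scale definitions (item lists,
ranges, polarities) ship as an editable JSON file covering the QLQ-C30 and
QLQ-CR29 scales used in long-term colorectal follow-up reporting.

## Toxicity tables

A patient contributes their *maximum* grade per item over follow-up visits
(matching "highest toxicity per patient" table semantics; whether the
original tables count per visit or per patient is not stated, and the
per-patient maximum is assumed). Percentages are rounded to integers and the
between-arm difference columns are computed on the rounded values, matching
the integer "+8/−4" presentation style.

## Inference

Confidence intervals come from a stratified nonparametric bootstrap
(resampling patients with replacement within each arm, percentile
intervals); p-values from arm-label permutations with the add-one estimator
$p = (1 + \#\{|\mathrm{NTB}^*| \ge |\mathrm{NTB}|\})/(1 + n_{perm})$, which
is never exactly zero. The published analysis does not name its
variance estimator, so no attempt is made to reproduce its exact interval
bounds; resampling was chosen because its operating characteristics are
directly testable by simulation (type-I error within [0.03, 0.07] at the 5%
level over 500 null replicates; bootstrap coverage near 95% on binary
endpoints). Defaults are 2000 resamples of each kind; both routines reuse a
precomputed patient-by-patient verdict matrix per level, so resamples only
index into it rather than rescoring pairs. Degenerate bootstrap resamples
are included, not rejected. A comparison of two identical arms returns NTB
exactly 0, win ratio 1, and permutation p exactly 1.

## The synthetic cohort generator

No patient-level data accompany the 5-year report, so `simulate_cohort()`
states a synthetic world calibrated to the published arm-level figures, and
the defaults are fixed once:

* arm sizes 156/150;
* exponential overall survival with hazards $-\log(0.858)/60$ and
  $-\log(0.842)/60$ per month (the published 5-year rates);
* per-patient administrative follow-up uniform on [58, 62] months — this
  reproduces the reported median 60 (IQR 58–62) directly rather than
  modelling calendar accrual;
* recurrence/metastasis as marginal Bernoulli events (probabilities
  0.069/0.059 and 0.217/0.2376) with event times uniform over follow-up and
  observation truncated at death;
* remission Bernoulli 0.21/0.27;
* complete baseline QLQ-C30 for everyone; one follow-up visit at month
  U(24, 36) for surviving patients, removed with probability 0.4 (the ~60%
  availability of long-term patient-reported outcomes), with a +5-point mean
  drift in global health in both arms (improvement was reported in both
  arms, with small between-arm differences);
* per-patient maximum toxicity grade drawn from the published
  highest-toxicity-per-patient distributions, recorded as a single
  "overall" toxicity item.

What the generator does **not** emulate: any dependence between endpoints
(none is reported, so independence is assumed and stated); per-item adverse
event profiles (item-level toxicity tables are exercised on constructed
fixtures); CR29 responses (scoring handles them when supplied); non-random
quality-of-life missingness. A green calibration test therefore establishes
that the pipeline recovers the stated marginal structure, not that it
reproduces the trial's joint distribution — the published survival curves,
interval bounds and p-values are not reproducible without the patient-level
data, and the test suite does not pretend otherwise.

`simulate_null_cohort()` replaces every arm-B parameter with arm A's,
keeping sizes, for type-I-error studies. All generation is deterministic
given a seed.

## Numerical and interface choices

* Times are months as decimals; missing time-to-event fields invalidate a
  row (no imputation). Validation reports offending row numbers.
* Verdict matrices are integer-coded; the cascade is pure integer
  arithmetic, so engine results are exactly reproducible and are checked
  *exactly* against an independent brute-force double loop on random
  cohorts.
* Reporting precision follows the field's conventions (deltas to 4
  decimals, win ratios to 2, win probabilities as percentages to 2
  decimals) in `print()` methods only; stored values are full precision.
* Configuration files (hierarchy, simulation parameters, scale definitions)
  are JSON; the report writer emits `report.json` (validated against a
  shipped field schema plus conservation identities) and a plain-text
  summary.
* A win ratio with zero comparator winners is reported as `Inf` with a
  warning rather than an error.
* Test simulations are scaled down from the sizes a methods paper would run
  (e.g. 150 coverage replicates rather than thousands) to keep the suite
  fast; the acceptance checks for size calibration run at 500 replicates
  with 500 permutations each.

## Known limitations

Two arms only; no stratified or matched GPC; no Peron (survival-curve
weighted) scoring for censored pairs; no interval censoring; no multiplicity
adjustment (deliberately, matching the exploratory character of the source
analysis); the bootstrap is percentile-only, with asymptotic U-statistic
variances left as an extension point.
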