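---
title: "Methods: claims-based JIA epidemiology and biologic treatment patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based JIA epidemiology and biologic treatment patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jiaepi)
```

## The analysis model

The package operationalises a retrospective claims-database design for
juvenile idiopathic arthritis (JIA): claims coverage 2011–2020 (the half-open
study window `[2011-01-01, 2021-01-01)`), patient identification 2012–2019,
and a dialect switch from ICD-9-CM to ICD-10-CM at exactly 2016-01-01. Four
flat tables carry everything: a beneficiary registry (one row per enrollment
interval), coded diagnoses, pharmacy fills with days supply, and annual
under-16 population denominators by age group and sex. All intervals are
half-open `[start, end)` and all dates ISO-8601.

### Case definition and cohorts

A person enters the prevalent cohort when all four criteria hold:

1. **Diagnosis codes** — at least one inpatient JIA code, or three outpatient
   JIA codes on distinct service dates spanning at most 365 days. The *index
   date* is the first in-window JIA code; the qualification window is anchored
   there and may extend into 2020. The design reserves 2020 as a
   minimum-observation year: requiring the whole qualifying triple to sit
   inside 2012–2019 would silently drop late-2019 onsets and bias incidence
   downward, so only the index code itself must fall in the identification
   window.
2. **Enrollment** overlapping the identification window.
3. **Age** — under 16 completed years at index. A configuration switch
   (`age_cutoff = 17`) emulates an "age 16 or below" reading, since published
   denominators are sometimes labelled either way.
4. **NSAID exposure** — a grace-merged NSAID episode covering more than 14
   days (i.e. ≥15 covered days) whose coverage intersects the 365 days after
   the first diagnosis. Whether the episode must *start* inside that window
   is not derivable from the design text; the default is *intersect*
   (`nsaid_rule = "start_within"` gives the stricter reading).

The incident cohort is the subset with no JIA code before 2012-01-01. The
database starts in 2011, so the washout is the entire available pre-window
history — one year. That is the washout the data permits; true first onsets
earlier than 2011 that re-present in-window are misclassified as incident by
construction, a limitation shared by any registry with a hard left edge.

Subgrouping: a patient is JIA-SpA when any spondyloarthritis-feature code
(ankylosing spondylitis, sacroiliitis, other inflammatory spondylopathies,
psoriatic arthropathy) appears anywhere in the record. "Concurrent" is read
as co-occurring in the patient's record, not same-day; `spa_same_day = TRUE`
gives the strict same-day variant.

### Rates

Annual prevalence divides cases counted in a year by the under-16 population
of that year. The numerator definition is genuinely open in a claims design;
the default is registry (cumulative) prevalence — diagnosed on or before the
year, still enrolled and under the age cutoff during it — because JIA is
chronic and a claims cohort has no recovery event. `prevalence_mode =
"active_claim"` instead requires at least one JIA claim in the year, which is
the other defensible reading; patients age out of the numerator at the cutoff
either way, matching the pediatric denominator. The annual incidence
proportion subtracts previously diagnosed patients from the at-risk
denominator. The pooled incidence rate divides incident cases by summed
at-risk person-years; prior cases are not subtracted from person-years, an
error of order cases/population (≈10⁻⁴ here) that is far below Monte-Carlo
noise at any feasible population size.

### Exposure episodes and treatment patterns

Each fill covers `[fill_date, fill_date + days_supply)`. A fill merges into
the running episode iff `fill_date ≤ episode_end + grace`, with grace 14 days
for NSAIDs/steroids/csDMARDs and 60 days for biologics; the gap between
retained episodes therefore strictly exceeds the grace. Overlapping fills
extend coverage from the maximum end — overlapped supply is *not* stockpiled,
the simplest defensible rule for pediatric dosing where titration, not
hoarding, drives overlap. Chronic use ("more than three consecutive months")
is ≥90 days within one merged episode; 90 rather than 92 days is the default
because month lengths vary and 3 × 30 is the convention the threshold is
meant to encode (`chronic_days` is configurable).

The first fill of etanercept, adalimumab or tocilizumab is the index
biologic (abatacept is excluded as an index drug but counts as a switch
target). Same-date ties break by larger days supply, then alphabetically — a
deterministic rule, not a clinical claim. Episodes built with the 60-day
grace drive a four-state classifier; the first qualifying event fixes the
pattern (switching within the gap, restart after an interruption,
discontinuation, else continuation). Two boundary decisions matter:

- a different biologic filled while the index episode is still covered is a
  within-gap switch at that fill date (overlap ⇒ gap 0);
- continuation requires the index episode to persist to within 60 days of
  follow-up end, so an end-of-study tail is never misread as
  discontinuation.

Switches occurring *after* an interruption are tabulated under restart (the
reported restart row is "restart any biologic after interruption"), with the
subtype retained in the course record.

### Drug survival

`km_fit()` implements the product-limit estimator with events processed
before censorings at tied times, Greenwood's variance of log S, and log(−log)
95% bounds `S^exp(±z·se(log S)/log S)` — the transformation keeps bounds in
[0, 1], which matters when curves approach the extremes in small per-drug
strata; plain Greenwood is available via `conf_type = "plain"`. The median is
the smallest event time with S ≤ 0.5 and is reported as undefined (`NA`), not
infinity, when the curve never reaches 0.5. Years are days/365.25
throughout. The default drug-survival event is any end of index-biologic use
(switch, interruption, discontinuation), with `event_definition =
"discontinuation_only"` as the alternative in which only terminal
discontinuation counts — the aggregate-data design text supports either
reading. Time-to-restart measures from the index episode end to the first
later biologic fill, censoring never-restarters at follow-up end.

### Statistics and disclosure control

Group contrasts use Pearson's chi-squared without continuity correction, or
Fisher's exact test when any expected cell is below 5 (the conventional
threshold; the design text names both tests without a selection rule, so the
rule is configurable and the test actually applied is always reported). Odds
ratios use Woolf log-scale intervals with a logged 0.5 continuity correction
on zero cells. Small-count suppression masks exactly the non-zero counts
below three, rendering them as "≤3" after the custodian's table convention;
suppression is idempotent, applied as the last reporting step, and zeros are
shown.

## The synthetic generator

`generate_bundle()` emulates the study conditions with known per-person
ground truth. Its defaults are the package's statement of those conditions:

| parameter | default | unit / meaning |
|---|---|---|
| `onset_hazard_per_100k` | 5.5 | annual first-onset hazard per 100,000 at-risk person-years |
| `spa_fraction` | 0.49 | SpA-feature share among cases |
| `male_fraction` | 0.71 / 0.44 | male probability, SpA / non-SpA |
| `onset_age_probs` | (0.8, 14.6, 84.6)% / (12.5, 35.7, 51.8)% | onset-age mix 0–5/6–11/12–15, SpA / non-SpA |
| `uveitis_prob` | 0.073 / 0.030 | comorbidity flags by subgroup |
| `biologic_prob` | 0.152 / 0.231 | biologic uptake by subgroup |
| `time_to_biologic_meanlog` | log(0.73 × 365.25) | log-normal delay (days) to the index biologic |
| `cycle_days`, `biologic_supply` | 28, 28 | refill cadence, days supply, jitter ±3 d |
| `p_switch_cycle`, `p_gap_cycle` | 0.0036, 0.0067 | per-refill-cycle competing hazards |
| `p_restart_given_gap` | 0.75 | restart share after an interruption |
| `near_miss_fraction` | 0.10 | near-miss patients per true case |

Onsets are drawn per calendar year as Bernoulli trials on each person's
at-risk fraction of the year (enrolled, under 16), so the expected case count
equals hazard × person-years by construction and the pipeline's pooled rate
is an unbiased recovery of the configured hazard. Case birth dates are then
re-anchored to the drawn onset-age category — a perturbation of a few dozen
rows in a population of tens of thousands, far below the granularity of the
analytically derived denominators. Biologic trajectories are
piecewise-exponential: each 28-day refill cycle draws switch/interruption
events against flat per-cycle hazards, chosen once so that the terminal
pattern mix lands near the observed continuation/switch/restart/
discontinuation shares under 2012–2019 follow-up. Month of onset is uniform:
the design reports no seasonality, so none is modelled.

Reproducibility is a single `set.seed(config$seed)` with a fixed draw order:
the same seed yields a byte-identical bundle. Per-person hashed substreams
were considered and rejected — they buy subset-invariance the tests never
need, at the cost of a hand-rolled RNG discipline.

Near-miss patients (10% of cases by default) each fail exactly one inclusion
criterion — only two outpatient codes, an NSAID supply of exactly 14 days, or
age ≥16 at index — so the cohort filters are exercised at their boundaries;
the tests assert that pipeline membership equals ground-truth case labels
with every near-miss excluded.

**What the generator does not emulate**: code miscoding and transfer between
insurers (claims are internally consistent by construction), reimbursement
adjudication, dose titration (days supply is authoritative), mortality, and
seasonality. Passing tests therefore demonstrate that the *algorithms*
implement their definitions exactly and recover known parameters — not that
the definitions are robust to real-world coding noise, which no synthetic
benchmark can establish.

## Numerical choices and degenerate inputs

- Qualification windows are half-open: three outpatient dates qualify when
  the first and third differ by ≤364 days.
- "More than 14 consecutive days" is strict: 14 covered days fail, 15 pass.
- Gaps equal to the grace still merge; the gap between retained episodes
  strictly exceeds it.
- Horizon look-ups (1/3/5-year discontinuation) evaluate the step function at
  the last event time ≤ round(365.25 × h) days; a horizon before the first
  event returns 0 with a degenerate interval.
- Empty inputs: an empty bundle is vacuously valid; an empty cohort yields
  header-only reports; `km_fit()` on zero observations is an error, as is a
  zero row/column margin in the chi-squared test.
- At S = 0 or 1 the log(−log) interval is pinned to the point estimate; the
  Greenwood sum is ∞ once the risk set is exhausted by events.

## Problem sizes used by the test suite

Property suites run at fixed seeds: episode merging against a day-by-day
coverage oracle (1,000 random timelines), pattern-label recovery on
adversarial timelines (4 patterns × 100 seeds, 100% required), Kaplan–Meier
agreement with an independent reference implementation to 10⁻¹⁰ (500 random
datasets, n ≤ 200), Fisher p-values against full hypergeometric enumeration
(n ≤ 40), and hazard recovery within 3 Monte-Carlo standard errors over 20
simulated populations of 200,000 persons at the default study conditions.
Unit tests use elevated onset hazards to obtain enough cases at small
population sizes; those hazards exercise the machinery and are not study
conditions.

## Known limitations

- The shipped diagnosis and drug code lists are a documented stand-in
  assembled from the public ICD-9-CM/ICD-10-CM indices; operational lists
  used against any real database should replace them via the YAML config.
- Outpatient qualification counts distinct service dates, not code
  occurrences; multiple same-day codes count once.
- The incidence-proportion denominator subtracts previously diagnosed
  patients from the headcount but the person-year denominator does not; both
  effects are O(prevalence) and negligible at realistic rates.
- No ILAR subtype inference, no multivariable modelling, no log-rank test:
  the design these methods implement reports crude rates and aggregate
  contrasts only.
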