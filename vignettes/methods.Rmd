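---
title: "Methods: refill-based hearing-aid persistence and EHR cohort preparation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: refill-based hearing-aid persistence and EHR cohort preparation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audcohort)
```

## The setting

Hearing-aid (HA) outcome research built on electronic health records
starts from a handful of relational tables keyed by a patient identifier:
per-station demographic records, outpatient diagnoses and procedures,
inpatient stays, audiometry, HA orders, battery orders, and patient
self-report surveys (IOI-HA). `audcohort` turns such an extract into a
patient-level analysis table and a set of derived outcome measures. This
vignette documents the models, the rules, the parameters that matter and
the design decisions that were genuinely open.

## Time conventions

All dates are integer days from a cohort epoch (default 2012-04-01).
Clinical rules in this domain are stated in months, which is ambiguous at
day resolution, so the package fixes exact day equivalents once:
6 months = 183 days, 12 months = 365 days, 18 months = 548 days,
24 months = 730 days. All four constants are configurable through
`persistence_params()` and the window arguments of the other modules;
every boundary rule below is exact and testable under this convention.

## The persistence model

Battery orders are treated as prescription refills. Each order carries a
nominal supply (the *dose*) of `dose_days` = 183 days; after the supply
runs out a patient may lapse for up to `gap_days` = 365 days (the
*acceptable gap*) before being deemed to have discontinued. A patient is
**persistent** at evaluation time $T$ days after fitting iff

$$T < t_\mathrm{last} + D_\mathrm{dose} + G_\mathrm{acc},$$

with $t_\mathrm{last}$ the most recent battery order *strictly* before
$T$, measured from the fitting-day order at $t = 0$.

Three consequences shape the implementation and its tests:

* Since every patient holds the fitting-day order, the smallest $T$ at
  which anyone can be non-persistent is
  $D_\mathrm{dose} + G_\mathrm{acc}$ = 548 days (18 months).
* The criterion depends only on the last order, so adding an order can
  never turn a persistent patient non-persistent, and multiplying all day
  quantities by a constant leaves every flag unchanged.
* "Strictly before $T$" means an order on day $T$ itself does not rescue
  persistence at $T$. This is the literal reading of "most recent order
  before $T$"; the tests pin the boundary on both sides.

`is_persistent()` applies the inequality; `is_persistent_brute()` is an
intentionally naive day-stepping oracle that walks every day, marks
supply coverage and tracks the terminal uncovered run. The two routes are
independent implementations and the suite checks their agreement on
10,000 random order histories across several parameter settings.

Cohort persistence at $T$ is the proportion of persistent patients among
those who survived through $[\mathrm{fitting}, \mathrm{fitting} + T)$;
patients dying inside the window are excluded rather than counted as
failures, and patients with implausible demographic dates are excluded
from all survival-dependent analyses.

The medication possession ratio (`medication_possession_ratio()`) is the
size of the union of supply intervals $[t, t + D_\mathrm{dose})$
intersected with the observation window, divided by the window length.
The verbal "days with medication on hand" definition does not say how
overlapping supplies combine; the union (no double counting) is the
standard days-covered convention and was chosen here, validated against a
literal day-counting oracle.

## Cohort preparation rules

**Demographics.** Patients seen at several stations have one demographic
record per station. Merging takes the modal value of each field; any
disagreement sets `inconsistent`. When no majority exists the value from
the earliest-dated source record wins — the merging rule in the field's
literature is silent on ties, and this choice is deterministic and
auditable (input order is the documented fallback). A record is
*implausible* when death strictly precedes birth or the first HA order;
same-day death and order is allowed because the rule is worded as strict
precedence. "Died within $w$" is the half-open interval
$[\mathrm{fitting}, \mathrm{fitting} + w)$, so a death exactly at
$\mathrm{fitting} + w$ survives the window.

**Audiometry.** Raw entries are text. Cleaning maps, in order: above-limit
audiometer tokens (defaults `NR`, `120+`, `>120`) to 120 dB HL with
provenance `ceiling_substituted`; ambiguous tokens (defaults `DNT`,
`CNT`, `--`, empty) and numeric values that are off the 5-dB testing grid
or outside $[-10, 120]$ dB to missing (`set_missing`); everything else
passes through (`as_entered`). Cleaning never raises an error. The token
lists are configurable because the full anomaly inventory of any real
extract is site-specific. An audiogram is *valid* when all four PTA
frequencies (0.5, 1, 2, 4 kHz) are numeric in both ears — 120 dB
substitutions count, other frequencies are irrelevant. Multiple valid
audiograms are averaged cell-wise over numeric values only (a cell is
missing only if missing everywhere); averages may be off the 5-dB grid,
since divisibility is a property of raw entries, not derived values. The
bilateral 4F-PTA is the mean of the two ear PTAs, which equals the
eight-value mean. Asymmetry is $|L - R| \ge 15$ dB, inclusive at exactly
15; `worse_ear` is `"none"` below the threshold even when ears differ.

**Fitting-date proxy.** The record systems have no single fitting code,
so the fitting date is the first battery order on or after the HA order,
accepted only when the lag is at most 180 days. Battery orders strictly
before the HA order are ignored: they belong to a prior device, and a
fitting cannot precede its order. Persistence analyses anchor to the
first order's fitting date; a `single_order_only` switch restricts to
single-order patients.

**IOI-HA.** Each survey is assigned to the latest HA order on or before
its completion date. Two surveys of one patient resolving to the same
order are both excluded — there is no principled way to pick one. The
return window (14–180 days after fitting) is read inclusively at both
ends. The patient-reported completion date governs the window, with the
system entry date as fallback when completion is missing; the source
convention does not say which date was used, and completion is the date
closer to the measured construct. The total score sums items 1–7 (range
7–35); item 8 (self-rated unaided difficulty) is an ordinal covariate and
is never totalled.

**Multimorbidity.** Each ICD-9 code maps to a chronic flag and one of 18
body systems. The index counts systems with at least two chronic codes in
the half-open window $[\mathrm{order} - 365, \mathrm{order})$, after
dropping codes beginning 389 (hearing loss), so that body system 6 stays
informative for other conditions. Codes on the order day are outside the
window ("before the order"). Matching is by normalised code string with
prefix semantics for category-level definitions (e.g. `250` matches
`250.01`); unknown codes are non-chronic. The shipped condition
definitions keep the source conventions verbatim, including arthritis =
360–379 and vision impairment = 710–739 even though these ranges are
transposed relative to standard ICD-9 chapter assignments (360–379 is the
eye chapter, 710–739 musculoskeletal); the discrepancy is documented
rather than silently corrected, and the definitions are configurable.

## The synthetic cohort generator

The generator (`generate_cohort()`) emulates the statistical structure the
pipeline assumes, with defaults calibrated to the descriptive profile of
a large veteran HA cohort:

* age at order from a two-component normal mixture (means 62 and 75.2 y,
  weights 0.35/0.65; the empirical distributions are not unimodal),
  truncated to 20–100 y; 98.4% male;
* a piecewise-constant mortality hazard by age band (1%/y below 60 up to
  22%/y at 90+), tuned so roughly a fifth of patients die before the end
  of follow-up;
* per-ear 4F-PTAs around 49.9/48.7 dB HL (SD 16.8) with a 14.6%
  asymmetry rate, 57.7% of asymmetries left-worse; audiograms are
  sloping losses whose 0.5/1/2/4 kHz offsets average zero around the
  target PTA, rounded to the 5-dB grid;
* an order-to-first-battery lag that is normal (mean 42, SD 46.6 days)
  truncated at zero — the fitting proxy;
* inter-battery gaps that are log-normal (median 237 days, log-SD 0.62,
  hence mean near 9.4 months), matching the right-skewed gap
  distributions seen in refill data;
* discontinuation as a mixture of a never-discontinue point mass (0.5)
  and an exponential hazard (1.18/y), calibrated so the implied two-year
  persistence sits near 63%; an optional log-odds coupling
  (`morbidity_coupling`) lets the hazard grow with the number of true
  chronic systems — the literature gives no value for this joint
  distribution, so the default is 0 (independence);
* chronic ICD-9 codes per body system with prevalences summing to 3.14
  and per-system code counts $1 + \mathrm{Poisson}(2)$ dated within the
  12-month window, giving an expected multimorbidity index near 2.7;
  hearing-loss 389.XX codes for everyone; acute noise codes;
* 78.6% audiogram availability, 20.1% IOI-HA response among fitted
  patients with return lags drawn mostly inside the 14–180-day window,
  and 1–3 duplicate station records per patient.

Anomalies are injected *after* clean generation, so the ground-truth
sidecar always holds pre-anomaly values. Injection applies per-entry (or
per-patient, for demographic anomalies) Bernoulli draws with precedence —
above-limit, then ambiguous, then off-grid — so each entry receives at
most one anomaly and the returned log is an exact account, which is what
makes the cleaning-conservation test exact rather than statistical.

`true_persistence()` is the generator's own oracle: a Monte-Carlo
simulation of the discontinuation-plus-gap process evaluated under the
persistence definition, returned with its standard error (and exactly 1,
in closed form, for $T < D_\mathrm{dose} + G_\mathrm{acc}$). Parameter
recovery compares the full pipeline estimate on generated cohorts with
this oracle. Note that under the refill definition even a
never-discontinuing patient can be transiently non-persistent when a
single gap exceeds $D_\mathrm{dose} + G_\mathrm{acc}$; the oracle
reflects the definition, not the latent state, because that is what the
pipeline can see. With degenerate gap parameters the oracle has a closed
form, which the suite uses as an independent cross-check.

What the generator does **not** emulate: clinic scheduling, device models
beyond style labels, ICD-10 streams, seasonal ordering patterns,
measurement correlation across frequencies beyond the common PTA shift,
and informative missingness (audiogram availability and IOI response are
independent of outcomes). Passing recovery tests therefore show the
pipeline is a consistent estimator of the generator's process — not that
real EHR data satisfy these independence assumptions.

## Problem sizes and tolerances

Statistical tests compare estimates with configured or analytically
derived expectations within 3 standard errors. Marginal calibration and
parameter recovery use cohorts of 50,000 patients (one shared fixture
plus two persistence regimes near 0.40 and 0.90); the truth oracle uses
100,000–500,000 Monte-Carlo replicates, and combined standard errors are
used when both sides are estimated. Formula/oracle equivalence runs
10,000 random histories for persistence and 1,000 for the MPR; the IOI-HA
scale anchors are verified over the exhaustive $5^7$ item space. These
sizes keep the full suite under a minute on a single CPU while leaving
comparison standard errors near 0.2 percentage points.

## Limitations

The persistence measure is coarse: a 6-month dose plus a 12-month gap
means nothing can be learned before 18 months, and behaviour is inferred
from ordering, not usage. The battery-order proxy assumes batteries come
from the observed system only. The multimorbidity index weighs all body
systems equally and ignores severity. The IOI-HA total treats seven
Likert items as one interval scale — a pragmatic convention adopted for
comparability, not a psychometric claim. The shipped code list and CCI
map are small synthetic stand-ins for the full curated resources, which
must be supplied for real analyses.
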