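---
title: "From clinical registry to research dataset: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From clinical registry to research dataset: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regforge)
```

## The problem

A patient-centered registry run by a collaborative-care (CCM) program
records, for each *patient instance* (episode), the date a patient became
eligible for the intervention, the date a care coordinator offered it
(the start or activation date), and the date the instance closed. A
contact log records every coordinator–patient contact with its duration
in minutes; questionnaire tables hold PHQ-9, GAD-7, MDQ and AUDIT
responses; a demographics table holds birth date, sex, race, marital
status, employment, consent and diagnosis flags. Because these data are
collected for care, not research, three obstacles stand between the raw
tables and an analyzable dataset: undetected data errors, missing key
dates, and the absence of explicit cohort labels. regforge addresses the
three in sequence, and ships a synthetic generator so that every stage
can be validated against planted ground truth.

## Data-quality model

Rules are organised in five families, each mapped to a fixed subset of
five quality dimensions (accuracy, completeness, consistency, validity,
uniqueness); timeliness is deliberately out of scope for this kind of
retrospective extract.

| family | example rule | typical action |
|---|---|---|
| attribute domain | PHQ-9 item in 0–3; employment free text → yes/no | set missing / normalize |
| relational integrity | unique `(patient, eligibility, start)` key; no orphans | flag |
| historical data | birth before all events; start ≤ end | flag |
| state-dependent | end date ⇒ eligibility date; baseline questionnaire ≤ start | flag |
| attribute dependency | PHQ-9 total = sum of 9 items | recompute total |

Execution order is fixed — domain rules first, so downstream rules see
normalized values; dependency rules last, so a total is compared against
repaired items. Design choices worth knowing:

* **Repair policies are explicit.** An out-of-domain questionnaire item
  is set to missing (flag-only is available); a total/item mismatch is
  repaired by recomputation from the items by default (`set_missing`
  alternative). Rows with any missing item are skipped by the dependency
  rule, because their item sum is undefined — this also means a single
  out-of-domain item produces exactly one violation, not a cascade.
* **The "enrolled instances have at least one contact date" rule fires
  only on episodes whose status was explicitly recorded as enrolled.**
  Before classification, a start-date-bearing episode with zero contacts
  is indistinguishable from a legitimate opt-out — flagging it would
  declare a third of the registry erroneous. When a recorded status
  exists the rule applies and labels the contact date missing.
* **The baseline questionnaire** of an episode is the earliest
  attributable response per instrument; it must be recorded on or before
  the enrollment date. Later responses are follow-ups and are not
  checked against the start date.
* **Idempotence** is a designed property: a second assessment on the
  cleaned output performs zero repair actions, and the test suite
  asserts it. Per-dimension report totals are exact integer sums over
  the rules tagged with each dimension.

## Missing data

Two procedures, run in order by `clean_missing()`:

1. **Complete-case drop.** Instances with a start date but no end date
   are data-entry errors under the registry's guidelines and are removed
   at the episode level — a patient's other episodes survive, since the
   unit of the registry is the patient instance. The missingness
   mechanism (MCAR by default) is an annotation on the report, never
   inferred: formal MCAR/MAR/MNAR testing is out of scope.
2. **Start-date recovery.** For an instance with a missing start date,
   the eligibility time (end − eligibility, days) is computed; when it
   is positive and the instance has attributable contacts, the earliest
   contact date becomes the start date (provenance `"recovered"`). The
   attribution window is the closed interval `[eligibility, end]`, so a
   recovered date can never fall outside it. A contact exactly on the
   end date counts; same-day duplicate contacts collapse to a single
   candidate date, so no tie-break is needed.

Derived per-episode metrics follow the registry's definitions:
activation time (end − start) when a start date exists, eligibility time
(end − eligibility) when it does not, CE time (end − first contact) for
recovered instances, plus contact frequency and total minutes over
attributable, dated contacts. Contact attribution, when episodes of one
patient overlap, picks the episode with the latest eligibility date not
after the contact; the generator avoids overlap entirely, and the
brute-force oracle tests cover the overlapping case explicitly.

## Cohort classification

Statuses partition the eligible instances into *enrolled*, *opt-out*,
*not approached*. Precedence: a recorded status always wins — the
derivation algorithms exist to fill the (common) gap where the clinic
recorded nothing. Derivation: with a start date present, zero contact
frequency **or** zero total minutes means the patient was offered the
intervention but never received it (opt-out); both positive means
enrolled. With the start date missing after recovery was attempted, a
recovered start means enrolled, otherwise the patient was never
approached. The disjunction is taken verbatim: an instance with positive
frequency but all-zero durations (legal, the minimum recorded contact
duration is 0 minutes) classifies as opt-out.

The eligibility screen runs before classification: research consent
first, then age ≥ 18 **at the eligibility date** (the registry does not
anchor age; this is the package's choice), depression diagnosis, no
bipolar history, screening PHQ-9 ≥ 10. The screening score is the latest
PHQ-9 total on or before the eligibility date. Enrolled instances below
the threshold are retained under a provider-discretion override (default
on), mirroring clinical practice where subthreshold patients are
included for, e.g., relapse history. The minimum-two-PHQ-9 criterion
belongs to the cross-sectional study pathway only and is a config toggle,
off by default. A missing screening score does not exclude by itself.

## Index dates and windows

Three strategies answer "when does follow-up start?":

1. `first_eligibility` — one common index, the patient's earliest
   eligibility date. Comparable windows; dilutes the treatment effect
   when enrollment happens late in the window.
2. `enrollment_linked` — intent-to-treat: enrolled patients indexed at
   the start date of their first enrolled episode (minimum start date;
   ties by eligibility date, then episode id); comparison patients at a
   configured eligibility pick. For comparison patients with several
   eligibility dates the first is used by default (`comparison_pick`
   switch), since no principled choice exists.
3. `shifted_eligibility` — comparison index = eligibility pick + the
   mean eligibility-to-enrollment lag of the treatment arm, rounded to
   the nearest whole day, equalising the effective follow-up.

Under the first-eligibility special case the package constructs four
cross-sectional cohorts over the half-open window
`[index, index + window_days)`, with `window_days = 183` encoding six
months (configurable; no authoritative day count exists). Precedence
inside the window is enrolled > opt-out > not approached, resolving the
mixed-status patients the registry is known to contain; the enrolled
patient's completed/incomplete split is decided by the first enrolled
episode starting in-window (completed iff its end date precedes the
window close). Enlarging the window can therefore promote incomplete to
completed enrollment but never the reverse — a property the tests check.
Records at exactly the index date belong to the outcome window, not the
observation window.

## The synthetic generator

The generator emulates the *structural and statistical* features the
pipeline consumes — never clinical trajectories (no symptom dynamics, no
remission curves). Episodes per patient follow a configurable
distribution (default 80/15/5% for 1/2/3 instances); per-patient
episodes are sequential and non-overlapping so that planted statuses are
unambiguous. Enrolled instances get a start date and 1+ positive-duration
contacts; opt-out instances a start date and no contacts; never-approached
instances neither. Recoverable instances are planted enrolled with the
start date withheld from the episode table and pinned as the earliest
in-window contact. Allocation is `exact` (rounded quotas, used by tests
that need exact counts) or `stochastic` (per-episode multinomial, used
for convergence checks). One root seed drives fixed per-table substreams,
so regenerating with the same `(config, seed)` is byte-identical.

`depression_profile_config()` encodes the published marginals of a large
depression registry: 15,576 instances, status mixture
(44.30, 33.30, 22.40)%, overall missing-start rate 23.42% — decomposed as
22.40% structural (never approached) plus a 2.30% recoverable fraction of
enrolled instances, which reconciles the registry's 3,649 missing starts
as 3,495 never-approached plus 154 recovered — eligibility dates
2008-03-03 to 2018-05-17, at most 123 contacts per instance and 990
minutes per contact. The published sub-counts themselves do not
reconcile perfectly (6,824 contact-bearing enrolled + 154 recovered ≠
6,900 enrolled), and the package does not attempt to reproduce that
internal inconsistency. Distributions beyond the published min/max are
the package's own choices and are deliberately simple: contact counts
1 + Poisson(3) capped at the maximum, contact minutes 5 + Poisson(15)
capped likewise, offer lags uniform on 0–60 days, activation times
uniform on 30–365 days, ages normal (mean 41.3, SD 16.2) truncated to
18–90. About 0.96% of enrolled instances are planted with subthreshold
screening scores (3–9) to exercise the override, and 0.17% of contact
rows carry a missing date, matching the registry's reported rate.

Error injection plants one fault per ledger entry across six types (two
attribute-domain types plus one per remaining family). Targets are
chosen so a single fault triggers exactly one rule — e.g. a date
inversion moves the end date between the eligibility and start dates, so
only the start/end ordering rule fires — which lets the tests assert an
exact one-to-one match between ledger and violations, not just recall.

What passing on synthetic data does **not** show: robustness to
free-text idiosyncrasy beyond the shipped normalization dictionary,
realistic correlation between severity and enrollment, unstructured
clinical notes, or multi-site linkage. Those are outside the package's
scope.

## Numerical and reporting conventions

* Dates are timezone-free calendar days; durations are whole days
  (episodes) or whole minutes (contacts).
* Tables are comma-separated text with ISO-8601 dates by default
  (`registry_dialect()` overrides both); a missing start date enters the
  composite key as the sentinel `<missing>`.
* Loading never drops or repairs rows; unparseable dates become missing
  and are logged on the bundle. All exclusions happen in later, logged
  stages, and clean bundles round-trip losslessly through disk.
* Percentages in summaries print to two decimals with half-up rounding;
  the age SD uses the sample (n − 1) convention. PHQ-9 severity bands
  are ≤5, >5–<10, ≥10–<15, ≥15–<20, ≥20, plus missing; the start-date
  band block for never-approached patients is reported as
  "No start date is available".
* Flow summaries refuse to emit a diagram whose splits do not conserve
  counts, naming the failing split. The pipeline's flow root is the set
  of instances entering the eligibility screen; cleaning drops are
  reported separately in the recovery report.

## Problem sizes in the test suite

The suite validates the engine at the sizes the methods are designed
for: planted-error detection on 2,000-instance bundles (60 injected
faults), exact status recovery at 5,000 instances, profile-scale runs at
15,576 instances over three seeds for the ±1-percentage-point
convergence checks, and 200 small random bundles (≤ 20 episodes) for
brute-force oracle equivalence of metrics and window cohorts. These
sizes keep a full run comfortably on one CPU while exercising every
code path at registry scale.

## Known limitations

Declarative rules only — no statistical outlier detection; no
model-based imputation (recovery is deterministic, from the contact
log); no longitudinal multi-window designs (single cross-sectional
window per configuration); no effectiveness estimation. The free-text
normalization dictionary ships with the two canonical employment
examples and is user-extensible; unknown answers are set to missing with
a flag rather than guessed.
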