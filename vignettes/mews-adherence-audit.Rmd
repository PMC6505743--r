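---
title: "Auditing an early-warning-score protocol: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing an early-warning-score protocol: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mewsaudit)
```

## The problem

Track-and-trigger scores such as the Modified Early Warning Score (MEWS)
summarize a patient's vital signs into a single number that dictates how soon
the next bedside assessment is due and when to escalate to a physician or the
rapid response team. On a surgical high-dependency unit (HDU), vital-sign
elements are recorded asynchronously — a blood pressure here, a temperature
twenty minutes later — so three operational questions arise before any
clinical question can be asked of the data:

1. *Scoring*: what is the MEWS implied by a set of measurements?
2. *Assembly*: which recordings constitute one bedside assessment?
3. *Adherence*: did the next assessment arrive within the interval the
   protocol demanded?

`mewsaudit` implements these three stages as a pipeline, adds the descriptive
and inferential comparisons used to contrast a conventional-charting period
with an automated-device period, and ships a synthetic cohort generator with
exact ground truth so that every stage can be validated without patient data.

## The scoring model

The scoring card bands four elements (heart rate, systolic blood pressure,
respiratory rate, temperature), maps the AVPU consciousness scale
categorically (Alert 0, Voice 1, Pain 2, Unconscious 3), and adds three point
rules: +1 if the nurse is worried about the patient, +1 if urine production
over the previous 4 hours is below 75 ml, and +3 if oxygen saturation is
below 90% *despite adequate oxygen therapy*. The card prints integer band
edges (e.g. heart rate "40–50" then "51–100"), so values are rounded to the
card's printed precision before lookup — integers for rates and pressures,
0.1 °C for temperature — after which the printed bands partition the real
line and are read as closed on their printed endpoints. This reproduces
exactly what a nurse reading the card does.

Three asymmetries of the card are implemented literally rather than
"corrected" toward other published MEWS variants: systolic pressure above
200 mmHg scores 2 (there is no high-side 3), temperature never scores above 1,
and respiratory rate below 9 scores 2. The maximum attainable total is 19.

Two readings of the card were genuinely open and are resolved as follows:

* **SpO2 on room air.** The card awards points only "despite adequate oxygen
  therapy"; a desaturated patient *not* on oxygen therefore scores 0 from
  saturation. We implement the literal reading; the oxygen-therapy flag
  travels with every SpO2 recording.
* **The worried flag.** It is treated as a scoreable element worth one point
  when set, and as "not worried" (0 points, not missing) when absent — it is
  the one element excluded from the completeness definition, which requires
  the seven core elements (heart rate, systolic BP, respiratory rate,
  temperature, SpO2, AVPU, urine).

The urine rule follows the card's 4-hour phrasing (the narrative elsewhere
mentions 24-hour urine production); the threshold is configurable, and whole
scoring tables can be loaded from YAML (`read_scoring_table()`) so other
early-warning variants can be audited with the same machinery.

```{r}
tab <- default_scoring_table()
score_element(tab, "HEART_RATE", c(45, 75, 105, 135))
compute_mews(c(HEART_RATE = 105, SYSTOLIC_BP = 95, RESP_RATE = 18,
               TEMPERATURE = 37.8, AVPU = 1, URINE_4H = 60, SPO2 = 95))
```

## Assembling assessments: the 15-minute rule

Measurements of one patient taken less than 15 minutes apart count as a
single assessment. Two groupings are consistent with that phrasing; we use an
*anchored* window: the first unassigned recording opens an assessment at its
timestamp, recordings strictly within 15 minutes of the anchor join it, and
the first recording at or past the anchor + window opens the next one. Unlike
a rolling window this cannot chain measurements 14 minutes apart into an
unbounded assessment, it is deterministic, and the result is independent of
input row order. A repeated element inside the window is treated as a
re-measurement: the latest value wins, and the superseded rows remain counted
so no recording leaves the partition. Timestamps carry minute resolution —
the finest protocol rule is 15 minutes, so sub-minute detail adds nothing.

Each assessment's MEWS is always recomputed from its elements. Incomplete
assessments are scored over what is present, which makes the total a lower
bound on the fully-observed score; the audit uses these partial scores by
default (configurable to complete assessments only) because in practice most
assessments in a conventional-charting regime are incomplete, yet they are
the scores the protocol clock ran on. Mixed-source assessments take the
majority source of their recordings, ties resolving to the automated side
(real assessments were recorded by one system; the rule only matters for
synthetic edge cases).

## The adherence audit

The response protocol maps the current score to a maximum interval until the
next assessment: 24 h at MEWS 0, 8 h at 1, 4 h at 2, and 1 h at 3 or more
(where escalation actions also begin; those are not auditable from
timestamps and are out of scope). An interval is the anchor-to-anchor
difference of consecutive assessments of one stay and is attributed to the
score — and, for subgroup analyses, the recording source — of the *earlier*
assessment, since that is the observation that started the clock.

The last assessment of a stay has no successor. The default policy
(`exclude_terminal`) removes it from the denominator; `terminal_nonadherent`
counts it as non-adherent instead, approximating an accounting in which every
assessment is in the denominator. Time-to-next-assessment strata report a
median and the IQR *width* (Q3 − Q1) per score level, using Tukey's hinges
(`fivenum()`) by default; the quartile rule is configurable because reporting
conventions differ between statistical packages.

## Statistical choices

* **Rank-sum test** (`rank_sum_test()`): U from midranks. For small tie-free
  samples (`min(n) <= 8`) the two-sided p is exact (doubled smaller tail of
  the enumerated U distribution); otherwise a normal approximation with
  tie-corrected variance and 0.5 continuity correction. The z-score is
  always reported, as interval tables conventionally print one. Degenerate
  pooled samples return z = 0, p = 1.
* **2×2 tests** (`contingency_test()`): Pearson chi-square without continuity
  correction unless any expected cell is below 5, then Fisher's exact test
  (two-sided by summation of tables at most as probable as the observed —
  the common software convention; doubling of the smaller tail is available).
* **Rounding**: proportions are reported at one decimal, halves up, computed
  from integer counts (`percent_from_counts()`) so that exact halves such as
  204/320 = 63.75% land on the intended side despite binary floating point.
* **No multiplicity correction** is applied, matching the single-threshold
  (p < 0.05) convention of the audit this pipeline emulates.

## The synthetic cohort generator

`generate_cohort()` exists so that each pipeline stage can be checked against
a known truth. Its defaults (`paper_like_config()`) encode the operational
conditions of the study unit: two arms with log-normal HDU stays (median
7.5 / 7.1 days, IQR width 7.0 / 6.0 — parameterized as
σ = asinh(IQR/2·median)/Φ⁻¹(0.75)); three daily nursing rounds (07, 14, 22 h,
each taking place during its hour with 20-minute jitter); arm-specific
per-element recording dropout (respiratory rate 0.96/0.03 and AVPU 1.00/0.03
as published; the remaining elements follow the usual charting pattern —
heart rate and blood pressure the most reliably recorded, urine output and
the worried flag the least); per-follow-up Bernoulli protocol compliance
(0.011 control, 0.254 intervention — the published adherence rates); and 39%
automated-device usage within the intervention arm.

Design points that matter for interpretation:

* **Event-level timing.** All elements of one intended assessment share an
  event time with 0–4 minute offsets; missingness then deletes elements.
  This is exactly the structure the missingness analysis measures, and the
  5-minute event span is far below the 15-minute window, so the builder
  reassembles ≥ 99% of intended events.
* **Compliance model.** At each event the next follow-up is, with the
  configured probability, scheduled inside the current true score's window
  (snapped to the next nursing round when one fits, producing the three-peak
  24-hour pattern) and otherwise delayed past the window by a log-normal
  overshoot before landing at the next round. A 10-minute guard margin on
  both sides of the window boundary keeps minute rounding and anchor offsets
  from flipping a scheduled-adherent pair to non-adherent or vice versa.
* **No terminal censoring.** The event chain runs until the nominal stay
  duration elapses and discharge falls just after the final assessment, so
  no scheduled follow-up is cut off by discharge. Truncating at a fixed
  discharge would preferentially censor the longer (late) follow-ups and
  inflate measured adherence by roughly ten percent relative — the audit
  would then not recover the configured compliance.
* **Baselines inside the zero band.** Stable-patient vitals are drawn from
  normals truncated to the zero-score band of each element (urine well above
  threshold, patients alert, staff not worried). All score elevation comes
  from deterioration episodes (Poisson, default 0.05/patient-day, mean 3 h),
  whose severity (uniform on [1, 2]) deterministically shifts every element
  toward its abnormal bands — at severity 1 the rarely-missing elements
  (heart rate, SpO2 on oxygen, systolic pressure) already carry a score of
  3+. This makes the response window computed from the *recorded* (partial)
  score agree with the true window for ~99.5% of events, so the adherence
  audit is an almost unbiased estimator of the configured compliance; with
  free Gaussian tails, elements hidden by missingness would systematically
  loosen the recorded window and bias adherence upward by more than the
  recovery tolerance in the heavily-missing control arm.
* **Outcomes are independent noise.** Stay outcomes (mortality, readmission,
  length of stay) are drawn at the published frequencies independently of
  the vitals process; the audit this emulates found no outcome effect, and
  coupling outcomes to deterioration is explicitly out of scope. The 28-day
  and in-hospital death flags are likewise independent of each other.

What the generator does *not* emulate: physiologic dynamics (no circadian or
pharmacologic structure, no autocorrelation between events), nurse behaviour
beyond the Bernoulli compliance rule, and the real unit's assessment density.
Following the compliance model literally yields ~6–9 assessments per stay,
whereas the real unit's three-rounds-a-day habit produced ~25; consequently
interval medians and stratum sizes are structurally different from the
published interval table, which depends on unavailable patient data and is
reproduced in layout only. Passing recovery tests therefore demonstrates
correctness of the pipeline's measurement logic under the configured
missingness/compliance/usage conditions — not realism of any particular
vital-sign trajectory. With the published control-arm AVPU dropout of 1.00,
the synthetic control arm contains no complete assessments at all (the
published 2.5% completeness is inconsistent with 100% AVPU dropout; we keep
the element-level published values, which the recovery analyses check).

## Problem sizes and numerical tolerances

The recovery analyses use 300 patients per arm (~2,500 assessments per arm),
at which every recovered proportion — per-element missingness, automated
fraction, per-arm compliance — is required to sit within three binomial
standard errors of its configured value. Scoring equivalence is checked
against an independently written chained-conditional oracle on dense grids
(~1,000–1,200 points per element, plus the full 0.1 °C temperature grid);
exact rank-sum p-values are checked against complete enumeration of all
rank assignments for every sample-size pair up to 6 + 6. Window-boundary
behaviour relies on the 10-minute scheduling margins described above rather
than on floating-point comparisons of minute-rounded timestamps.

## Known limitations

* The audit measures only the monitoring-interval component of the response
  protocol; physician and rapid-response actions leave no timestamp trail in
  the record model.
* Partial MEWS totals are lower bounds; an assessment missing a deranged
  element is audited against a looser window than the patient's true state
  warranted. This mirrors what any record-based audit can know.
* No carry-forward: a temperature taken 30 minutes before an assessment does
  not count toward it. The real nurses may have reasoned otherwise; the
  record model cannot tell.
* The generator's two-regime structure (zero-band baseline vs episode) makes
  intermediate scores (1–2) rare relative to a real cohort; analyses
  stratified on those levels run on thin synthetic strata.
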