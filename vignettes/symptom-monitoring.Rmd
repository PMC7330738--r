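---
title: "Rule-based symptom monitoring: model, assumptions, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based symptom monitoring: model, assumptions, and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentinel)
```

## The monitoring model

`sentinel` implements the evaluation core of a remote symptom-monitoring
service for patients recovering from pancreatic cancer surgery. Each day a
patient submits a report scoring each assessed symptom on up to three
dimensions:

* **occurrence** — did the symptom occur? (yes/no, coded 1/0);
* **frequency** — how often? (4-point ordinal, coded 1–4 ascending);
* **distress** — how bothersome? (4-point ordinal, coded 1–4 ascending).

Follow-up dimensions exist only when the symptom occurred, and not every
symptom carries every dimension (fever and infusion-access problems are
occurrence-only; constipation and at-home activity limitation carry distress
but not frequency).

A **risk-assessment ruleset** maps responses to alerts. Each rule is the
tuple *(symptom, dimension, qualifying label set, window length in
consecutive days, severity, care phase)*. A rule fires when its qualifying
condition has held on `window_days` calendar-consecutive reported days.
Severity is two-tier: **red** demands clinic contact within one hour,
**yellow** contact the same working day. Two phases exist: *post-surgery*
(12 symptoms, windows of 1, 2, 3 or 7 days) and *adjuvant chemotherapy*
(15 symptoms — three added for treatment side effects and infusion access —
with single-report rules only, because chemotherapy patients already have
weekly nurse contact). The built-in ruleset
(`builtin_pancreas_ruleset()`) encodes this table exactly — 30 rules — and
any other ruleset can be loaded from a single YAML document
(`load_ruleset()`), which round-trips losslessly through
`serialize_ruleset()`.

Label sets, not thresholds: a rule like *loose stool, frequency, {"Often",
"Almost always"}, 3 days, yellow* is stored as a set of canonical labels
with an ordinal code map. Comparisons are by code lookup, never by string
inequality, because the clinical table mixes contiguous top categories with
deliberate gaps (during chemotherapy, vomiting "Almost always" is red while
"Often" alone is yellow — the yellow set is *not* an up-set on its own).

### Streak semantics

The defining subtlety is what "N consecutive days" means when days can be
missing:

* a qualifying response on the day after the last qualifying day extends
  the streak;
* a qualifying response after **any** gap — a missed report, a
  non-qualifying report, or the start of monitoring — restarts the streak
  at 1;
* a non-qualifying response clears it.

A missed day breaks streaks because an unreported day is unknown, and a
safety system must not assume a symptom persisted through silence. Streaks
are calendar-consecutive, not report-consecutive.

Further policy decisions, all configurable through `engine_options()`:

* **Re-trigger policy** (`retrigger = "every_day"`, the default): a rule
  fires on every day its condition holds with streak ≥ window, not only the
  first. Deployed systems of this kind log alert counts per symptom far
  exceeding plausible episode counts (e.g. 87 fever alerts from 16
  patients), which is only consistent with per-day re-triggering; no
  cool-down is described anywhere. `"once_per_episode"` is available for
  the alternative reading.
* **Red supersedes yellow** (default on): when a red and a yellow rule for
  the *same symptom* fire on the same report, only the red alert is
  emitted — one phone call is made either way — but the yellow streak still
  advances, so a symptom that de-escalates can still complete a yellow
  window.
* **Phase switch resets streaks.** The chemotherapy panel has no multi-day
  windows and its rule identities differ, so a streak begun under one panel
  has no meaning under the other. The phase switches *on* the chemotherapy
  start date (inclusive): infusion-day symptoms should be judged by the
  chemotherapy rules. The boundary convention is ours; the source workflow
  does not state one.
* **Whether a red-qualifying day feeds the same symptom's yellow window**
  is likewise unstated; the engine advances both streaks, which is the
  conservative (more alerting) reading.

### Two implementations and one oracle

`run_timeline()` is the production path: a vectorized run-length
computation per rule (`gap`/`start-of-run`/`cummax` bookkeeping over the
report dates). `evaluate_report()` is the incremental single-report
operation with explicit `StreakState`, usable for online evaluation; a fold
of it over a timeline is the reference semantics. `oracle_alerts()` is a
third, deliberately naive route: for each rule and date it directly asks
whether the trailing `window_days` dates were all qualifying. The test
suite asserts all three agree — exhaustively on every frequency sequence of
length ≤ 6, and on hundreds of seeded random cohorts.

## Canonicalization and phases

Raw submissions may contain resubmissions; `canonicalize()` keeps the
latest `submitted_at` per patient-day ("how do I feel today" semantics),
drops rows outside the patient's closed reporting window `[start, end]`
into a `rejected` attribute with a warning, and sorts. An exact timestamp
tie has no temporal winner, so ties are broken by content ordering —
without this, canonicalization would depend on input order, violating its
own idempotence/permutation-invariance contract.

## Contact scheduling

`schedule_contact()` converts an alert into a contact task under a
`work_calendar()` (defaults: 08:00–16:00, Saturday/Sunday off, no
holidays; extra non-working dates are representable). Within working
hours, red deadline = submission + 1 h, yellow = end of the working day.
A red alert submitted after 15:00 is **clipped to 16:00** rather than
spilling into the next day — "same day" is the outer bound the clinic
workflow supports; the source material does not specify this corner, so it
is a package decision. Outside working hours the task is deferred to the
next working day's opening (same-day opening if submitted before 08:00 on
a working day), and the red/yellow rules run from there. The end bound is
exclusive: a report at exactly 16:00 is already outside working hours.

## Analytics

* `adherence()`: days reported ÷ days expected (every day of the closed
  window — no excusals, since none are defined in the source workflow), as
  a percentage.
* `pct()` rounds **half-up** at the caller's precision, matching how
  clinical percentages are conventionally printed (13.655 → 13.7); base
  R's round-half-even would disagree on exactly such cases.
* `symptom_summary()`: per-symptom occurrence counts and shares, and
  mean (SD) of frequency/distress codes over occurrence-positive
  responses. Whether such tables pool responses across patients or average
  per-patient means first is genuinely ambiguous in descriptive reports;
  **pooled is the default** and `mode = "per_patient"` provides the other
  reading. Zero-occurrence symptoms get `NA` means, flagged rather than
  dropped.
* `alert_summary()` / `advice_summary()`: per-symptom red/yellow tallies
  with per-patient medians and ranges; per-advice view and viewer counts.

## The synthetic cohort

Real patient-level streams from studies of this kind are unpublished, so
`generate_cohort()` states a world with the structure the engine assumes:

* **Occurrence** of each symptom follows a two-state Markov chain per
  patient-day (`p_onset`, `p_persist`), the simplest process that produces
  the multi-day occurrence streaks consecutive-day rules need. Defaults
  order symptoms by clinical plausibility after pancreatic surgery
  (fatigue `p_onset` 0.15 / `p_persist` 0.85 down to fever 0.01 / 0.30).
  The latent state evolves on every calendar day, including unreported
  ones.
* **Severity codes** are resampled i.i.d. on each occurring day from
  `severity_dist` (default 0.30/0.40/0.20/0.10 over codes 1–4, mean ≈ 2.1,
  matching the 2.1–2.5 pooled means such cohorts report).
* **Follow-up** lengths are Beta(2.6, 1.2)-skewed inside 35–245 days —
  most patients complete the ~6-month programme, a tail stops early —
  giving a median near 190 days. **Missed days** are i.i.d. per day with a
  per-patient Beta(1.6, 7.3) probability (mean ≈ 0.18), so cohort
  adherence spans roughly 25–100% with a median in the low 80s. **85% of
  patients** start chemotherapy 3–8 weeks into reporting (treatment must
  begin within 10 weeks of surgery; reporting starts after discharge).
* A **truth log** records every (patient, rule, day) qualification,
  computed at generation time by direct label lookup — a code path
  independent of the engine — for the oracle to scan.
* Randomness fans out from one master seed into per-patient substreams, so
  enlarging a cohort leaves existing patients byte-identical.

These choices were made once, from the stated clinical regime, and are
exercised by soft sanity checks only (follow-up within its envelope,
median adherence above 60%); they are not tuned against any test outcome.
What a green oracle-equivalence run establishes is that the engine
computes the declared streak semantics correctly on data with realistic
persistence, gaps and phase switches — not that the simulator reproduces
any real cohort's alert mix. In particular the simulator has no
free-text behaviour worth analyzing, no within-week seasonality, no
correlation between symptoms, and no reporting-fatigue trend; conclusions
about those phenomena cannot be drawn from it.

## Numerical and degenerate-input choices

* Ordinal codes are integers; no floating-point comparisons occur in rule
  evaluation. `pct()` nudges by a relative epsilon before flooring so that
  binary-representation error on exact halves cannot round down.
* Empty rulesets, empty report streams, empty ledgers and empty view logs
  all yield empty, correctly-typed tables, never errors.
* Alert identifiers are FNV-1a hashes of (patient, rule, date): stable
  across reruns, content-addressed, and independent of evaluation order.
* Reports dated outside a patient's window are rejected loudly rather than
  silently clipped; a zero-length reporting window is an error.

## Known limitations

* The two lowest frequency/distress labels ("Seldom"/"Sometimes",
  "A little"/"Somewhat") are conventional defaults — the source instrument
  names only the alert-qualifying upper categories — and are overridable
  per ruleset document.
* Free text is carried opaquely; no NLP. In the real service patients used
  free text to modulate contact ("no need to call me"), which is a human
  workflow outside the engine.
* The scheduler models deadlines, not delivery: no SMS/phone integration,
  no nurse assignment.
* Single-timezone (UTC) timestamps; a deployment spanning timezones would
  need zone-aware calendars.
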