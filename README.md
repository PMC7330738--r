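# sentinel

Rule-based alerting and adherence analytics for daily patient-reported
symptom monitoring.

## The problem

After pancreatic cancer surgery (pancreaticoduodenectomy), patients carry a
heavy symptom burden at home and much of the responsibility for managing
it. Remote-monitoring services ask them to submit a short daily report —
for each symptom: occurrence (yes/no) and, when present, frequency and
distress on 4-point ordinal scales — and screen those reports with a
clinical **risk-assessment ruleset**. Each rule maps

> (symptom, rated dimension, qualifying response labels, *N* consecutive
> days, care phase) → alert severity

with two severities: **red** (contact the patient within 1 hour) and
**yellow** (contact the same working day). The rule panel differs by care
phase: 12 symptoms with 1/2/3/7-day windows after surgery; 15 symptoms with
single-report rules only during adjuvant chemotherapy. `sentinel`
implements this engine end to end for analysts and research engineers
working with ePRO (electronic patient-reported outcome) data:

* **ruleset** — typed rules/scales/catalog, a built-in pancreatic-surgery
  ruleset (30 rules), YAML load/serialize with validation;
* **reports** — patient profiles, canonicalization of raw submissions
  (latest same-day submission wins), phase assignment, validation;
* **alert engine** — consecutive-day streak evaluation with
  missed-day resets, per-day re-triggering, red-supersedes-yellow
  collision handling, phase resets, advice suggestions;
* **scheduler** — contact deadlines under a working-hours calendar
  (default 08:00–16:00, weekdays), with deferral of out-of-hours alerts to
  the next working day;
* **analytics** — adherence (days reported / days expected), half-up
  rounded percentages, per-symptom occurrence/frequency/distress tables,
  alert and advice-view summaries;
* **synthetic cohort** — a seeded simulator (two-state Markov symptom
  occurrence, missed days, phase switches) emitting a truth log, plus an
  independent brute-force window-scan **oracle** the engine is tested
  against;
* **pipeline/CLI** — `run_pipeline()` and a `sentinel` command-line
  dispatcher (simulate → evaluate → schedule → summarize) with a manifest.

The streak semantics in one line: a rule fires when its qualifying
condition held on `window_days` *calendar*-consecutive reported days; any
gap — missed report, non-qualifying answer, phase switch — resets the run.

## Worked example

```r
library(sentinel)

rs <- builtin_pancreas_ruleset()
co <- generate_cohort(cohort_params(n_patients = 6, seed = 42))
alerts <- run_cohort(co$profiles, co$reports, rs)

nrow(alerts)                        # 225 alerts
sum(alerts$severity == "red")       # 63
sum(alerts$severity == "yellow")    # 162

head(alerts[, .(patient_id, symptom_id, severity, trigger_date, streak_length)], 3)
#>    patient_id symptom_id severity trigger_date streak_length
#> 1:       P001  dizziness   yellow   2015-04-28             2
#> 2:       P001  dizziness      red   2015-05-14             1
#> 3:       P001       pain      red   2015-05-18             1
```

P001's first yellow dizziness alert fired on the second consecutive
qualifying day (the 2-day window rule); the red alerts are single-report
rules firing the same day.

```r
cohort_adherence(co$profiles, co$reports)
#>    patient_id days_reported days_expected adherence_pct
#> 1:       P001           183           201          91.0
#> 2:       P002           178           239          74.5
#> 3:       P003           186           235          79.1
#> 4:       P004           159           176          90.3
#> 5:       P005           130           157          82.8
#> 6:       P006            59           130          45.4
```

Adherence is the share of expected reporting days (every day of the
patient's window) with a submitted report.

```r
schedule_contacts(alerts)[1:2, .(severity, submitted_at, contact_deadline, deferred)]
#>    severity        submitted_at    contact_deadline deferred
#> 1:   yellow 2015-04-28 17:21:24 2015-04-29 16:00:00     TRUE
#> 2:      red 2015-05-14 15:05:17 2015-05-14 16:00:00    FALSE
```

The 17:21 yellow alert was submitted after hours, so it defers to the next
working day with an end-of-day deadline; the 15:05 red alert's 1-hour
deadline is clipped to the 16:00 close.

```r
pct(182, 512, 1)   # 35.5  — half-up percentage, e.g. red share of alerts
```

## Verification

The engine is checked three ways against independent computations: an
incremental per-report fold (`evaluate_report()`), the vectorized
production path (`run_timeline()`), and a brute-force trailing-window scan
(`oracle_alerts()`) over the simulator's truth log — exhaustively on all
5460 frequency sequences of length ≤ 6 and on 200 seeded random cohorts.

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "sentinel", load_package = "installed")'
```

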