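Package: sentinel
Title: Rule-Based Alerting and Adherence Analytics for Daily Symptom Reports
Version: 0.1.0
Authors@R:
    person("Sentinel", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: An engine for remote symptom monitoring in post-surgical cancer
    care. Patients submit daily reports scoring symptom occurrence (yes/no)
    and frequency or distress on 4-point ordinal scales; a phase-dependent
    risk-assessment ruleset turns those reports into red and yellow alerts
    via single-report and consecutive-day streak rules. The package ships
    the built-in pancreatic-surgery ruleset (post-surgery and adjuvant
    chemotherapy phases), a working-hours contact scheduler, adherence and
    cohort summary analytics, a seeded synthetic-cohort simulator with an
    independent brute-force alert oracle, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
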