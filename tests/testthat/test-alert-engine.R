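# The alert engine: qualification, streaks, re-triggering, severity
# collision, phase resets — cross-checked against an independent
# window-scan oracle written in the test helpers.

test_that("response_qualifies maps codes to labels and tests set membership", {
  rs <- builtin_pancreas_ruleset()
  red_pain <- rs$rules$ps_pain_red      # frequency "Almost always"
  yel_pain <- rs$rules$ps_pain_yellow   # frequency "Often" OR "Almost always"
  resp <- function(occ, freq = NA) list(symptom_id = "pain", occurrence = occ,
                                        frequency = freq, distress = NA)
  expect_true(response_qualifies(red_pain, resp(TRUE, 4), rs$scales))
  expect_false(response_qualifies(red_pain, resp(TRUE, 3), rs$scales))
  expect_true(response_qualifies(yel_pain, resp(TRUE, 3), rs$scales))
  expect_false(response_qualifies(yel_pain, resp(TRUE, 2), rs$scales))
  expect_false(response_qualifies(red_pain, resp(FALSE), rs$scales))

  fever <- rs$rules$ps_fever_red
  expect_true(response_qualifies(
    fever, list(symptom_id = "fever", occurrence = TRUE), rs$scales))
  expect_false(response_qualifies(
    fever, list(symptom_id = "fever", occurrence = FALSE), rs$scales))

  # dimension not assessed for the symptom -> error (needs the catalog)
  bogus <- alert_rule("x", "fever", "frequency", "Often", 1, "red",
                      "post_surgery")
  expect_error(response_qualifies(
    bogus, list(symptom_id = "fever", occurrence = TRUE, frequency = 3), rs),
    "not assessed")
  expect_error(response_qualifies(
    red_pain, list(symptom_id = "fever", occurrence = TRUE), rs$scales),
    "different symptom")
})

test_that("window rules fire on the Nth consecutive day only", {
  rs <- builtin_pancreas_ruleset()
  pr <- mini_profile(n_days = 30)
  # loose stool "Often" (code 3) on days 1..3: the window-3 yellow rule
  # fires on day 3 only
  al <- run_timeline(pr[1], stream_reports(c(3, 3, 3),
                                           symptom = "loose_stool"), rs)
  expect_equal(nrow(al), 1)
  expect_equal(al$rule_id, "ps_loose_stool_yellow")
  expect_equal(al$trigger_date, DAY0 + 2)
  expect_equal(al$severity, "yellow")
  expect_equal(al$streak_length, 3L)

  # a missed day breaks the streak: Often on 1,2, gap, Often on 4 -> nothing
  al2 <- run_timeline(pr[1], stream_reports(c(3, 3, NA, 3),
                                            symptom = "loose_stool"), rs)
  expect_equal(nrow(al2), 0)

  # ... and a reported non-qualifying day breaks it just the same
  al3 <- run_timeline(pr[1], stream_reports(c(3, 3, 1, 3),
                                            symptom = "loose_stool"), rs)
  expect_equal(nrow(al3), 0)
})

test_that("red supersedes yellow for the same symptom, same day", {
  rs <- builtin_pancreas_ruleset()
  pr <- mini_profile(n_days = 10)
  # vomiting "Almost always": red window-1 fires; the window-2 yellow rule
  # must not double-report on day 2 even though its streak reached 2
  al <- run_timeline(pr[1], stream_reports(c(4, 4), symptom = "vomiting"), rs)
  expect_equal(sort(unique(al$severity)), "red")
  expect_equal(nrow(al), 2)
  # but the yellow streak kept advancing: dropping to "Sometimes" (code 2)
  # on day 3 completes a yellow window whose streak includes days 1-2
  al2 <- run_timeline(pr[1], stream_reports(c(4, 4, 2), symptom = "vomiting"),
                      rs)
  y <- al2[severity == "yellow"]
  expect_equal(y$trigger_date, DAY0 + 2)
  expect_equal(y$streak_length, 3L)
})

test_that("window-1 rules re-trigger on every qualifying day", {
  rs <- builtin_pancreas_ruleset()
  pr <- mini_profile(n_days = 40)
  # fever on k scattered days -> k red alerts
  codes <- rep(0, 30)
  fever_days <- c(2, 3, 9, 17, 30)
  codes[fever_days] <- 1
  fever_stream <- stream_reports(ifelse(codes == 1, 1, 0), symptom = "fever")
  fever_stream$frequency <- NA_integer_  # fever is occurrence-only
  al <- run_timeline(pr[1], fever_stream, rs)
  expect_equal(nrow(al), length(fever_days))
  expect_true(all(al$severity == "red"))
  expect_equal(al$trigger_date, DAY0 + fever_days - 1)

  # all-"no" reports emit nothing
  expect_equal(nrow(run_timeline(pr[1], stream_reports(rep(0, 30),
                                                       symptom = "fever"),
                                 rs)), 0)
})

test_that("streaks reset at the phase switch", {
  rs <- builtin_pancreas_ruleset()
  pr <- patient_profiles("P1", DAY0, DAY0 + 29, chemo_start = DAY0 + 2)
  # pain "Often" every day; post-surgery yellow needs 7 consecutive days but
  # only days 1-2 are post-surgery; chemo has no "Often" pain rule, so the
  # streak must not carry over and nothing may ever fire
  al <- run_timeline(pr[1], stream_reports(rep(3, 12), symptom = "pain"), rs)
  expect_equal(nrow(al), 0)
  # whereas without the phase switch day 7 fires
  pr2 <- patient_profiles("P2", DAY0, DAY0 + 29)
  al2 <- run_timeline(pr2[1], stream_reports(rep(3, 12), pid = "P2",
                                             symptom = "pain"), rs)
  expect_equal(al2$trigger_date, DAY0 + 6:11)
})

test_that("exhaustive: engine equals window-scan oracle on all short streams", {
  # every frequency sequence of length 1..6 over codes 1..4, run as one
  # multi-patient cohort through the engine and compared day-by-day with
  # the independent brute-force oracle
  rs <- mini_ruleset()
  all_codes <- list()
  for (len in 1:6)
    all_codes <- c(all_codes,
                   asplit(as.matrix(expand.grid(rep(list(1:4), len))), 1))
  pids <- sprintf("S%04d", seq_along(all_codes))
  reports <- data.table::rbindlist(
    Map(function(codes, pid) stream_reports(codes, pid = pid), all_codes,
        pids))
  profiles <- patient_profiles(pids, DAY0, DAY0 + 6)
  alerts <- run_cohort(profiles, reports, rs)
  got <- split(alerts[, .(day = as.integer(trigger_date - DAY0) + 1L,
                          rule_id, patient_id)],
               by = "patient_id", keep.by = FALSE)
  for (i in seq_along(all_codes)) {
    want <- brute_alerts(as.numeric(all_codes[[i]]))
    g <- got[[pids[i]]]
    same <- if (is.null(g)) nrow(want) == 0 else
      identical(unname(as.list(g[order(day, rule_id)])),
                unname(as.list(want)))
    if (!same)  # only pay the waldo-diff cost on an actual mismatch
      expect_equal(if (is.null(g)) data.frame() else
                     as.data.frame(g[order(day, rule_id)]),
                   as.data.frame(want), ignore_attr = TRUE,
                   label = paste("stream", paste(all_codes[[i]],
                                                 collapse = "")))
  }
  succeed()
})

test_that("random streams with gaps: engine equals oracle under both policies", {
  set.seed(99)
  for (rep_i in 1:40) {
    codes <- sample(c(NA, 0:4), sample(5:60, 1), replace = TRUE,
                    prob = c(0.15, 0.25, 0.15, 0.15, 0.15, 0.15))
    for (pol in c("every_day", "once_per_episode")) {
      opt <- engine_options(retrigger = pol)
      got <- engine_alert_days(codes, opt)
      want <- brute_alerts(codes, retrigger = pol)
      expect_equal(as.data.frame(got), as.data.frame(want[, .(day, rule_id)]),
                   ignore_attr = TRUE,
                   label = sprintf("stream %d policy %s", rep_i, pol))
    }
  }
})

test_that("vectorized timeline equals an evaluate_report fold", {
  # run_timeline is a vectorized run-length implementation; folding the
  # incremental evaluate_report over the same reports must agree exactly,
  # including across a mid-stream phase switch
  rs <- builtin_pancreas_ruleset()
  set.seed(123)
  for (i in 1:15) {
    n_days <- sample(10:40, 1)
    chemo <- if (i %% 2 == 0) DAY0 + sample(3:(n_days - 3), 1) else NA
    pr <- patient_profiles("P1", DAY0, DAY0 + n_days - 1, chemo_start = chemo)
    reports <- data.table::rbindlist(lapply(
      c("pain", "vomiting", "fever", "nausea"),
      function(s) stream_reports(sample(c(NA, 0:4), n_days, replace = TRUE),
                                 symptom = s)))
    reports[symptom_id == "fever", frequency := NA_integer_]
    srt <- function(x) as.data.frame(
      data.table::setorder(x, trigger_date, rule_id))
    fast <- run_timeline(pr[1], reports, rs)
    slow <- sentinel:::run_timeline_fold(pr[1], reports, rs)
    expect_equal(srt(fast), srt(slow), ignore_attr = TRUE,
                 label = paste("case", i))
    opt <- engine_options(retrigger = "once_per_episode")
    expect_equal(srt(run_timeline(pr[1], reports, rs, opt)),
                 srt(sentinel:::run_timeline_fold(pr[1], reports, rs, opt)),
                 ignore_attr = TRUE, label = paste("case", i, "episode"))
  }
})

test_that("monotonicity: appending a qualifying day never removes alerts", {
  set.seed(7)
  for (i in 1:20) {
    codes <- sample(c(NA, 0:4), 15, replace = TRUE)
    base <- engine_alert_days(codes)
    ext <- engine_alert_days(c(codes, 4))
    expect_true(nrow(data.table::fsetdiff(base, ext)) == 0,
                label = paste("stream", i))
  }
})

test_that("alert ids and ordering are deterministic", {
  co <- generate_cohort(cohort_params(n_patients = 3,
                                      followup_days_range = c(15, 25),
                                      seed = 21))
  rs <- builtin_pancreas_ruleset()
  a1 <- run_cohort(co$profiles, co$reports, rs)
  a2 <- run_cohort(co$profiles, co$reports, rs)
  expect_identical(a1, a2)
  expect_false(anyDuplicated(a1$alert_id) > 0)
  # ids are content-addressed: same (patient, rule, date) -> same id
  expect_identical(a1$alert_id,
                   sentinel:::alert_id_for(a1$patient_id, a1$rule_id,
                                           a1$trigger_date))
})

test_that("suggest_advice deduplicates and warns on unmapped symptoms", {
  rs <- builtin_pancreas_ruleset()
  pr <- mini_profile(n_days = 10)
  al <- run_timeline(pr[1], stream_reports(c(1, 1), symptom = "fever"), rs)
  expect_equal(suggest_advice(al), "adv_fever")
  expect_equal(suggest_advice(al[0]), character())
  expect_warning(out <- suggest_advice(al, advice_map = list(pain = "adv_pain")),
                 "no advice mapped")
  expect_equal(out, character())
})
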