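# Independent brute-force alert oracle.
#
# The oracle never tracks streaks. For each rule and each candidate date it
# directly asks: were the `window_days` trailing calendar dates *all*
# qualifying for this rule? This is the definition of a consecutive-day
# alert, implemented by direct window scan, and is the cross-check for the
# incremental engine.

#' Enumerate alerts by direct window scan of a qualification log
#'
#' @param truth_log a data.frame with columns `patient_id`, `rule_id`,
#'   `qual_date` (Date): one row per (patient, rule, day) on which the
#'   rule's qualifying condition held on a submitted report. Days with no
#'   row were either unreported or non-qualifying — either way they break a
#'   window.
#' @param rs the [ruleset] the log refers to.
#' @param options an [engine_options()] object; the oracle honours the same
#'   re-trigger and red-supersedes-yellow policies so its output is
#'   comparable to the engine's ledger.
#' @return data.table with columns `patient_id`, `rule_id`, `symptom_id`,
#'   `severity`, `trigger_date`, `streak_length`, sorted.
#' @export
oracle_alerts <- function(truth_log, rs, options = engine_options()) {
  tl <- data.table::as.data.table(truth_log)
  empty <- data.table::data.table(
    patient_id = character(), rule_id = character(), symptom_id = character(),
    severity = character(), trigger_date = as.Date(character()),
    streak_length = integer())
  if (!nrow(tl)) return(empty)
  tl[, qual_date := as.Date(qual_date)]
  rt <- rules_table(rs)

  rows <- list()
  for (pid in unique(tl$patient_id)) {
    for (rid in unique(tl[patient_id == pid, rule_id])) {
      rule <- rs$rules[[rid]]
      if (is.null(rule))
        stop("truth log references unknown rule ", rid, call. = FALSE)
      qd <- sort(unique(tl[patient_id == pid & rule_id == rid, qual_date]))
      w <- rule$window_days
      for (di in seq_along(qd)) {
        d <- qd[di]
        window <- seq(d - w + 1L, d, by = "day")
        if (all(window %in% qd)) {
          # streak length = full run of consecutive qualifying days ending at d
          len <- 0L
          while ((d - len) %in% qd) len <- len + 1L
          if (options$retrigger == "every_day" ||
              (options$retrigger == "once_per_episode" && len == w)) {
            rows[[length(rows) + 1L]] <- data.table::data.table(
              patient_id = pid, rule_id = rid, symptom_id = rule$symptom_id,
              severity = rule$severity, trigger_date = d,
              streak_length = len)
          }
        }
      }
    }
  }
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) return(empty)
  if (options$red_supersedes_yellow) {
    reds <- out[severity == "red", .(patient_id, symptom_id, trigger_date)]
    if (nrow(reds)) {
      reds[, .red := TRUE]
      out <- merge(out, reds, all.x = TRUE,
                   by = c("patient_id", "symptom_id", "trigger_date"))
      out <- out[!(severity == "yellow" & !is.na(.red))][, .red := NULL]
    }
  }
  data.table::setorder(out, patient_id, trigger_date, rule_id)
  data.table::setcolorder(out, names(empty))
  out[]
}

#' Per-rule alert counts by direct window scan
#'
#' @inheritParams oracle_alerts
#' @return data.table with one row per rule that alerted: `rule_id`,
#'   `symptom_id`, `severity`, `n_alerts`, `n_patients`.
#' @export
oracle_count_alerts <- function(truth_log, rs, options = engine_options()) {
  al <- oracle_alerts(truth_log, rs, options)
  if (!nrow(al))
    return(data.table::data.table(rule_id = character(),
                                  symptom_id = character(),
                                  severity = character(),
                                  n_alerts = integer(),
                                  n_patients = integer()))
  al[, .(n_alerts = .N, n_patients = data.table::uniqueN(patient_id)),
     by = .(rule_id, symptom_id, severity)][order(rule_id)]
}

#' Build a qualification log directly from canonical reports
#'
#' A second, declarative route to the truth log (the simulator emits its own
#' during generation): for every report row and phase-matching rule, test
#' the qualifying condition with [response_qualifies()].
#'
#' @param profiles patient profile table.
#' @param reports canonical reports.
#' @param rs a [ruleset].
#' @return truth-log data.table (`patient_id`, `rule_id`, `qual_date`).
#' @export
qualification_log <- function(profiles, reports, rs) {
  r <- normalize_reports(reports)
  p <- data.table::as.data.table(profiles)
  rows <- list()
  for (i in seq_len(nrow(p))) {
    pr <- p[i]
    rp <- r[patient_id == pr$patient_id]
    if (!nrow(rp)) next
    rp[, phase := assign_phase(pr, report_date)]
    for (j in seq_len(nrow(rp))) {
      for (rule in phase_rules(rs, rp$phase[j])) {
        if (rule$symptom_id != rp$symptom_id[j]) next
        if (response_qualifies(rule, rp[j], rs$scales))
          rows[[length(rows) + 1L]] <- data.table::data.table(
            patient_id = pr$patient_id, rule_id = rule$rule_id,
            qual_date = rp$report_date[j])
      }
    }
  }
  out <- data.table::rbindlist(rows)
  if (!nrow(out))
    out <- data.table::data.table(patient_id = character(),
                                  rule_id = character(),
                                  qual_date = as.Date(character()))
  out[]
}
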