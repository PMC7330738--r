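# Alert engine: evaluates canonical daily reports against the phase-matching
# rules, maintaining a per-rule consecutive-day streak. A rule fires when its
# qualifying condition has held on `window_days` *calendar*-consecutive
# reported days: a missed day is unknown, and a safety system must not assume
# a symptom persisted through silence, so gaps reset every streak.

#' Engine policy switches
#'
#' @param retrigger `"every_day"` (default): a rule fires on every day its
#'   condition holds with streak >= window, matching deployments where the
#'   alert count per symptom can far exceed the episode count;
#'   `"once_per_episode"`: fire only on the day the streak first reaches the
#'   window.
#' @param red_supersedes_yellow if `TRUE` (default), when a red and a yellow
#'   rule for the *same symptom* both fire on the same report only the red
#'   alert is emitted (one phone call is made either way); yellow streaks
#'   still advance.
#' @return a list of class `engine_options`.
#' @export
engine_options <- function(retrigger = c("every_day", "once_per_episode"),
                           red_supersedes_yellow = TRUE) {
  structure(list(retrigger = match.arg(retrigger),
                 red_supersedes_yellow = isTRUE(red_supersedes_yellow)),
            class = "engine_options")
}

#' Fresh streak state for a ruleset
#'
#' One tracker per rule: the current run length of calendar-consecutive
#' qualifying days and the date of the last qualifying report.
#'
#' @param rs a [ruleset].
#' @return named list rule_id -> list(run_length, last_qualifying_date).
#' @export
new_streak_state <- function(rs) {
  out <- lapply(rs$rules, function(r)
    list(run_length = 0L, last_qualifying_date = as.Date(NA)))
  names(out) <- names(rs$rules)
  out
}

#' Does a response qualify for a rule?
#'
#' Maps the rated value to its response label via the dimension's scale and
#' tests membership in the rule's qualifying set. For occurrence rules the
#' label is derived from the yes/no answer. Comparison is always by the
#' label/code map, never by string order.
#'
#' @param rule an [alert_rule].
#' @param response a list or one-row data.frame with fields `symptom_id`,
#'   `occurrence`, and (optionally) `frequency` and `distress` codes.
#' @param scales named list of [rating_scale]s, or a whole [ruleset] (whose
#'   catalog is then used to verify the dimension is assessed).
#' @return `TRUE` or `FALSE`.
#' @export
response_qualifies <- function(rule, response, scales) {
  if (inherits(scales, "ruleset")) {
    sym <- scales$catalog[[rule$symptom_id]]
    if (!is.null(sym) && !rule$dimension %in% sym$dimensions)
      stop(sprintf("dimension '%s' is not assessed for symptom '%s'",
                   rule$dimension, rule$symptom_id), call. = FALSE)
    scales <- scales$scales
  }
  if (!is.null(response$symptom_id) &&
      as.character(response$symptom_id) != rule$symptom_id)
    stop("response is for a different symptom than the rule", call. = FALSE)
  occ <- isTRUE(as.logical(response$occurrence))
  if (rule$dimension == "occurrence") {
    label <- scale_label(scales$occurrence, as.integer(occ))
    return(label %in% rule$responses)
  }
  if (!occ) return(FALSE)  # follow-up dimensions only exist when occurring
  code <- response[[rule$dimension]]
  if (is.null(code) || length(code) == 0 || is.na(code)) return(FALSE)
  label <- scale_label(scales[[rule$dimension]], as.integer(code))
  if (is.na(label))
    stop(sprintf("code %s is not on the %s scale", code, rule$dimension),
         call. = FALSE)
  label %in% rule$responses
}

alert_id_for <- function(patient_id, rule_id, trigger_date) {
  fnv1a32(paste(patient_id, rule_id, as.character(trigger_date), sep = "|"))
}

empty_alerts <- function() {
  data.table::data.table(
    alert_id = character(), patient_id = character(), rule_id = character(),
    symptom_id = character(), severity = character(),
    trigger_date = as.Date(character()),
    triggered_at = as.POSIXct(character(), tz = "UTC"),
    streak_length = integer()
  )
}

#' Evaluate one canonical daily report
#'
#' Updates every phase-matching rule's streak and emits the alerts due on
#' this report. Streak semantics: a qualifying response on the day after the
#' last qualifying date extends the run; a qualifying response after any gap
#' (missed day, non-qualifying day, or first report) restarts it at 1; a
#' non-qualifying response clears it. A rule fires when the run length
#' reaches its window (see [engine_options()] for the re-trigger policy).
#' If a red and a yellow rule for the same symptom both fire on one report,
#' only the red alert is emitted.
#'
#' @param report a list with `patient_id`, `report_date`, `submitted_at`,
#'   `phase`, and `responses` (data.frame with `symptom_id`, `occurrence`,
#'   `frequency`, `distress`).
#' @param rs a [ruleset].
#' @param state streak state from [new_streak_state()] or a previous call.
#' @param options an [engine_options()] object.
#' @return list with `alerts` (data.table, possibly empty) and `state`.
#' @export
evaluate_report <- function(report, rs, state, options = engine_options()) {
  rules <- phase_rules(rs, report$phase)
  date <- as.Date(report$report_date)
  resp <- report$responses
  resp_idx <- match(vapply(rules, `[[`, "", "symptom_id"), resp$symptom_id)

  fired <- list()
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    st <- state[[r$rule_id]]
    i <- resp_idx[[k]]
    qual <- if (is.na(i)) FALSE else
      response_qualifies(r, lapply(resp, `[[`, i), rs$scales)
    if (qual) {
      consecutive <- !is.na(st$last_qualifying_date) &&
        date == st$last_qualifying_date + 1L
      st$run_length <- if (consecutive) st$run_length + 1L else 1L
      st$last_qualifying_date <- date
      fire <- if (options$retrigger == "every_day")
        st$run_length >= r$window_days
      else st$run_length == r$window_days
      if (fire)
        fired[[length(fired) + 1L]] <- list(rule = r, streak = st$run_length)
    } else {
      st$run_length <- 0L
      st$last_qualifying_date <- as.Date(NA)
    }
    state[[r$rule_id]] <- st
  }

  if (!length(fired)) return(list(alerts = empty_alerts(), state = state))

  sev <- vapply(fired, function(f) f$rule$severity, "")
  sy <- vapply(fired, function(f) f$rule$symptom_id, "")
  keep <- rep(TRUE, length(fired))
  if (options$red_supersedes_yellow) {
    red_symptoms <- unique(sy[sev == "red"])
    keep <- !(sev == "yellow" & sy %in% red_symptoms)
  }
  fired <- fired[keep]
  if (!length(fired)) return(list(alerts = empty_alerts(), state = state))

  alerts <- data.table::data.table(
    patient_id = report$patient_id,
    rule_id = vapply(fired, function(f) f$rule$rule_id, ""),
    symptom_id = vapply(fired, function(f) f$rule$symptom_id, ""),
    severity = vapply(fired, function(f) f$rule$severity, ""),
    trigger_date = date,
    triggered_at = as_time_utc(report$submitted_at),
    streak_length = vapply(fired, function(f) as.integer(f$streak), 1L)
  )
  alerts[, alert_id := alert_id_for(patient_id, rule_id, trigger_date)]
  data.table::setcolorder(alerts, names(empty_alerts()))
  list(alerts = alerts, state = state)
}

#' Run the engine over one patient's timeline
#'
#' Evaluates the patient's canonical reports in date order with the same
#' streak semantics as a day-by-day fold of [evaluate_report()] (the two
#' routes are property-tested against each other), implemented as a
#' vectorized run-length computation per rule. All streaks are reset when
#' the care phase switches: the rule identities differ across phases and a
#' streak begun under one panel has no meaning under the other.
#'
#' @param profile one-row patient profile.
#' @param reports canonical long-format reports (may include other patients;
#'   they are ignored).
#' @param rs a [ruleset].
#' @param options an [engine_options()] object.
#' @return alert ledger `data.table` sorted by trigger date.
#' @export
run_timeline <- function(profile, reports, rs, options = engine_options()) {
  r <- normalize_reports(reports)
  run_timeline_normalized(profile, r[patient_id == profile$patient_id],
                          rs, options)
}

run_timeline_normalized <- function(profile, r, rs, options) {
  if (!nrow(r)) return(empty_alerts())
  data.table::setorder(r, report_date, symptom_id)
  dates <- unique(r$report_date)
  phases <- assign_phase(profile, dates)
  sub_at <- r$submitted_at[match(dates, r$report_date)]

  out <- list()
  for (ph in unique(phases)) {
    in_ph <- phases == ph
    block <- eval_phase_block(r[report_date %in% dates[in_ph]],
                              dates[in_ph], phase_rules(rs, ph),
                              rs$scales, options)
    if (!is.null(block)) out[[length(out) + 1L]] <- block
  }
  if (!length(out)) return(empty_alerts())
  alerts <- data.table::rbindlist(out)
  if (options$red_supersedes_yellow && nrow(alerts)) {
    red_keys <- alerts[severity == "red",
                       paste(symptom_id, trigger_date)]
    alerts <- alerts[!(severity == "yellow" &
                         paste(symptom_id, trigger_date) %in% red_keys)]
  }
  if (!nrow(alerts)) return(empty_alerts())
  alerts[, patient_id := profile$patient_id]
  alerts[, triggered_at := sub_at[match(trigger_date, dates)]]
  alerts[, alert_id := alert_id_for(patient_id, rule_id, trigger_date)]
  data.table::setorder(alerts, trigger_date, rule_id)
  data.table::setcolorder(alerts, names(empty_alerts()))
  alerts[]
}

# vectorized per-rule streak evaluation over one contiguous phase block
eval_phase_block <- function(rb, dates, rules, scales, options) {
  if (!length(rules) || !length(dates)) return(NULL)
  gap <- c(TRUE, diff(as.integer(dates)) != 1L)
  pos <- seq_along(dates)
  by_symptom <- split(rb, by = "symptom_id")
  hits <- list()
  for (rule in rules) {
    sym_rows <- by_symptom[[rule$symptom_id]]
    if (is.null(sym_rows)) next
    i <- match(dates, sym_rows$report_date)
    occ <- !is.na(i) & sym_rows$occurrence[i] %in% TRUE
    qual <- if (rule$dimension == "occurrence") {
      # an unanswered symptom never qualifies, even for "No"-label rules
      !is.na(i) &
        scales$occurrence$labels[as.integer(occ) + 1L] %in% rule$responses
    } else {
      code <- sym_rows[[rule$dimension]][i]
      occ & !is.na(code) & scales[[rule$dimension]]$labels[code] %in%
        rule$responses
    }
    if (!any(qual)) next
    start_new <- qual & (gap | !c(FALSE, qual[-length(qual)]))
    run_start <- cummax(ifelse(start_new, pos, 0L))
    streak <- ifelse(qual, pos - run_start + 1L, 0L)
    fire <- if (options$retrigger == "every_day")
      streak >= rule$window_days
    else streak == rule$window_days
    if (!any(fire)) next
    hits[[length(hits) + 1L]] <- data.table::data.table(
      rule_id = rule$rule_id, symptom_id = rule$symptom_id,
      severity = rule$severity, trigger_date = dates[fire],
      streak_length = as.integer(streak[fire]))
  }
  if (!length(hits)) return(NULL)
  data.table::rbindlist(hits)
}

# reference implementation: day-by-day fold of evaluate_report(); kept as
# the cross-check route for the vectorized run_timeline
run_timeline_fold <- function(profile, reports, rs,
                              options = engine_options()) {
  r <- normalize_reports(reports)
  r <- r[patient_id == profile$patient_id]
  if (!nrow(r)) return(empty_alerts())
  data.table::setorder(r, report_date, symptom_id)
  days <- split(r, by = "report_date")

  state <- new_streak_state(rs)
  prev_phase <- NULL
  out <- vector("list", length(days))
  for (j in seq_along(days)) {
    d <- days[[j]]
    phase <- assign_phase(profile, d$report_date[1])
    if (!is.null(prev_phase) && phase != prev_phase)
      state <- new_streak_state(rs)
    prev_phase <- phase
    rep_obj <- list(patient_id = profile$patient_id,
                    report_date = d$report_date[1],
                    submitted_at = d$submitted_at[1],
                    phase = phase,
                    responses = d[, .(symptom_id, occurrence, frequency, distress)])
    ev <- evaluate_report(rep_obj, rs, state, options)
    state <- ev$state
    out[[j]] <- ev$alerts
  }
  data.table::rbindlist(out)
}

#' Run the engine over a whole cohort
#'
#' @param profiles patient profile table.
#' @param reports canonical long-format reports.
#' @param rs a [ruleset].
#' @param options an [engine_options()] object.
#' @return combined alert ledger for all patients.
#' @export
run_cohort <- function(profiles, reports, rs, options = engine_options()) {
  p <- data.table::as.data.table(profiles)
  r <- normalize_reports(reports)
  by_patient <- split(r, by = "patient_id")
  out <- lapply(seq_len(nrow(p)), function(i)
    run_timeline_normalized(p[i], by_patient[[p$patient_id[i]]] %||% r[0],
                            rs, options))
  data.table::rbindlist(out)
}

#' Suggest self-care advice for a set of alerts
#'
#' When an alert fires the patient is pointed to the self-care advice for
#' the alerting symptom(s). Returns deduplicated advice ids in order of
#' first alerting symptom appearance; symptoms missing from the map are
#' skipped with a warning.
#'
#' @param alerts alert ledger (rows for one report or any collection).
#' @param advice_map named list: symptom_id -> character vector of advice
#'   ids (see [builtin_advice_map()]).
#' @return character vector of advice ids (possibly empty).
#' @export
suggest_advice <- function(alerts, advice_map = builtin_advice_map()) {
  if (!nrow(alerts)) return(character())
  syms <- unique(alerts$symptom_id)
  unmapped <- setdiff(syms, names(advice_map))
  if (length(unmapped)) {
    warning("no advice mapped for symptom(s): ",
            paste(unmapped, collapse = ", "), call. = FALSE)
    syms <- setdiff(syms, unmapped)
  }
  unique(unlist(advice_map[syms], use.names = FALSE)) %||% character()
}
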