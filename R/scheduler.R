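# Working-hours contact scheduler.
#
# Alerts are only monitored during clinic working hours (by default 8 am to
# 4 pm on non-weekend days). A red alert submitted within working hours must
# lead to patient contact within 1 hour; a yellow alert the same working
# day. Alerts submitted outside working hours are deferred: the clinic is
# notified at the start of the next working day and the same contact rules
# apply from that point.

#' Construct a clinic work calendar
#'
#' @param work_start,work_end working-hours bounds as `"HH:MM"` strings
#'   (start inclusive, end exclusive; defaults 08:00 and 16:00).
#' @param weekend_days integer weekdays that are off (1 = Monday ... 7 =
#'   Sunday; default Saturday and Sunday).
#' @param holidays optional `Date` vector of extra non-working dates.
#' @return a list of class `work_calendar`.
#' @export
work_calendar <- function(work_start = "08:00", work_end = "16:00",
                          weekend_days = c(6L, 7L),
                          holidays = as.Date(character())) {
  ws <- hm_to_secs(work_start); we <- hm_to_secs(work_end)
  if (ws >= we) stop("work_start must be before work_end", call. = FALSE)
  weekend_days <- as.integer(weekend_days)
  if (any(weekend_days < 1 | weekend_days > 7))
    stop("weekend_days must be in 1..7 (Monday = 1)", call. = FALSE)
  structure(list(work_start = work_start, work_end = work_end,
                 work_start_secs = ws, work_end_secs = we,
                 weekend_days = weekend_days,
                 holidays = as.Date(holidays)),
            class = "work_calendar")
}

iso_weekday <- function(date) {
  # ISO weekday: Monday = 1 ... Sunday = 7
  w <- as.POSIXlt(date)$wday
  ifelse(w == 0L, 7L, w)
}

is_working_day <- function(date, cal) {
  !(iso_weekday(date) %in% cal$weekend_days) & !(as.Date(date) %in% cal$holidays)
}

next_working_day <- function(date, cal) {
  d <- as.Date(date) + 1L
  while (!is_working_day(d, cal)) d <- d + 1L
  d
}

day_at <- function(date, secs) {
  as.POSIXct(as.Date(date), tz = "UTC") + secs
}

#' Schedule clinic contact for one alert
#'
#' If the alert's report was submitted within working hours, the clinic is
#' notified immediately: a red alert's deadline is one hour later (clipped
#' to the end of the working day — "same day" is the outer bound the
#' workflow supports), a yellow alert's deadline is the end of the working
#' day. Outside working hours the task is deferred to the next working
#' day's opening time, from which the same red/yellow rules run.
#'
#' @param alert one alert (a list or one-row data.frame with `alert_id` and
#'   `severity`).
#' @param submitted_at POSIXct timestamp of the triggering report.
#' @param cal a [work_calendar()].
#' @return a one-row `data.table`: `alert_id`, `severity`, `submitted_at`,
#'   `notify_at`, `contact_deadline`, `deferred`.
#' @export
schedule_contact <- function(alert, submitted_at, cal = work_calendar()) {
  t <- as_time_utc(submitted_at)
  sev <- match.arg(as.character(alert$severity), SEVERITIES)
  secs <- secs_of_day(t)
  in_hours <- is_working_day(as.Date(t), cal) &&
    secs >= cal$work_start_secs && secs < cal$work_end_secs

  if (in_hours) {
    notify_at <- t
    deferred <- FALSE
    eod <- day_at(as.Date(t), cal$work_end_secs)
    deadline <- if (sev == "red") min(t + 3600, eod) else eod
  } else {
    # before opening on a working day -> that day's opening; otherwise the
    # next working day's opening
    day <- as.Date(t)
    if (is_working_day(day, cal) && secs < cal$work_start_secs) {
      notify_day <- day
    } else {
      notify_day <- next_working_day(day, cal)
    }
    notify_at <- day_at(notify_day, cal$work_start_secs)
    deferred <- TRUE
    eod <- day_at(notify_day, cal$work_end_secs)
    deadline <- if (sev == "red") min(notify_at + 3600, eod) else eod
  }
  data.table::data.table(
    alert_id = as.character(alert$alert_id %||% NA_character_),
    severity = sev, submitted_at = t, notify_at = notify_at,
    contact_deadline = deadline, deferred = deferred)
}

#' Schedule contacts for an alert ledger
#'
#' @param alerts alert ledger from [run_timeline()] / [run_cohort()] (must
#'   carry `triggered_at`).
#' @param cal a [work_calendar()].
#' @return contact-task `data.table`, one row per alert.
#' @export
schedule_contacts <- function(alerts, cal = work_calendar()) {
  a <- data.table::as.data.table(alerts)
  if (!nrow(a))
    return(data.table::data.table(
      alert_id = character(), severity = character(),
      submitted_at = as.POSIXct(character(), tz = "UTC"),
      notify_at = as.POSIXct(character(), tz = "UTC"),
      contact_deadline = as.POSIXct(character(), tz = "UTC"),
      deferred = logical()))
  out <- lapply(seq_len(nrow(a)), function(i)
    schedule_contact(a[i], a$triggered_at[i], cal))
  data.table::rbindlist(out)
}
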