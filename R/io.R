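# Readers and writers for the interchange formats: long-format CSV (one
# symptom response per row — spreadsheet-auditable) and JSON-lines (one
# whole report per line — lossless nesting). Every writer's output is
# re-readable by the matching reader.

#' Read a long-format report CSV
#'
#' Expected columns: `patient_id, report_date, submitted_at, symptom_id,
#' occurrence, frequency, distress, free_text` (the last three optional).
#'
#' @param path CSV file path.
#' @return normalized long-format `data.table` (not yet canonicalized).
#' @export
read_reports <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  normalize_reports(data.table::fread(path, colClasses = list(
    character = "patient_id")))
}

#' Write reports to long-format CSV
#' @param reports long-format report table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  data.table::fwrite(normalize_reports(reports), path,
                     dateTimeAs = "write.csv")
  invisible(path)
}

#' Read reports from JSON-lines
#'
#' One report per line:
#' `{"patient_id": ..., "report_date": ..., "submitted_at": ...,
#'   "free_text": ..., "responses": [{"symptom_id": ..., "occurrence": ...,
#'   "frequency": ..., "distress": ...}, ...]}`.
#'
#' @param path JSON-lines file path.
#' @return normalized long-format `data.table`.
#' @export
read_reports_jsonl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_reports())
  rows <- lapply(lines, function(ln) {
    doc <- jsonlite::fromJSON(ln, simplifyDataFrame = TRUE)
    resp <- doc$responses
    data.table::data.table(
      patient_id = doc$patient_id, report_date = doc$report_date,
      submitted_at = doc$submitted_at,
      symptom_id = resp$symptom_id,
      occurrence = resp$occurrence,
      frequency = if ("frequency" %in% names(resp)) resp$frequency else NA_integer_,
      distress = if ("distress" %in% names(resp)) resp$distress else NA_integer_,
      # free_text is report-level; the long format carries it on the first
      # response row only
      free_text = c(doc$free_text %||% NA_character_,
                    rep(NA_character_, nrow(resp) - 1L)))
  })
  normalize_reports(data.table::rbindlist(rows, fill = TRUE))
}

#' Write reports to JSON-lines
#' @inheritParams write_reports
#' @export
write_reports_jsonl <- function(reports, path) {
  r <- normalize_reports(reports)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(r)) {
    key <- paste(r$patient_id, r$report_date, r$submitted_at)
    for (grp in split(r, factor(key, levels = unique(key)))) {
      doc <- list(
        patient_id = grp$patient_id[1],
        report_date = as.character(grp$report_date[1]),
        submitted_at = format(grp$submitted_at[1], "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC"),
        free_text = grp$free_text[!is.na(grp$free_text)][1],
        responses = grp[, .(symptom_id, occurrence, frequency, distress)])
      if (is.na(doc$free_text)) doc$free_text <- NULL
      writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, na = "null",
                                  digits = NA), con)
    }
  }
  invisible(path)
}

#' Read / write patient profile CSVs
#' @param path CSV path.
#' @return profile `data.table`.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  p <- data.table::fread(path, colClasses = list(character = "patient_id"))
  patient_profiles(p$patient_id, p$reporting_start, p$reporting_end,
                   if ("chemo_start" %in% names(p)) p$chemo_start else NA,
                   if ("stop_reason" %in% names(p)) p$stop_reason
                   else NA_character_)
}

#' @rdname read_profiles
#' @param profiles profile table.
#' @export
write_profiles <- function(profiles, path) {
  data.table::fwrite(data.table::as.data.table(profiles), path)
  invisible(path)
}

#' Read / write advice-view event CSVs
#' @param path CSV path.
#' @return event `data.table` (`patient_id`, `advice_id`, `viewed_at`).
#' @export
read_advice_views <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- data.table::fread(path, colClasses = list(character = "patient_id"))
  need <- c("patient_id", "advice_id", "viewed_at")
  if (length(setdiff(need, names(v))))
    stop("advice-view file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  v[, patient_id := as.character(patient_id)]
  v[, advice_id := as.character(advice_id)]
  v[, viewed_at := as_time_utc(viewed_at)]
  v[]
}

#' @rdname read_advice_views
#' @param views event table.
#' @export
write_advice_views <- function(views, path) {
  data.table::fwrite(data.table::as.data.table(views), path,
                     dateTimeAs = "write.csv")
  invisible(path)
}

#' Read / write alert ledger CSVs
#' @param path CSV path.
#' @return alert ledger `data.table`.
#' @export
read_alerts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  a <- data.table::fread(path, colClasses = list(character = "patient_id"))
  a[, trigger_date := as.Date(trigger_date)]
  a[, triggered_at := as_time_utc(triggered_at)]
  a[]
}

#' @rdname read_alerts
#' @param alerts ledger table.
#' @export
write_alerts <- function(alerts, path) {
  data.table::fwrite(data.table::as.data.table(alerts), path,
                     dateTimeAs = "write.csv")
  invisible(path)
}

#' Read a work calendar from YAML
#'
#' Keys: `work_start`, `work_end` ("HH:MM"), `weekend_days` (1 = Monday),
#' `holidays` (dates). All optional; defaults are the standard clinic hours.
#'
#' @param path YAML file path.
#' @return a [work_calendar()].
#' @export
read_work_calendar <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  work_calendar(
    work_start = doc$work_start %||% "08:00",
    work_end = doc$work_end %||% "16:00",
    weekend_days = unlist(doc$weekend_days) %||% c(6L, 7L),
    holidays = as.Date(unlist(doc$holidays) %||% character()))
}
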