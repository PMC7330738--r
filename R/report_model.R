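# Patients, phases and daily reports.
#
# Reports are kept in long format: one row per (patient, report day,
# symptom). A "report" is the set of rows sharing (patient_id, report_date,
# submitted_at); canonicalization collapses resubmissions so downstream code
# sees exactly one report per patient-day.

#' Build a patient profile table
#'
#' @param patient_id character vector of patient keys.
#' @param reporting_start,reporting_end first and last day (inclusive) the
#'   patient was meant to report.
#' @param chemo_start optional date the adjuvant-chemotherapy phase begins
#'   (`NA` for patients who never start chemotherapy). The phase switches
#'   *on* this date.
#' @param stop_reason optional reason reporting ended early: one of
#'   `own_choice`, `transferred`, `death`, `completed` or `NA`.
#' @return a `data.table` with one row per patient.
#' @export
patient_profiles <- function(patient_id, reporting_start, reporting_end,
                             chemo_start = NA, stop_reason = NA_character_) {
  p <- data.table::data.table(
    patient_id = as.character(patient_id),
    reporting_start = as.Date(reporting_start),
    reporting_end = as.Date(reporting_end),
    chemo_start = as.Date(chemo_start),
    stop_reason = as.character(stop_reason)
  )
  if (anyDuplicated(p$patient_id))
    stop("duplicate patient_id in profiles", call. = FALSE)
  if (any(p$reporting_start > p$reporting_end))
    stop("reporting_start must be <= reporting_end", call. = FALSE)
  bad_reason <- !is.na(p$stop_reason) &
    !p$stop_reason %in% c("own_choice", "transferred", "death", "completed")
  if (any(bad_reason))
    stop("unknown stop_reason: ",
         paste(unique(p$stop_reason[bad_reason]), collapse = ", "),
         call. = FALSE)
  cs <- p$chemo_start
  if (any(!is.na(cs) & (cs < p$reporting_start | cs > p$reporting_end)))
    stop("chemo_start must lie within the reporting window", call. = FALSE)
  p
}

#' Assign the care phase of a report date
#'
#' A date belongs to the chemotherapy phase iff the patient has a
#' `chemo_start` and the date is on or after it; otherwise it is
#' post-surgery. Vectorized over `report_date`.
#'
#' @param profile a one-row profile (from [patient_profiles()]).
#' @param report_date Date vector within the patient's reporting window.
#' @return character vector of phases.
#' @export
assign_phase <- function(profile, report_date) {
  report_date <- as.Date(report_date)
  if (any(report_date < profile$reporting_start |
          report_date > profile$reporting_end))
    stop("report_date outside the reporting window of patient ",
         profile$patient_id, call. = FALSE)
  cs <- profile$chemo_start
  if (is.na(cs)) rep("post_surgery", length(report_date))
  else ifelse(report_date >= cs, "chemotherapy", "post_surgery")
}

# empty long-format report table with canonical column types
empty_reports <- function() {
  data.table::data.table(
    patient_id = character(), report_date = as.Date(character()),
    submitted_at = as.POSIXct(character(), tz = "UTC"),
    symptom_id = character(), occurrence = logical(),
    frequency = integer(), distress = integer(), free_text = character()
  )
}

normalize_reports <- function(reports) {
  r <- data.table::as.data.table(reports)
  need <- c("patient_id", "report_date", "submitted_at", "symptom_id",
            "occurrence")
  missing_cols <- setdiff(need, names(r))
  if (length(missing_cols))
    stop("reports are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  r[, patient_id := as.character(patient_id)]
  r[, report_date := as.Date(report_date)]
  r[, submitted_at := as_time_utc(submitted_at)]
  r[, symptom_id := as.character(symptom_id)]
  r[, occurrence := as.logical(occurrence)]
  if (!"frequency" %in% names(r)) r[, frequency := NA_integer_]
  if (!"distress" %in% names(r)) r[, distress := NA_integer_]
  if (!"free_text" %in% names(r)) r[, free_text := NA_character_]
  r[, frequency := as.integer(frequency)]
  r[, distress := as.integer(distress)]
  r[, free_text := as.character(free_text)]
  r[!is.na(free_text) & free_text == "", free_text := NA_character_]
  r[]
}

#' Canonicalize raw report submissions
#'
#' Collapses multiple submissions on the same patient-day (the latest
#' `submitted_at` wins — a later submission supersedes the earlier picture
#' of "how I feel today") and drops rows outside the patient's reporting
#' window, recording them in a `rejected` attribute and a warning. Output
#' is sorted by (patient, date, symptom) so the result is independent of
#' input order.
#'
#' @param raw_reports long-format report table (see [read_reports()]).
#' @param profiles patient profile table; used to window-check rows.
#' @return canonical `data.table`, one submission per patient-day, with
#'   attribute `rejected` holding the excluded rows (possibly empty).
#' @export
canonicalize <- function(raw_reports, profiles = NULL) {
  r <- normalize_reports(raw_reports)
  rejected <- r[0]
  if (!is.null(profiles) && nrow(r)) {
    p <- data.table::as.data.table(profiles)
    r <- merge(r, p[, .(patient_id, reporting_start, reporting_end)],
               by = "patient_id", all.x = TRUE, sort = FALSE)
    bad <- is.na(r$reporting_start) | r$report_date < r$reporting_start |
      r$report_date > r$reporting_end
    if (any(bad)) {
      rejected <- r[bad, !c("reporting_start", "reporting_end")]
      warning(sprintf("%d report row(s) outside the reporting window dropped (%s)",
                      sum(bad),
                      paste(unique(rejected$patient_id), collapse = ", ")),
              call. = FALSE)
      r <- r[!bad]
    }
    r[, c("reporting_start", "reporting_end") := NULL]
  }
  if (nrow(r)) {
    # latest submission per patient-day wins
    r[, .keep_at := max(submitted_at), by = .(patient_id, report_date)]
    r <- r[submitted_at == .keep_at][, .keep_at := NULL]
    # an exact timestamp tie has no temporal winner; break it by content
    # ordering so canonicalization stays independent of input order
    data.table::setorderv(r, c("patient_id", "report_date", "symptom_id",
                               "occurrence", "frequency", "distress",
                               "free_text"), na.last = FALSE)
    r <- unique(r, by = c("patient_id", "report_date", "symptom_id"),
                fromLast = TRUE)
    data.table::setorder(r, patient_id, report_date, symptom_id)
  }
  data.table::setattr(r, "rejected", rejected)
  r[]
}

#' Validate canonical reports against a ruleset
#'
#' Checks the completeness and coding invariants a canonical report stream
#' must satisfy: known symptoms, every phase-assessed symptom answered
#' exactly once per report, follow-up codes only when the symptom occurred
#' and the dimension is assessed, and codes on the scale.
#'
#' @param reports canonical report table.
#' @param profiles patient profile table.
#' @param rs a [ruleset].
#' @return invisibly, a character vector of problems (empty if valid);
#'   errors if any problem is found and `stop_on_error` is TRUE.
#' @param stop_on_error raise an error on the first problem set found.
#' @export
validate_reports <- function(reports, profiles, rs, stop_on_error = TRUE) {
  r <- normalize_reports(reports)
  p <- data.table::as.data.table(profiles)
  problems <- character()
  unknown <- setdiff(unique(r$symptom_id), names(rs$catalog))
  if (length(unknown))
    problems <- c(problems, paste("unknown symptom_id:",
                                  paste(unknown, collapse = ", ")))
  orphans <- setdiff(unique(r$patient_id), p$patient_id)
  if (length(orphans))
    problems <- c(problems, paste("reports for unknown patient:",
                                  paste(orphans, collapse = ", ")))
  known <- r[patient_id %in% p$patient_id & symptom_id %in% names(rs$catalog)]
  if (nrow(known)) {
    known <- merge(known, p[, .(patient_id, chemo_start)], by = "patient_id",
                   sort = FALSE)
    known[, phase := ifelse(!is.na(chemo_start) & report_date >= chemo_start,
                            "chemotherapy", "post_surgery")]
    for (ph in unique(known$phase)) {
      expected <- sort(phase_symptoms(rs, ph))
      bad <- known[phase == ph,
                   .(ok = identical(sort(symptom_id), expected)),
                   by = .(patient_id, report_date)][!(ok)]
      if (nrow(bad))
        problems <- c(problems, sprintf(
          "%d report(s) in phase %s with incomplete or extra symptom answers (e.g. %s on %s)",
          nrow(bad), ph, bad$patient_id[1], bad$report_date[1]))
    }
    for (dim in c("frequency", "distress")) {
      v <- known[[dim]]
      assessed <- vapply(rs$catalog[known$symptom_id],
                         function(s) dim %in% s$dimensions, TRUE)
      if (any(!is.na(v) & !known$occurrence))
        problems <- c(problems,
                      sprintf("%s coded on non-occurring symptom rows", dim))
      if (any(!is.na(v) & !assessed))
        problems <- c(problems,
                      sprintf("%s coded for symptoms where it is not assessed", dim))
      codes <- rs$scales[[dim]]$codes
      if (any(!is.na(v) & !v %in% codes))
        problems <- c(problems, sprintf("%s codes outside the scale", dim))
      if (any(is.na(v) & known$occurrence & assessed))
        problems <- c(problems, sprintf(
          "missing %s code on occurring symptoms where it is assessed", dim))
    }
  }
  if (length(problems) && stop_on_error)
    stop("invalid reports:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  invisible(problems)
}
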