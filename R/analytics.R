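# Adherence and descriptive cohort summaries: the shapes a monitoring study
# reports — per-patient reporting adherence, per-symptom occurrence /
# frequency / distress tables, per-symptom alert distributions, and
# advice-view tallies.

#' Rounded percentage
#'
#' `100 * numerator / denominator`, rounded **half-up** at `decimals`
#' decimal places (the convention used when printing clinical percentages).
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @param decimals non-negative integer decimal places (default 1).
#' @return numeric percentage on the 0-100 scale.
#' @examples
#' pct(182, 512, 1)   # 35.5
#' pct(512, 6320, 0)  # 8
#' @export
pct <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  if (any(decimals < 0)) stop("decimals must be >= 0", call. = FALSE)
  round_half_up(100 * numerator / denominator, decimals)
}

#' Reporting adherence for one patient
#'
#' Adherence is the number of days with a submitted report divided by the
#' number of days the patient was meant to report (every day of the closed
#' reporting window), as a percentage.
#'
#' @param profile one-row patient profile.
#' @param reports canonical reports (other patients' rows are ignored).
#' @param decimals decimal places for the percentage (default 1).
#' @return one-row `data.table`: `patient_id`, `days_reported`,
#'   `days_expected`, `adherence_pct`.
#' @export
adherence <- function(profile, reports, decimals = 1L) {
  days_expected <- as.integer(profile$reporting_end - profile$reporting_start) + 1L
  if (days_expected < 1L) stop("zero-length reporting window", call. = FALSE)
  r <- normalize_reports(reports)
  dates <- unique(r[patient_id == profile$patient_id, report_date])
  dates <- dates[dates >= profile$reporting_start & dates <= profile$reporting_end]
  days_reported <- length(dates)
  data.table::data.table(
    patient_id = profile$patient_id,
    days_reported = days_reported,
    days_expected = days_expected,
    adherence_pct = pct(days_reported, days_expected, decimals))
}

#' Reporting adherence for a cohort
#'
#' @param profiles patient profile table.
#' @param reports canonical reports.
#' @param decimals decimal places for the percentages.
#' @return `data.table`, one row per patient (see [adherence()]).
#' @export
cohort_adherence <- function(profiles, reports, decimals = 1L) {
  p <- data.table::as.data.table(profiles)
  data.table::rbindlist(lapply(seq_len(nrow(p)), function(i)
    adherence(p[i], reports, decimals)))
}

#' Per-symptom occurrence / frequency / distress summary
#'
#' One row per cataloged symptom: how many patients ever reported it, the
#' number of patient-days it occurred, that count as a percentage of all
#' symptom occurrences, the per-patient occurrence-count median and range,
#' and mean (SD) and range of the frequency and distress codes over
#' occurrence-positive responses. Rows sort by occurrence count, descending.
#'
#' @param reports canonical reports.
#' @param rs a [ruleset] (provides the catalog and assessed dimensions).
#' @param mode `"pooled"` (default): mean/SD over all responses pooled
#'   across patients; `"per_patient"`: mean of per-patient means, SD across
#'   per-patient means. Both are defensible readings of a cohort table; the
#'   choice is reported, not hidden.
#' @return `data.table` with attribute `total_occurrences`.
#' @export
symptom_summary <- function(reports, rs, mode = c("pooled", "per_patient")) {
  mode <- match.arg(mode)
  r <- normalize_reports(reports)
  occ <- r[occurrence == TRUE]
  total <- nrow(occ)

  stat_block <- function(v, by_patient) {
    v_ok <- !is.na(v)
    if (!any(v_ok)) return(list(mean = NA_real_, sd = NA_real_,
                                min = NA_integer_, max = NA_integer_))
    if (mode == "pooled") {
      m <- mean(v[v_ok]); s <- stats::sd(v[v_ok])
    } else {
      pm <- tapply(v[v_ok], by_patient[v_ok], mean)
      m <- mean(pm); s <- stats::sd(pm)
    }
    list(mean = m, sd = if (is.na(s)) 0 else s,
         min = min(v[v_ok]), max = max(v[v_ok]))
  }

  rows <- lapply(rs$catalog, function(sdef) {
    s <- sdef$symptom_id
    o <- occ[symptom_id == s]
    per_pat <- if (nrow(o)) o[, .N, by = patient_id]$N else integer()
    fq <- stat_block(o$frequency, o$patient_id)
    ds <- stat_block(o$distress, o$patient_id)
    data.table::data.table(
      symptom_id = s,
      n_patients_reporting = data.table::uniqueN(o$patient_id),
      occurrence_count = nrow(o),
      occurrence_pct = if (total > 0) pct(nrow(o), total, 2L) else NA_real_,
      per_patient_median = if (length(per_pat)) stats::median(per_pat) else NA_real_,
      per_patient_min = if (length(per_pat)) min(per_pat) else NA_integer_,
      per_patient_max = if (length(per_pat)) max(per_pat) else NA_integer_,
      frequency_mean = fq$mean, frequency_sd = fq$sd,
      frequency_min = fq$min, frequency_max = fq$max,
      distress_mean = ds$mean, distress_sd = ds$sd,
      distress_min = ds$min, distress_max = ds$max)
  })
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, -occurrence_count, symptom_id)
  data.table::setattr(out, "total_occurrences", total)
  out[]
}

#' Per-symptom alert summary
#'
#' One row per alerting symptom: patients generating the alert, per-patient
#' alert-count median and range, and red/yellow totals. Grand totals are
#' attached as attributes `total_red` and `total_yellow`.
#'
#' @param alerts alert ledger.
#' @return `data.table`, sorted by total alerts descending.
#' @export
alert_summary <- function(alerts) {
  a <- data.table::as.data.table(alerts)
  if (!nrow(a)) {
    out <- data.table::data.table(
      symptom_id = character(), n_patients_alerting = integer(),
      per_patient_median = numeric(), per_patient_min = integer(),
      per_patient_max = integer(), red_count = integer(),
      yellow_count = integer())
    data.table::setattr(out, "total_red", 0L)
    data.table::setattr(out, "total_yellow", 0L)
    return(out)
  }
  per_pat <- a[, .N, by = .(symptom_id, patient_id)]
  out <- per_pat[, .(n_patients_alerting = .N,
                     per_patient_median = as.numeric(stats::median(N)),
                     per_patient_min = min(N),
                     per_patient_max = max(N)),
                 by = symptom_id]
  sev <- a[, .(red_count = sum(severity == "red"),
               yellow_count = sum(severity == "yellow")),
           by = symptom_id]
  out <- merge(out, sev, by = "symptom_id")
  data.table::setorder(out, -red_count, -yellow_count, symptom_id)
  out[, total := red_count + yellow_count]
  data.table::setorder(out, -total, symptom_id)
  out[, total := NULL]
  data.table::setattr(out, "total_red", sum(sev$red_count))
  data.table::setattr(out, "total_yellow", sum(sev$yellow_count))
  out[]
}

#' Advice-view summary
#'
#' @param views advice-view event log: `patient_id`, `advice_id`,
#'   `viewed_at`.
#' @param top,bottom optional: keep only the `top` most-viewed and/or
#'   `bottom` least-viewed advice items.
#' @return `data.table`: `advice_id`, `n_patients_viewing`, `view_count`,
#'   sorted by views descending.
#' @export
advice_summary <- function(views, top = NULL, bottom = NULL) {
  v <- data.table::as.data.table(views)
  if (!nrow(v))
    return(data.table::data.table(advice_id = character(),
                                  n_patients_viewing = integer(),
                                  view_count = integer()))
  out <- v[, .(n_patients_viewing = data.table::uniqueN(patient_id),
               view_count = .N), by = advice_id]
  data.table::setorder(out, -view_count, advice_id)
  if (!is.null(top) || !is.null(bottom)) {
    keep <- unique(c(utils::head(seq_len(nrow(out)), top %||% 0L),
                     utils::tail(seq_len(nrow(out)), bottom %||% 0L)))
    out <- out[sort(keep)]
  }
  out[]
}
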