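# End-to-end pipeline: read inputs, canonicalize, evaluate, schedule,
# summarize, and write an auditable set of output tables plus a manifest.

#' Run the full monitoring pipeline
#'
#' Reads a ruleset (or uses the built-in one), patient profiles and raw
#' reports; canonicalizes the reports; runs the alert engine per patient;
#' schedules clinic contacts; computes adherence, symptom, alert and advice
#' summaries; and writes everything to `out_dir` together with a
#' `manifest.json` recording inputs, policy switches and output checksums.
#' On failure, partially written outputs are removed.
#'
#' @param reports_path long-format report CSV (or JSON-lines if the file
#'   ends in `.jsonl`).
#' @param profiles_path patient profile CSV.
#' @param out_dir output directory (created if needed).
#' @param ruleset_path optional YAML ruleset; default the built-in
#'   pancreatic ruleset.
#' @param calendar_path optional YAML work calendar; default standard hours.
#' @param advice_views_path optional advice-view CSV.
#' @param options an [engine_options()] object.
#' @param decimals decimal places for percentages in summaries.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(reports_path, profiles_path, out_dir,
                         ruleset_path = NULL, calendar_path = NULL,
                         advice_views_path = NULL,
                         options = engine_options(), decimals = 1L) {
  rs <- if (is.null(ruleset_path)) builtin_pancreas_ruleset()
        else load_ruleset(ruleset_path, is_path = TRUE)
  cal <- if (is.null(calendar_path)) work_calendar()
         else read_work_calendar(calendar_path)
  profiles <- read_profiles(profiles_path)
  raw <- if (grepl("\\.jsonl$", reports_path)) read_reports_jsonl(reports_path)
         else read_reports(reports_path)
  views <- if (is.null(advice_views_path)) NULL
           else read_advice_views(advice_views_path)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    data.table::fwrite(obj, p, dateTimeAs = "write.csv")
    written <<- c(written, p)
    p
  }

  reports <- canonicalize(raw, profiles)
  alerts <- run_cohort(profiles, reports, rs, options)
  contacts <- schedule_contacts(alerts, cal)
  adher <- cohort_adherence(profiles, reports, decimals)
  sym <- symptom_summary(reports, rs)
  alrt <- alert_summary(alerts)

  emit(alerts, "alerts.csv")
  emit(contacts, "contacts.csv")
  emit(adher, "adherence.csv")
  emit(sym, "symptom_summary.csv")
  emit(alrt, "alert_summary.csv")
  adv <- NULL
  if (!is.null(views)) {
    adv <- advice_summary(views)
    emit(adv, "advice_summary.csv")
  }

  manifest <- list(
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    package_version = as.character(utils::packageVersion("sentinel")),
    ruleset = rs$name,
    inputs = list(reports = reports_path, profiles = profiles_path,
                  ruleset = ruleset_path, calendar = calendar_path,
                  advice_views = advice_views_path),
    policy = list(retrigger = options$retrigger,
                  red_supersedes_yellow = options$red_supersedes_yellow,
                  decimals = decimals),
    totals = list(n_patients = nrow(profiles),
                  n_reports = length(unique(paste(reports$patient_id,
                                                  reports$report_date))),
                  n_alerts = nrow(alerts),
                  n_red = sum(alerts$severity == "red"),
                  n_yellow = sum(alerts$severity == "yellow")),
    outputs = lapply(stats::setNames(written, basename(written)),
                     function(p) list(md5 = unname(tools::md5sum(p))))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  written <- c(written, mp)
  ok <- TRUE
  invisible(list(ruleset = rs, reports = reports, alerts = alerts,
                 contacts = contacts, adherence = adher,
                 symptom_summary = sym, alert_summary = alrt,
                 advice_summary = adv, manifest = manifest))
}

#' Simulate a cohort and write its artifact files
#'
#' Convenience wrapper around [generate_cohort()] that writes
#' `profiles.csv`, `reports.csv`, `advice_views.csv` and `truth_log.csv` in
#' the same formats the pipeline consumes.
#'
#' @param out_dir output directory.
#' @param params a [cohort_params()].
#' @param rs a [ruleset].
#' @return invisibly, the generated cohort list.
#' @export
simulate_to_dir <- function(out_dir, params = cohort_params(),
                            rs = builtin_pancreas_ruleset()) {
  co <- generate_cohort(params, rs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_profiles(co$profiles, file.path(out_dir, "profiles.csv"))
  write_reports(co$reports, file.path(out_dir, "reports.csv"))
  write_advice_views(co$advice_views, file.path(out_dir, "advice_views.csv"))
  data.table::fwrite(co$truth_log, file.path(out_dir, "truth_log.csv"))
  invisible(co)
}
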