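# Seeded synthetic-cohort simulator.
#
# Stands in for unpublished clinical report streams. Each symptom follows a
# two-state (absent/present) Markov chain per patient-day — the simplest
# process that produces the multi-day occurrence streaks consecutive-day
# rules need — with ordinal severity resampled on each occurring day.
# Reports are missed iid, a fraction of patients switches to the
# chemotherapy phase at an individual date, and a truth log records every
# (patient, rule, day) qualification for independent oracle checks.

default_symptom_dynamics <- function() {
  # onset = P(absent -> present) per day; persist = P(present -> present).
  # Ordered roughly by how commonly each symptom is seen after pancreatic
  # surgery: fatigue/pain dominate, fever/vomiting are rare but alert-heavy.
  data.table::data.table(
    symptom_id = c("fatigue", "pain", "activities_outside", "nausea",
                   "eating_difficulties", "loose_stool", "activities_home",
                   "sadness", "dizziness", "constipation", "fever",
                   "vomiting", "numbness", "svp_picc",
                   "breathing_difficulties"),
    p_onset = c(0.15, 0.10, 0.08, 0.07, 0.06, 0.07, 0.06,
                0.04, 0.04, 0.03, 0.01, 0.01, 0.04, 0.02, 0.02),
    p_persist = c(0.85, 0.80, 0.80, 0.75, 0.80, 0.70, 0.80,
                  0.85, 0.70, 0.50, 0.30, 0.40, 0.85, 0.60, 0.60)
  )
}

#' Parameters of the synthetic cohort
#'
#' Defaults emulate a 6-month post-pancreaticoduodenectomy monitoring
#' cohort: 26 patients, follow-up right-skewed towards completing the
#' programme within a 35-245-day envelope, a mean daily missed-report
#' probability of ~0.18 (per-patient, Beta-distributed, giving cohort
#' adherence spanning roughly 25-100%), and ~85% of patients starting
#' adjuvant chemotherapy 3-8 weeks into reporting.
#'
#' @param n_patients number of patients.
#' @param followup_days_range inclusive (min, max) follow-up length in days.
#' @param followup_shape Beta(a, b) shape for where follow-up lengths fall
#'   inside the range (right-skewed by default).
#' @param p_miss_shape Beta(a, b) for per-patient daily missed-report
#'   probability.
#' @param chemo_fraction probability a patient starts chemotherapy.
#' @param chemo_start_day_range (min, max) reporting day on which the
#'   chemotherapy phase starts.
#' @param dynamics per-symptom Markov table (`symptom_id`, `p_onset`,
#'   `p_persist`); see `default_symptom_dynamics`.
#' @param severity_dist probabilities over ordinal codes 1..4 used for both
#'   frequency and distress on occurring days.
#' @param p_view_on_qualifying probability an advice item is viewed on a day
#'   the symptom qualified for a rule.
#' @param baseline_view_rate expected baseline advice views per patient-day.
#' @param p_free_text probability a report carries a free-text comment.
#' @param cohort_start first possible reporting start date.
#' @param seed integer master seed; every draw derives from it.
#' @return validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 26L,
                          followup_days_range = c(35L, 245L),
                          followup_shape = c(2.6, 1.2),
                          p_miss_shape = c(1.6, 7.3),
                          chemo_fraction = 0.85,
                          chemo_start_day_range = c(21L, 56L),
                          dynamics = default_symptom_dynamics(),
                          severity_dist = c(0.30, 0.40, 0.20, 0.10),
                          p_view_on_qualifying = 0.6,
                          baseline_view_rate = 0.12,
                          p_free_text = 0.05,
                          cohort_start = as.Date("2015-03-01"),
                          seed = 1L) {
  p <- list(n_patients = as.integer(n_patients),
            followup_days_range = as.integer(followup_days_range),
            followup_shape = as.numeric(followup_shape),
            p_miss_shape = as.numeric(p_miss_shape),
            chemo_fraction = as.numeric(chemo_fraction),
            chemo_start_day_range = as.integer(chemo_start_day_range),
            dynamics = data.table::as.data.table(dynamics),
            severity_dist = as.numeric(severity_dist),
            p_view_on_qualifying = as.numeric(p_view_on_qualifying),
            baseline_view_rate = as.numeric(baseline_view_rate),
            p_free_text = as.numeric(p_free_text),
            cohort_start = as.Date(cohort_start),
            seed = as.integer(seed))
  if (p$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  for (rg in list(p$followup_days_range, p$chemo_start_day_range))
    if (length(rg) != 2 || rg[1] > rg[2] || rg[1] < 1)
      stop("ranges must be ordered pairs of positive days", call. = FALSE)
  probs <- c(p$chemo_fraction, p$p_view_on_qualifying, p$p_free_text,
             p$severity_dist, p$dynamics$p_onset, p$dynamics$p_persist)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must be in [0, 1]", call. = FALSE)
  if (abs(sum(p$severity_dist) - 1) > 1e-8 || length(p$severity_dist) != 4)
    stop("severity_dist must be 4 probabilities summing to 1", call. = FALSE)
  if (p$baseline_view_rate < 0) stop("baseline_view_rate must be >= 0",
                                     call. = FALSE)
  structure(p, class = "cohort_params")
}

# generator-side qualification test: label-set membership computed directly
# from the rule's label list, independently of the engine's code path
.qualifies_raw <- function(rule, scales, occurrence, frequency, distress) {
  if (rule$dimension == "occurrence")
    return(scales$occurrence$labels[occurrence + 1L] %in% rule$responses)
  if (!occurrence) return(FALSE)
  code <- if (rule$dimension == "frequency") frequency else distress
  if (is.na(code)) return(FALSE)
  scales[[rule$dimension]]$labels[code] %in% rule$responses
}

#' Generate a synthetic monitoring cohort
#'
#' Deterministic given `params$seed`: every patient draws from an
#' independent substream derived from the master seed, so enlarging the
#' cohort leaves existing patients' trajectories untouched.
#'
#' @param params a [cohort_params()] object.
#' @param rs the [ruleset] the cohort reports under (default the built-in
#'   pancreatic ruleset).
#' @return list with `profiles`, `reports` (canonical long format),
#'   `advice_views`, `truth_log` (`patient_id`, `rule_id`, `qual_date`) and
#'   the `params` used.
#' @export
generate_cohort <- function(params = cohort_params(),
                            rs = builtin_pancreas_ruleset()) {
  stopifnot(inherits(params, "cohort_params"), inherits(rs, "ruleset"))
  dyn <- params$dynamics
  missing_dyn <- setdiff(names(rs$catalog), dyn$symptom_id)
  if (length(missing_dyn))
    stop("dynamics table lacks symptom(s): ",
         paste(missing_dyn, collapse = ", "), call. = FALSE)

  profiles <- vector("list", params$n_patients)
  reports <- vector("list", params$n_patients)
  views <- vector("list", params$n_patients)
  truth <- vector("list", params$n_patients)

  rules_by_phase <- lapply(stats::setNames(PHASES, PHASES),
                           function(ph) phase_rules(rs, ph))
  syms_by_phase <- lapply(stats::setNames(PHASES, PHASES),
                          function(ph) phase_symptoms(rs, ph))

  for (i in seq_len(params$n_patients)) {
    set.seed(substream_seed(params$seed, i))
    pid <- sprintf("P%03d", i)

    L <- params$followup_days_range[1] +
      floor(stats::rbeta(1, params$followup_shape[1], params$followup_shape[2]) *
              (diff(params$followup_days_range) + 1L))
    L <- min(L, params$followup_days_range[2])
    start <- params$cohort_start + sample.int(365L, 1L) - 1L
    end <- start + L - 1L
    p_miss <- stats::rbeta(1, params$p_miss_shape[1], params$p_miss_shape[2])

    chemo_start <- as.Date(NA)
    if (stats::runif(1) < params$chemo_fraction) {
      rng <- seq.int(params$chemo_start_day_range[1],
                     params$chemo_start_day_range[2])
      cd <- rng[sample.int(length(rng), 1L)]
      if (cd <= L) chemo_start <- start + cd - 1L
    }
    profiles[[i]] <- data.table::data.table(
      patient_id = pid, reporting_start = start, reporting_end = end,
      chemo_start = chemo_start,
      stop_reason = if (L < params$followup_days_range[2] * 0.6)
        "transferred" else "completed")

    # latent symptom states evolve every calendar day; reports observe them
    state <- stats::setNames(rep(FALSE, nrow(dyn)), dyn$symptom_id)
    missed <- stats::runif(L) < p_miss
    day_rows <- list(); day_truth <- list(); day_views <- list()
    for (d in seq_len(L)) {
      date <- start + d - 1L
      p_trans <- ifelse(state, dyn$p_persist, dyn$p_onset)
      state <- stats::setNames(stats::runif(nrow(dyn)) < p_trans,
                               dyn$symptom_id)
      if (missed[d]) next
      phase <- if (!is.na(chemo_start) && date >= chemo_start)
        "chemotherapy" else "post_surgery"
      syms <- syms_by_phase[[phase]]
      occ <- unname(state[syms])
      n <- length(syms)
      freq <- rep(NA_integer_, n); dist <- rep(NA_integer_, n)
      for (k in seq_len(n)) {
        if (!occ[k]) next
        dims <- rs$catalog[[syms[k]]]$dimensions
        if ("frequency" %in% dims)
          freq[k] <- sample.int(4L, 1L, prob = params$severity_dist)
        if ("distress" %in% dims)
          dist[k] <- sample.int(4L, 1L, prob = params$severity_dist)
      }
      submitted <- as.POSIXct(date, tz = "UTC") +
        round(stats::runif(1, 7 * 3600, 22 * 3600))
      ft <- if (stats::runif(1) < params$p_free_text)
        sample(c("Feeling better today.", "You do not need to call me.",
                 "Weight 72.4 kg this morning.",
                 "Worse after yesterday's treatment."), 1L)
      else NA_character_
      # report-level free text rides on the first row in canonical
      # (alphabetical) symptom order, matching the long-format convention
      ft_vec <- rep(NA_character_, n)
      ft_vec[order(syms)[1L]] <- ft %||% NA_character_
      day_rows[[length(day_rows) + 1L]] <- data.table::data.table(
        patient_id = pid, report_date = date, submitted_at = submitted,
        symptom_id = syms, occurrence = occ, frequency = freq,
        distress = dist, free_text = ft_vec)

      # truth log + advice browsing for this day
      for (rule in rules_by_phase[[phase]]) {
        k <- match(rule$symptom_id, syms)
        if (is.na(k)) next
        if (.qualifies_raw(rule, rs$scales, occ[k], freq[k], dist[k])) {
          day_truth[[length(day_truth) + 1L]] <- data.table::data.table(
            patient_id = pid, rule_id = rule$rule_id, qual_date = date)
          if (stats::runif(1) < params$p_view_on_qualifying)
            day_views[[length(day_views) + 1L]] <- data.table::data.table(
              patient_id = pid, advice_id = paste0("adv_", rule$symptom_id),
              viewed_at = submitted + 1800)
        }
      }
      n_base <- stats::rpois(1, params$baseline_view_rate)
      if (n_base > 0) {
        day_views[[length(day_views) + 1L]] <- data.table::data.table(
          patient_id = pid,
          advice_id = paste0("adv_", sample(syms, n_base, replace = TRUE)),
          viewed_at = submitted + 3600)
      }
    }
    reports[[i]] <- data.table::rbindlist(day_rows)
    truth[[i]] <- data.table::rbindlist(day_truth)
    views[[i]] <- data.table::rbindlist(day_views)
  }

  tl <- data.table::rbindlist(truth)
  if (!nrow(tl))
    tl <- data.table::data.table(patient_id = character(),
                                 rule_id = character(),
                                 qual_date = as.Date(character()))
  tl <- unique(tl)  # one symptom can qualify several same-day rules; one row each
  av <- data.table::rbindlist(views)
  if (!nrow(av))
    av <- data.table::data.table(patient_id = character(),
                                 advice_id = character(),
                                 viewed_at = as.POSIXct(character(), tz = "UTC"))
  rep_all <- data.table::rbindlist(reports)
  if (!nrow(rep_all)) rep_all <- empty_reports()
  data.table::setorder(rep_all, patient_id, report_date, symptom_id)
  list(profiles = data.table::rbindlist(profiles),
       reports = rep_all,
       advice_views = av,
       truth_log = tl,
       params = params)
}
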