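# Shared fixtures: tiny rulesets, scripted single-symptom report streams,
# random stream generators, and a from-first-principles window-scan oracle
# used to cross-check the engine (deliberately re-derived here rather than
# calling the package's oracle).

DAY0 <- as.Date("2021-03-01")  # a Monday

# one-symptom catalog + rules used by the exhaustive and property tests:
# red window-1 on code 4, yellow window-2 on codes >= 2, yellow window-3 on
# codes >= 3; same symptom so red-supersedes-yellow is exercised
mini_ruleset <- function() {
  ruleset(
    catalog = list(symptom_definition("s", "Test symptom")),
    rules = list(
      alert_rule("r_red1", "s", "frequency", "Almost always", 1, "red",
                 "post_surgery"),
      alert_rule("r_yel2", "s", "frequency",
                 c("Sometimes", "Often", "Almost always"), 2, "yellow",
                 "post_surgery"),
      alert_rule("r_yel3", "s", "frequency", c("Often", "Almost always"),
                 3, "yellow", "post_surgery")
    ),
    name = "mini")
}

mini_profile <- function(pid = "P1", n_days = 60, start = DAY0) {
  patient_profiles(pid, start, start + n_days - 1)
}

# Build a one-symptom report stream from a code vector:
#   NA -> missed day (no report); 0 -> reported, symptom absent;
#   1..4 -> reported, occurring with that frequency code.
stream_reports <- function(codes, pid = "P1", start = DAY0, symptom = "s") {
  rows <- lapply(seq_along(codes), function(d) {
    v <- codes[d]
    if (is.na(v)) return(NULL)
    data.table::data.table(
      patient_id = pid, report_date = start + d - 1,
      submitted_at = as.POSIXct(start + d - 1, tz = "UTC") + 10 * 3600,
      symptom_id = symptom, occurrence = v > 0,
      frequency = if (v > 0) as.integer(v) else NA_integer_,
      distress = NA_integer_, free_text = NA_character_)
  })
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) out <- sentinel:::empty_reports()
  out
}

# Independent window-scan oracle over a code vector for the mini ruleset.
# For each rule, day d alerts iff codes[d-w+1 .. d] are all in the
# qualifying set (no NA, no gap); yellow alerts on a day with a red alert
# are dropped. Returns data.table(day, rule_id).
brute_alerts <- function(codes, retrigger = "every_day") {
  spec <- list(r_red1 = list(q = 4L, w = 1L, sev = "red"),
               r_yel2 = list(q = 2:4, w = 2L, sev = "yellow"),
               r_yel3 = list(q = 3:4, w = 3L, sev = "yellow"))
  hits <- list()
  for (rid in names(spec)) {
    s <- spec[[rid]]
    for (d in seq_along(codes)) {
      if (d < s$w) next
      win <- codes[(d - s$w + 1):d]
      if (any(is.na(win)) || !all(win %in% s$q)) next
      if (retrigger == "once_per_episode") {
        prev <- if (d > s$w) codes[d - s$w] else NA
        if (!is.na(prev) && prev %in% s$q) next
      }
      hits[[length(hits) + 1]] <- data.table::data.table(
        day = d, rule_id = rid, severity = s$sev)
    }
  }
  out <- data.table::rbindlist(hits)
  if (!nrow(out))
    return(data.table::data.table(day = integer(), rule_id = character(),
                                  severity = character()))
  red_days <- out[severity == "red", unique(day)]
  out <- out[!(severity == "yellow" & day %in% red_days)]
  out[order(day, rule_id), .(day, rule_id)]
}

engine_alert_days <- function(codes, options = engine_options()) {
  pr <- mini_profile(n_days = length(codes) + 1)
  al <- run_timeline(pr[1], stream_reports(codes), mini_ruleset(), options)
  if (!nrow(al))
    return(data.table::data.table(day = integer(), rule_id = character()))
  al[, .(day = as.integer(trigger_date - DAY0) + 1L, rule_id)][
    order(day, rule_id)]
}

# random valid ruleset for serialization round-trip property tests
random_ruleset <- function() {
  n_sym <- sample(1:5, 1)
  syms <- paste0("sym", seq_len(n_sym))
  catalog <- lapply(syms, function(s)
    symptom_definition(
      s, paste("Symptom", s),
      dimensions = c("occurrence",
                     sample(c("frequency", "distress"),
                            sample(0:2, 1))),
      phases = sample(list("post_surgery", "chemotherapy",
                           c("post_surgery", "chemotherapy")), 1)[[1]]))
  names(catalog) <- syms
  scales <- default_scales()
  n_rules <- sample(0:6, 1)
  rules <- list()
  k <- 0
  while (length(rules) < n_rules && k < 50) {
    k <- k + 1
    sdef <- catalog[[sample(syms, 1)]]
    dim <- sample(sdef$dimensions, 1)
    phase <- sample(sdef$phases, 1)
    labels <- scales[[dim]]$labels
    resp <- sample(labels, sample(seq_along(labels), 1))
    rules[[length(rules) + 1]] <- alert_rule(
      paste0("r", length(rules) + 1), sdef$symptom_id, dim, resp,
      sample(c(1, 2, 3, 7), 1), sample(c("red", "yellow"), 1), phase)
  }
  ruleset(catalog, rules, scales, name = paste0("rand", sample(1e6, 1)))
}

expect_same_alerts <- function(engine, oracle) {
  cols <- c("patient_id", "rule_id", "trigger_date", "severity",
            "streak_length")
  e <- data.table::setorderv(engine[, ..cols], cols)
  o <- data.table::setorderv(oracle[, ..cols], cols)
  expect_equal(as.data.frame(e), as.data.frame(o),
               ignore_attr = TRUE)
}
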