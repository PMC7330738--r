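# Ruleset: symptom catalog, ordinal rating scales, and alert rules.
#
# A ruleset is the machine-readable form of a clinical risk-assessment table:
# each rule maps (symptom, rated dimension, qualifying response labels,
# consecutive-day window, care phase) to an alert severity. Responses are
# compared by ordinal code via the scale's label->code map, never by string
# inequality, because rules name *sets* of qualifying labels.

#' Construct a rating scale
#'
#' A rated dimension with ordered response labels and strictly increasing
#' integer codes. Occurrence is binary (codes 0/1); frequency and distress
#' are 4-point ordinal scales coded 1..4 in ascending severity.
#'
#' @param dimension one of `"occurrence"`, `"frequency"`, `"distress"`.
#' @param labels character vector of response labels, ascending severity.
#' @param codes integer codes parallel to `labels`.
#' @return an object of class `rating_scale`.
#' @examples
#' rating_scale("occurrence", c("No", "Yes"), 0:1)
#' @export
rating_scale <- function(dimension, labels, codes) {
  dimension <- match.arg(dimension, DIMENSIONS)
  labels <- as.character(labels)
  codes <- as.integer(codes)
  if (length(labels) != length(codes))
    stop("labels and codes must have the same length", call. = FALSE)
  if (any(diff(codes) <= 0))
    stop("codes must be strictly increasing", call. = FALSE)
  n_req <- if (dimension == "occurrence") 2L else 4L
  if (length(labels) != n_req)
    stop(sprintf("%s scale must have exactly %d labels", dimension, n_req),
         call. = FALSE)
  if (anyDuplicated(labels))
    stop("scale labels must be unique", call. = FALSE)
  structure(list(dimension = dimension, labels = labels, codes = codes),
            class = "rating_scale")
}

#' Default rating scales
#'
#' Occurrence is No/Yes. The two top frequency labels ("Often",
#' "Almost always") and distress labels ("Rather much", "Very much") are
#' fixed by the built-in rule table; the lower two of each scale are
#' conventional defaults and may be overridden in a config file.
#'
#' @return named list of [rating_scale] objects keyed by dimension.
#' @export
default_scales <- function() {
  list(
    occurrence = rating_scale("occurrence", c("No", "Yes"), c(0L, 1L)),
    frequency  = rating_scale("frequency",
                              c("Seldom", "Sometimes", "Often", "Almost always"),
                              1:4),
    distress   = rating_scale("distress",
                              c("A little", "Somewhat", "Rather much", "Very much"),
                              1:4)
  )
}

scale_label <- function(scale, code) scale$labels[match(code, scale$codes)]
scale_code  <- function(scale, label) scale$codes[match(label, scale$labels)]

#' Construct a symptom definition
#'
#' @param symptom_id short stable key (snake_case).
#' @param display_name human-readable name.
#' @param dimensions dimensions assessed for this symptom; must include
#'   `"occurrence"` (the gate question — frequency/distress are only asked
#'   when a symptom occurred).
#' @param phases care phases in which the symptom is assessed.
#' @return a plain list with class `symptom_definition`.
#' @export
symptom_definition <- function(symptom_id, display_name = symptom_id,
                               dimensions = c("occurrence", "frequency", "distress"),
                               phases = PHASES) {
  dimensions <- match.arg(dimensions, DIMENSIONS, several.ok = TRUE)
  phases <- match.arg(phases, PHASES, several.ok = TRUE)
  if (!"occurrence" %in% dimensions)
    stop("occurrence is always assessed", call. = FALSE)
  structure(list(symptom_id = as.character(symptom_id),
                 display_name = as.character(display_name),
                 dimensions = dimensions, phases = phases),
            class = "symptom_definition")
}

#' Construct an alert rule
#'
#' @param rule_id unique key.
#' @param symptom_id key into the symptom catalog.
#' @param dimension the rated dimension the rule tests.
#' @param responses character set of qualifying response labels.
#' @param window_days number of consecutive calendar days the qualifying
#'   response must hold before the alert fires (1 = a single report).
#' @param severity `"red"` (contact within 1 hour) or `"yellow"` (contact
#'   the same working day).
#' @param phase care phase the rule belongs to.
#' @return a plain list with class `alert_rule`.
#' @export
alert_rule <- function(rule_id, symptom_id, dimension, responses,
                       window_days, severity, phase) {
  dimension <- match.arg(dimension, DIMENSIONS)
  severity <- match.arg(severity, SEVERITIES)
  phase <- match.arg(phase, PHASES)
  window_days <- as.integer(window_days)
  if (is.na(window_days) || window_days < 1L)
    stop("window_days must be a positive integer", call. = FALSE)
  responses <- as.character(responses)
  if (length(responses) == 0)
    stop("qualifying responses must be non-empty", call. = FALSE)
  structure(list(rule_id = as.character(rule_id),
                 symptom_id = as.character(symptom_id),
                 dimension = dimension,
                 responses = responses,
                 window_days = window_days,
                 severity = severity, phase = phase),
            class = "alert_rule")
}

#' Assemble and validate a ruleset
#'
#' Cross-checks every rule against the catalog and scales: referenced
#' symptoms must exist and be assessed in the rule's phase and dimension,
#' and every qualifying label must be on the dimension's scale.
#'
#' @param catalog list of [symptom_definition] objects.
#' @param rules list of [alert_rule] objects.
#' @param scales named list of [rating_scale] objects (default
#'   [default_scales()]).
#' @param name optional ruleset name recorded in serializations.
#' @return an object of class `ruleset`.
#' @export
ruleset <- function(catalog, rules, scales = default_scales(),
                    name = "custom") {
  stopifnot(is.list(catalog), is.list(rules), is.list(scales))
  for (d in DIMENSIONS) {
    if (is.null(scales[[d]]) || !inherits(scales[[d]], "rating_scale"))
      stop(sprintf("missing rating scale for dimension '%s'", d),
           call. = FALSE)
  }
  ids <- vapply(catalog, `[[`, "", "symptom_id")
  if (anyDuplicated(ids))
    stop("duplicate symptom_id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(catalog) <- ids
  rids <- vapply(rules, `[[`, "", "rule_id")
  if (anyDuplicated(rids))
    stop("duplicate rule_id: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "), call. = FALSE)
  names(rules) <- rids
  for (r in rules) {
    sym <- catalog[[r$symptom_id]]
    if (is.null(sym))
      stop(sprintf("rule '%s' references unknown symptom '%s'",
                   r$rule_id, r$symptom_id), call. = FALSE)
    if (!r$phase %in% sym$phases)
      stop(sprintf("rule '%s': symptom '%s' is not assessed in phase '%s'",
                   r$rule_id, r$symptom_id, r$phase), call. = FALSE)
    if (!r$dimension %in% sym$dimensions)
      stop(sprintf("rule '%s': dimension '%s' is not assessed for symptom '%s'",
                   r$rule_id, r$dimension, r$symptom_id), call. = FALSE)
    unknown <- setdiff(r$responses, scales[[r$dimension]]$labels)
    if (length(unknown))
      stop(sprintf("rule '%s': label(s) not on the %s scale: %s",
                   r$rule_id, r$dimension, paste(unknown, collapse = ", ")),
           call. = FALSE)
  }
  structure(list(name = as.character(name), catalog = catalog,
                 rules = rules, scales = scales),
            class = "ruleset")
}

#' @export
print.ruleset <- function(x, ...) {
  rt <- rules_table(x)
  cat(sprintf("<ruleset '%s'>: %d symptoms, %d rules\n",
              x$name, length(x$catalog), length(x$rules)))
  if (nrow(rt)) {
    tab <- table(rt$phase, rt$severity)
    print(tab)
  }
  invisible(x)
}

#' Rules of a ruleset as a data.table
#'
#' One row per rule; `responses` is a list column of label sets.
#'
#' @param rs a [ruleset].
#' @return a `data.table` with columns `rule_id`, `symptom_id`, `dimension`,
#'   `responses`, `window_days`, `severity`, `phase`.
#' @export
rules_table <- function(rs) {
  stopifnot(inherits(rs, "ruleset"))
  if (!length(rs$rules)) {
    return(data.table::data.table(
      rule_id = character(), symptom_id = character(), dimension = character(),
      responses = list(), window_days = integer(), severity = character(),
      phase = character()))
  }
  data.table::data.table(
    rule_id = vapply(rs$rules, `[[`, "", "rule_id"),
    symptom_id = vapply(rs$rules, `[[`, "", "symptom_id"),
    dimension = vapply(rs$rules, `[[`, "", "dimension"),
    responses = lapply(rs$rules, `[[`, "responses"),
    window_days = vapply(rs$rules, `[[`, 1L, "window_days"),
    severity = vapply(rs$rules, `[[`, "", "severity"),
    phase = vapply(rs$rules, `[[`, "", "phase")
  )
}

#' Rules applicable in a phase
#' @param rs a [ruleset].
#' @param phase care phase.
#' @return list of [alert_rule] objects.
#' @export
phase_rules <- function(rs, phase) {
  phase <- match.arg(phase, PHASES)
  Filter(function(r) r$phase == phase, rs$rules)
}

#' Symptoms assessed in a phase
#' @param rs a [ruleset].
#' @param phase care phase.
#' @return character vector of symptom ids.
#' @export
phase_symptoms <- function(rs, phase) {
  phase <- match.arg(phase, PHASES)
  ids <- vapply(rs$catalog, `[[`, "", "symptom_id")
  keep <- vapply(rs$catalog, function(s) phase %in% s$phases, TRUE)
  unname(ids[keep])
}

#' Serialize a ruleset to YAML text
#'
#' The serialization is a single self-contained document with top-level keys
#' `name`, `scales`, `symptoms` and `rules` — one auditable clinical rule
#' artifact. [load_ruleset()] inverts it exactly.
#'
#' @param rs a [ruleset].
#' @return a single character string of YAML.
#' @export
serialize_ruleset <- function(rs) {
  stopifnot(inherits(rs, "ruleset"))
  doc <- list(
    name = rs$name,
    scales = lapply(rs$scales, function(s)
      list(labels = as.list(s$labels), codes = as.list(as.integer(s$codes)))),
    symptoms = lapply(unname(rs$catalog), function(s)
      list(id = s$symptom_id, display_name = s$display_name,
           dimensions = as.list(s$dimensions), phases = as.list(s$phases))),
    rules = lapply(unname(rs$rules), function(r)
      list(id = r$rule_id, symptom = r$symptom_id, dimension = r$dimension,
           responses = as.list(r$responses),
           window_days = as.integer(r$window_days),
           severity = r$severity, phase = r$phase))
  )
  yaml::as.yaml(doc)
}

#' Load and validate a ruleset from YAML
#'
#' @param config_text YAML text (single string or lines), or a file path to
#'   a YAML document when `is_path = TRUE`.
#' @param is_path read `config_text` as a file path.
#' @return a validated [ruleset].
#' @export
load_ruleset <- function(config_text, is_path = FALSE) {
  doc <- tryCatch(
    if (is_path) yaml::read_yaml(config_text)
    else yaml::yaml.load(paste(config_text, collapse = "\n")),
    error = function(e) stop("ruleset config failed to parse: ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(doc) || is.null(doc$symptoms))
    stop("ruleset config must define 'symptoms'", call. = FALSE)
  scales <- default_scales()
  for (d in names(doc$scales %||% list())) {
    sc <- doc$scales[[d]]
    scales[[d]] <- rating_scale(d, unlist(sc$labels), unlist(sc$codes))
  }
  catalog <- lapply(doc$symptoms, function(s)
    symptom_definition(s$id, s$display_name %||% s$id,
                       unlist(s$dimensions %||% DIMENSIONS),
                       unlist(s$phases %||% PHASES)))
  rules <- lapply(doc$rules %||% list(), function(r) {
    for (f in c("id", "symptom", "dimension", "responses", "window_days",
                "severity", "phase"))
      if (is.null(r[[f]]))
        stop(sprintf("rule '%s' is missing field '%s'",
                     r$id %||% "<unnamed>", f), call. = FALSE)
    alert_rule(r$id, r$symptom, r$dimension, unlist(r$responses),
               r$window_days, r$severity, r$phase)
  })
  ruleset(catalog, rules, scales, name = doc$name %||% "custom")
}
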