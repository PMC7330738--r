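# Built-in risk-assessment ruleset for patients monitored after
# pancreaticoduodenectomy, with a distinct single-report panel for the
# adjuvant-chemotherapy phase (during chemotherapy the patient already has
# weekly nurse contact, so no multi-day windows are used there).

#' Built-in pancreatic-surgery ruleset
#'
#' Twelve symptoms are assessed after surgery; three more (breathing
#' difficulties, numbness/tingling, SVP/PICC access-site problems) are added
#' during adjuvant chemotherapy. The post-surgery panel holds 15 rules
#' (4 red, 11 yellow; windows of 1, 2, 3 or 7 consecutive days); the
#' chemotherapy panel holds 15 rules (6 red, 9 yellow), all single-report.
#'
#' Fever, constipation and activity limitations have reduced follow-up
#' dimensions (fever and the access site are occurrence-only; constipation
#' and activities-at-home carry distress but not frequency).
#'
#' @return a validated [ruleset].
#' @examples
#' rs <- builtin_pancreas_ruleset()
#' rules_table(rs)[phase == "post_surgery" & severity == "red"]
#' @export
builtin_pancreas_ruleset <- function() {
  sym <- function(...) symptom_definition(...)
  all_dims <- c("occurrence", "frequency", "distress")
  catalog <- list(
    sym("fever", "Fever", dimensions = "occurrence"),
    sym("pain", "Pain", all_dims),
    sym("vomiting", "Vomiting", all_dims),
    sym("dizziness", "Dizziness", all_dims),
    sym("loose_stool", "Loose stool", all_dims),
    sym("constipation", "Constipation", c("occurrence", "distress")),
    sym("eating_difficulties", "Eating difficulties", all_dims),
    sym("nausea", "Nausea", all_dims),
    sym("fatigue", "Fatigue", all_dims),
    sym("sadness", "Sadness/depression/worry", all_dims),
    sym("activities_home", "Problems performing activities at home",
        c("occurrence", "distress")),
    sym("activities_outside", "Problems performing activities outside home",
        all_dims),
    sym("breathing_difficulties", "Breathing difficulties", all_dims,
        phases = "chemotherapy"),
    sym("numbness", "Numbness/tingling in hands and/or feet", all_dims,
        phases = "chemotherapy"),
    sym("svp_picc", "Swelling/pain/redness from SVP/PICC",
        dimensions = "occurrence", phases = "chemotherapy")
  )

  AA <- "Almost always"; OFT <- "Often"; SOM <- "Sometimes"
  RM <- "Rather much"; VM <- "Very much"
  ps <- function(id, symptom, dim, resp, win, sev)
    alert_rule(id, symptom, dim, resp, win, sev, "post_surgery")
  ch <- function(id, symptom, dim, resp, sev)
    alert_rule(id, symptom, dim, resp, 1L, sev, "chemotherapy")

  rules <- list(
    # --- post-surgery panel ---
    ps("ps_fever_red", "fever", "occurrence", "Yes", 1, "red"),
    ps("ps_pain_red", "pain", "frequency", AA, 1, "red"),
    ps("ps_vomiting_red", "vomiting", "frequency", AA, 1, "red"),
    ps("ps_dizziness_red", "dizziness", "frequency", AA, 1, "red"),
    ps("ps_vomiting_yellow", "vomiting", "frequency", c(SOM, OFT, AA), 2, "yellow"),
    ps("ps_dizziness_yellow", "dizziness", "frequency", c(SOM, OFT, AA), 2, "yellow"),
    ps("ps_loose_stool_yellow", "loose_stool", "frequency", c(OFT, AA), 3, "yellow"),
    ps("ps_constipation_yellow", "constipation", "occurrence", "Yes", 3, "yellow"),
    ps("ps_eating_yellow", "eating_difficulties", "frequency", c(OFT, AA), 7, "yellow"),
    ps("ps_pain_yellow", "pain", "frequency", c(OFT, AA), 7, "yellow"),
    ps("ps_nausea_yellow", "nausea", "frequency", c(OFT, AA), 7, "yellow"),
    ps("ps_fatigue_yellow", "fatigue", "distress", c(RM, VM), 7, "yellow"),
    ps("ps_sadness_yellow", "sadness", "distress", c(RM, VM), 7, "yellow"),
    ps("ps_act_home_yellow", "activities_home", "distress", c(RM, VM), 7, "yellow"),
    ps("ps_act_outside_yellow", "activities_outside", "distress", c(RM, VM), 7, "yellow"),
    # --- chemotherapy panel (all single-report) ---
    ch("ch_fever_red", "fever", "occurrence", "Yes", "red"),
    ch("ch_breathing_red", "breathing_difficulties", "frequency", AA, "red"),
    ch("ch_nausea_red", "nausea", "frequency", AA, "red"),
    ch("ch_vomiting_red", "vomiting", "frequency", AA, "red"),
    ch("ch_numbness_red", "numbness", "frequency", AA, "red"),
    ch("ch_eating_red", "eating_difficulties", "frequency", AA, "red"),
    ch("ch_svp_picc_yellow", "svp_picc", "occurrence", "Yes", "yellow"),
    ch("ch_loose_stool_yellow", "loose_stool", "frequency", AA, "yellow"),
    ch("ch_pain_yellow", "pain", "frequency", AA, "yellow"),
    ch("ch_dizziness_yellow", "dizziness", "frequency", c(AA, OFT), "yellow"),
    ch("ch_vomiting_yellow", "vomiting", "frequency", OFT, "yellow"),
    ch("ch_nausea_yellow", "nausea", "frequency", OFT, "yellow"),
    ch("ch_breathing_yellow", "breathing_difficulties", "frequency", OFT, "yellow"),
    ch("ch_constipation_yellow", "constipation", "distress", VM, "yellow"),
    ch("ch_sadness_yellow", "sadness", "distress", VM, "yellow")
  )
  ruleset(catalog, rules, default_scales(), name = "pancreas")
}

#' Default advice catalog for the built-in ruleset
#'
#' Maps each alerting symptom to a self-care advice identifier. Real
#' deployments carry a richer advice library (diet, enzyme supplements,
#' wound care, ...); this minimal map covers what the alert engine needs to
#' suggest advice for a triggered symptom.
#'
#' @return named list: symptom_id -> character vector of advice ids.
#' @export
builtin_advice_map <- function() {
  ids <- vapply(builtin_pancreas_ruleset()$catalog, `[[`, "", "symptom_id")
  out <- lapply(ids, function(s) paste0("adv_", s))
  names(out) <- ids
  out
}
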