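# Decision-support cards and the rule families that emit them.
#
# Each rule family is a pure function from patient context to a list of
# cards: same inputs, identical cards. Families are exposed directly as
# library functions here and behind the CDS Hooks document contract in
# cdshooks.R; the service layer is a thin serialisation of these functions.

CARD_KINDS <- c("risk_score", "diagnosis_suggestion", "lab_order",
                "goal_suggestion", "medication_suggestion",
                "contraindication_warning", "referral_suggestion",
                "follow_up_suggestion", "module_transition_prompt")

#' Decision-support card
#'
#' @param rule_id id of the rule that produced the card
#' @param kind one of the nine platform card kinds
#' @param payload named list of structured content; `concept` holds the coded
#'   payload (ICD-10 / parameter / specialty) where the kind implies one
#' @param rationale non-empty human-readable justification
#' @param accepted tri-state review status
#' @export
cds_card <- function(rule_id, kind, payload = list(), rationale,
                     accepted = c("pending", "accepted", "rejected")) {
  kind <- match.arg(kind, CARD_KINDS)
  accepted <- match.arg(accepted)
  if (!nzchar(rationale)) stop("card rationale must be non-empty")
  coded_kinds <- c("diagnosis_suggestion", "lab_order", "goal_suggestion",
                   "medication_suggestion", "contraindication_warning",
                   "referral_suggestion", "module_transition_prompt")
  if (kind %in% coded_kinds && !inherits(payload$concept, "coded_concept"))
    stop("card of kind ", kind, " requires a coded payload")
  structure(list(rule_id = rule_id, kind = kind, payload = payload,
                 rationale = rationale, accepted = accepted),
            class = "cds_card")
}

#' @export
print.cds_card <- function(x, ...) {
  cat(sprintf("[%s] %s (%s): %s\n", x$kind, x$rule_id, x$accepted, x$rationale))
  invisible(x)
}

#' CDS rule descriptor
#'
#' Declarative description of one module rule, consumed by the rule families
#' and attachable to flow pages. `family` selects the evaluator; the other
#' fields parameterise it.
#'
#' @param id rule id
#' @param family evaluator family: `"diagnosis"`, `"module_transition"`,
#'   `"preventive_referral"`
#' @param when optional predicate (list or `dmp_predicate`)
#' @param ... family-specific fields (`icd10`, `label`, `requires`,
#'   `target_module`, `unless_monitored`, `specialty`, `every_months`)
#' @export
cds_rule <- function(id, family, when = NULL, ...) {
  extra <- list(...)
  if (!is.null(when)) when <- predicate_to_list(as_predicate(when))
  r <- c(list(id = id, family = family, when = when), extra)
  structure(r[!vapply(r, is.null, TRUE)], class = "cds_rule_descriptor")
}

rule_when <- function(rule) {
  if (is.null(rule$when)) NULL else predicate_from_list(rule$when)
}

# --- diagnosis recommendations -------------------------------------------

#' Recommend diagnoses from session values
#'
#' Evaluates the module's diagnosis rules against values entered during an
#' encounter (falling back to the stored record for parameters not entered).
#' Each satisfied rule yields one diagnosis card carrying its ICD-10 code.
#' A rule whose required parameters are missing entirely yields a
#' measurement-request card of kind `lab_order` instead of an error.
#'
#' @param session_values named list key -> value of in-session entries
#' @param module a [disease_module()]
#' @param dataset optional `patient_dataset` backing the session
#' @param as_of reference date
#' @return list of `cds_card`s
#' @export
recommend_diagnosis <- function(session_values, module, dataset = NULL,
                                as_of = Sys.Date()) {
  if (is.null(dataset)) dataset <- empty_dataset()
  ctx <- predicate_context(dataset, as_of, session_values = session_values)
  cards <- list()
  for (rule in module$cds_rules) {
    if (!identical(rule$family, "diagnosis")) next
    req <- unlist(rule$requires %||% character())
    available <- vapply(req, function(k) {
      !is.null(session_values[[k]]) ||
        !is.null(latest_observation(dataset, k, as_of)$observation)
    }, TRUE)
    if (length(req) && !all(available)) {
      for (k in req[!available])
        cards[[length(cards) + 1L]] <- cds_card(
          rule$id, "lab_order",
          payload = list(concept = param_concept(k), status = "absent"),
          rationale = sprintf("%s is required to evaluate rule %s and has never been measured",
                              param_unit_display(k), rule$id))
      next
    }
    when <- rule_when(rule)
    if (is.null(when) || eval_predicate(when, ctx))
      cards[[length(cards) + 1L]] <- cds_card(
        rule$id, "diagnosis_suggestion",
        payload = list(concept = icd10(rule$icd10, rule$label %||% rule$icd10)),
        rationale = sprintf("Criteria met: %s",
                            if (is.null(when)) "unconditional rule" else describe_predicate(when)))
  }
  cards
}

param_unit_display <- function(key) {
  cat_ <- param_catalog()
  cat_$display[match(key, cat_$key)]
}

empty_dataset <- function() {
  patient_dataset(patient_record("anonymous", as.Date("1970-01-01"), "female"))
}

# --- lab panel ------------------------------------------------------------

#' Required lab/measurement panel
#'
#' One order card per parameter with a configured validity period whose
#' latest observation is expired or absent at `as_of`; fresh parameters are
#' omitted.
#'
#' @param dataset a `patient_dataset`
#' @param module a [disease_module()]
#' @param as_of reference date
#' @return list of `cds_card`s of kind `lab_order`
#' @export
required_lab_panel <- function(dataset, module, as_of) {
  cards <- list()
  vp <- module$validity_periods
  for (key in names(vp)) {
    hit <- latest_observation(dataset, key, as_of, vp[[key]])
    if (hit$freshness == "fresh") next
    cards[[length(cards) + 1L]] <- cds_card(
      paste0(module$module_id, "_lab_", key), "lab_order",
      payload = list(concept = param_concept(key), status = hit$freshness,
                     validity_months = vp[[key]]),
      rationale = if (hit$freshness == "absent")
        sprintf("%s has never been measured", param_unit_display(key))
      else
        sprintf("%s last measured %s, older than its %g-month validity period",
                param_unit_display(key),
                as_iso_date(hit$observation$effective_date), vp[[key]]))
  }
  cards
}

# --- treatment goals ------------------------------------------------------

#' Default treatment-goal targets
#'
#' The goal vocabulary the platform assesses (systolic and diastolic blood
#' pressure, fasting glucose, HbA1c, LDL, HDL, triglyceride, weight, BMI,
#' waist circumference), with guideline-conventional default targets. The
#' LDL target tightens monotonically with the risk category; the waist
#' target is sex-specific; the weight target is a 5 percent reduction from
#' the current weight.
#'
#' @return data.frame(param, comparator, target, unit, risk_level)
#' @export
default_goal_targets <- function() {
  rbind(
    data.frame(param = "sbp", comparator = "le", target = 140, risk_level = "default"),
    data.frame(param = "dbp", comparator = "le", target = 90, risk_level = "default"),
    data.frame(param = "fpg", comparator = "le", target = 130, risk_level = "default"),
    data.frame(param = "hba1c", comparator = "le", target = 7, risk_level = "default"),
    data.frame(param = "ldl", comparator = "le", target = 3.0, risk_level = "default"),
    data.frame(param = "ldl", comparator = "le", target = 2.6, risk_level = "high"),
    data.frame(param = "ldl", comparator = "le", target = 1.8, risk_level = "very_high"),
    data.frame(param = "hdl", comparator = "ge", target = 1.0, risk_level = "default"),
    data.frame(param = "tg", comparator = "le", target = 1.7, risk_level = "default"),
    data.frame(param = "bmi", comparator = "lt", target = 30, risk_level = "default"),
    data.frame(param = "waist", comparator = "le", target = 102, risk_level = "male"),
    data.frame(param = "waist", comparator = "le", target = 88, risk_level = "female")
  )
}

#' Recommend personalised treatment goals
#'
#' Goal cards for the configured parameter set, keyed by risk category,
#' comorbidity and sex. Glycaemic goals (fasting glucose, HbA1c) are
#' included for patients with an active diabetes diagnosis; a weight goal (5
#' percent reduction) is added when a current weight is on record and BMI
#' exceeds 25. Every goal card's payload round-trips into a [goal_record()].
#'
#' @param dataset a `patient_dataset`
#' @param module a [disease_module()]
#' @param as_of reference date
#' @param risk optional risk result (see [cvd_risk_score()]) or category string
#' @param targets goal-target configuration, see [default_goal_targets()]
#' @return list of `cds_card`s of kind `goal_suggestion`
#' @export
recommend_goals <- function(dataset, module, as_of, risk = NULL,
                            targets = default_goal_targets()) {
  risk_cat <- if (is.null(risk)) NA_character_
              else if (is.list(risk)) risk$category else as.character(risk)
  diabetic <- has_active_condition(dataset, expand_icd10_range("E10-E14"), as_of)
  sex <- dataset$patient$sex
  pick <- function(param, level_keys) {
    part <- targets[targets$param == param, , drop = FALSE]
    for (k in level_keys) if (k %in% part$risk_level)
      return(part[part$risk_level == k, , drop = FALSE][1L, ])
    NULL
  }
  wanted <- c("sbp", "dbp", "ldl", "hdl", "tg", "bmi", "waist")
  if (diabetic) wanted <- c(wanted, "fpg", "hba1c")
  cards <- list()
  for (param in wanted) {
    keys <- c(if (!is.na(risk_cat)) risk_cat, sex, "default")
    row <- pick(param, keys)
    if (is.null(row)) next
    cards[[length(cards) + 1L]] <- goal_card(module, param, row$comparator,
                                             row$target, as_of)
  }
  # 5% weight-reduction goal when overweight and a current weight is known
  w <- latest_observation(dataset, "weight", as_of)$observation
  b <- latest_observation(dataset, "bmi", as_of)$observation
  if (!is.null(w) && !is.null(b) && b$value > 25)
    cards[[length(cards) + 1L]] <- goal_card(module, "weight", "le",
                                             round(w$value * 0.95, 1), as_of)
  cards
}

goal_card <- function(module, param, comparator, target, as_of) {
  cmp_txt <- c(le = "at or below", ge = "at or above", lt = "below", gt = "above")
  cds_card(
    paste0(module$module_id, "_goal_", param), "goal_suggestion",
    payload = list(concept = param_concept(param), comparator = comparator,
                   target = as.numeric(target), unit = param_unit(param),
                   set_date = as_iso_date(as_of)),
    rationale = sprintf("Keep %s %s %g %s", param_unit_display(param),
                        cmp_txt[[comparator]], target, param_unit(param)))
}

#' Convert a goal card into a goal record
#' @param card a goal-suggestion `cds_card`
#' @param set_by recording attribution
#' @return a [goal_record()]
#' @export
goal_card_to_record <- function(card, set_by = "cds_suggested") {
  stopifnot(card$kind == "goal_suggestion")
  goal_record(card$payload$concept, card$payload$comparator,
              card$payload$target, card$payload$unit,
              card$payload$set_date, set_by)
}

# --- medication advice ----------------------------------------------------

#' Default contraindication table
#'
#' Demonstration knowledge content mapping therapeutic classes to ICD-10
#' comorbidity prefixes that contraindicate them. The operational knowledge
#' base is configuration; only the mechanism (comorbidity-keyed filtering
#' with named conflicts) is fixed.
#'
#' @return data.frame(class, icd10_prefix, condition_label)
#' @export
default_contraindications <- function() {
  data.frame(
    class = c("beta_blocker", "metformin", "thiazide", "nsaid"),
    icd10_prefix = c("J45", "N18", "M10", "N18"),
    condition_label = c("asthma", "chronic kidney disease", "gout",
                        "chronic kidney disease"),
    stringsAsFactors = FALSE)
}

#' Medication suggestions with contraindication screening
#'
#' Each candidate class yields either a suggestion card or, when an active
#' condition matches the contraindication table, a warning card naming the
#' conflicting condition.
#'
#' @param dataset a `patient_dataset`
#' @param module a [disease_module()]
#' @param candidate_classes character vector of therapeutic classes under
#'   consideration
#' @param as_of reference date
#' @param contraindications table, see [default_contraindications()]
#' @return list of `cds_card`s
#' @export
medication_advice <- function(dataset, module, candidate_classes, as_of,
                              contraindications = default_contraindications()) {
  cards <- list()
  for (cls in candidate_classes) {
    rows <- contraindications[contraindications$class == cls, , drop = FALSE]
    conflict <- NULL
    for (i in seq_len(nrow(rows)))
      if (has_active_condition(dataset, rows$icd10_prefix[i], as_of)) {
        conflict <- rows[i, ]; break
      }
    concept <- coded_concept(SYS_DMP, paste0("class-", cls), cls)
    if (is.null(conflict)) {
      cards[[length(cards) + 1L]] <- cds_card(
        paste0(module$module_id, "_med_", cls), "medication_suggestion",
        payload = list(concept = concept),
        rationale = sprintf("Consider %s for %s management", cls, module$module_id))
    } else {
      cards[[length(cards) + 1L]] <- cds_card(
        paste0(module$module_id, "_med_", cls), "contraindication_warning",
        payload = list(concept = concept,
                       conflicting_condition = conflict$icd10_prefix),
        rationale = sprintf("%s is contraindicated: patient has active %s (%s)",
                            cls, conflict$condition_label, conflict$icd10_prefix))
    }
  }
  cards
}

# --- referrals ------------------------------------------------------------

#' Referral suggestions
#'
#' Two rules: a nephrology referral when the latest fresh estimated
#' glomerular filtration rate is strictly below 60 mL/min/1.73m2, and — for
#' diabetes monitoring — a retinopathy-check referral when no ophthalmology
#' referral has been made within the last 12 months.
#'
#' @param dataset a `patient_dataset`
#' @param module a [disease_module()]
#' @param as_of reference date
#' @param track encounter track for context-dependent rules
#' @return list of `cds_card`s of kind `referral_suggestion`
#' @export
referral_advice <- function(dataset, module, as_of, track = "monitoring") {
  as_of <- as.Date(as_of)
  cards <- list()
  validity <- module$validity_periods[["egfr"]] %||% 12
  hit <- latest_observation(dataset, "egfr", as_of, validity)
  if (hit$freshness == "fresh" && hit$observation$value < 60)
    cards[[length(cards) + 1L]] <- cds_card(
      "egfr_nephrology_referral", "referral_suggestion",
      payload = list(concept = coded_concept(SYS_DMP, "specialty-nephrology", "Nephrology"),
                     egfr = hit$observation$value),
      rationale = sprintf("eGFR %g mL/min/1.73m2 is below 60: refer to nephrology",
                          hit$observation$value))
  if (module$module_id == "diabetes" && track == "monitoring") {
    for (rule in module$cds_rules) {
      if (!identical(rule$family, "preventive_referral")) next
      last <- last_referral_date(dataset, rule$specialty)
      every <- rule$every_months %||% 12
      if (is.na(last) || months_between(last, as_of) > every)
        cards[[length(cards) + 1L]] <- cds_card(
          rule$id, "referral_suggestion",
          payload = list(concept = coded_concept(SYS_DMP,
                                                 paste0("specialty-", rule$specialty),
                                                 rule$specialty)),
          rationale = if (is.na(last))
            sprintf("%s: no prior %s referral on record", rule$label %||% rule$id, rule$specialty)
          else
            sprintf("%s: last %s referral on %s is older than %g months",
                    rule$label %||% rule$id, rule$specialty, as_iso_date(last), every))
    }
  }
  cards
}

# most recent date associated with a referral activity to a specialty:
# the referring encounter's date when resolvable, else the activity due date
last_referral_date <- function(dataset, specialty) {
  code <- paste0("specialty-", specialty)
  dates <- as.Date(character())
  for (plan in dataset$care_plans) {
    hit <- any(vapply(plan$activities, function(a)
      a$kind == "referral" && a$payload$code == code, TRUE))
    if (!hit) next
    enc <- Filter(function(e) paste0(e$module_id, "-", as_iso_date(e$date)) == plan$encounter_ref ||
                    identical(plan$encounter_ref, ""), dataset$encounters)
    if (length(enc)) {
      dates <- c(dates, max(as.Date(vapply(enc, function(e) as.character(e$date), ""))))
    } else {
      due <- Filter(function(a) a$kind == "referral" && a$payload$code == code,
                    plan$activities)
      dd <- as.Date(vapply(due, function(a) as.character(a$due_date), ""))
      dates <- c(dates, dd[!is.na(dd)])
    }
  }
  if (length(dates) == 0L) return(as.Date(NA))
  max(dates)
}

# --- follow-up ------------------------------------------------------------

#' Follow-up interval recommendation
#'
#' Resolves the recall interval for a module/track from its interval rule —
#' by risk category (e.g. cardiovascular screening every 24 months at low
#' risk, every 12 at high risk) or control status, falling back to the
#' default key when the context is unknown — and wraps it in a follow-up
#' card carrying the computed due date.
#'
#' @param module a [disease_module()]
#' @param track `"screening"` or `"monitoring"`
#' @param as_of date the interval counts from
#' @param risk_category,control_status optional context keys (risk takes
#'   precedence when both resolve)
#' @return list with `months` and `card`
#' @export
follow_up_interval <- function(module, track, as_of,
                               risk_category = NA_character_,
                               control_status = NA_character_) {
  rule <- if (track == "screening") module$screening_interval else module$monitoring_interval
  key <- if (!is.na(risk_category) && risk_category %in% names(rule)) risk_category
         else if (!is.na(control_status) && control_status %in% names(rule)) control_status
         else NA_character_
  months <- resolve_interval(rule, key)
  due <- add_months(as_of, months)
  card <- cds_card(
    paste0(module$module_id, "_followup_", track), "follow_up_suggestion",
    payload = list(interval_months = months, due_date = as_iso_date(due)),
    rationale = sprintf("Next %s %s encounter due %s (every %g months%s)",
                        module$module_id, track, as_iso_date(due), months,
                        if (is.na(key)) "" else sprintf(", %s", key)))
  list(months = months, card = card)
}

# --- module transitions ---------------------------------------------------

#' Cross-module transition prompts
#'
#' Automated care-pathway transitions for multimorbid patients:
#' a fasting plasma glucose strictly above 110 mg/dL prompts a diabetes
#' screening unless the patient is already monitored for diabetes, and a
#' patient aged over 40 with no recorded cardiovascular risk score is
#' prompted into the cardiovascular risk module during hypertension or
#' diabetes monitoring.
#'
#' @param dataset a `patient_dataset`
#' @param module the module of the current encounter
#' @param as_of reference date
#' @param session_values in-session entered values (shadow the record)
#' @param track current encounter track
#' @return list of `cds_card`s of kind `module_transition_prompt`
#' @export
module_transition_check <- function(dataset, module, as_of,
                                    session_values = list(),
                                    track = "screening") {
  as_of <- as.Date(as_of)
  cards <- list()
  fpg <- session_values[["fpg"]]
  if (is.null(fpg)) {
    hit <- latest_observation(dataset, "fpg", as_of, 12)
    if (!is.null(hit$observation) && hit$freshness == "fresh") fpg <- hit$observation$value
  }
  diabetes_monitored <- has_active_condition(dataset, expand_icd10_range("E10-E14"), as_of)
  if (!is.null(fpg) && fpg > 110 && !diabetes_monitored)
    cards[[length(cards) + 1L]] <- cds_card(
      "fpg_diabetes_prompt", "module_transition_prompt",
      payload = list(concept = coded_concept(SYS_MODULE, "diabetes", "Diabetes module"),
                     fpg = fpg),
      rationale = sprintf("Fasting plasma glucose %g mg/dL exceeds 110: consider diabetes screening", fpg))
  if (module$module_id %in% c("hypertension", "diabetes") && track == "monitoring") {
    age <- age_at(dataset$patient$birth_date, as_of)
    score <- latest_observation(dataset, "score10y", as_of)$observation
    if (age > 40 && is.null(score))
      cards[[length(cards) + 1L]] <- cds_card(
        "missing_cvd_risk_prompt", "module_transition_prompt",
        payload = list(concept = coded_concept(SYS_MODULE, "cvd_risk",
                                               "Cardiovascular risk module")),
        rationale = "Aged over 40 with no recorded cardiovascular risk score: continue with the cardiovascular risk module")
  }
  cards
}
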