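#' Patient demographics record
#'
#' @param patient_id opaque identifier
#' @param birth_date date of birth
#' @param sex `"female"` or `"male"`
#' @param assigned_fmp identifier of the family medicine practitioner whose
#'   panel the patient belongs to (may be `NA`)
#' @export
patient_record <- function(patient_id, birth_date, sex, assigned_fmp = NA_character_) {
  sex <- match.arg(sex, c("female", "male"))
  structure(list(patient_id = as.character(patient_id),
                 birth_date = as.Date(birth_date),
                 sex = sex,
                 assigned_fmp = as.character(assigned_fmp)),
            class = "patient_record")
}

#' Quantitative clinical observation
#'
#' @param code a `coded_concept` or a parameter key from [param_catalog()]
#' @param value finite numeric value
#' @param unit unit string; defaults to the catalogue unit when `code` is a key
#' @param effective_date measurement date
#' @param origin where the value came from: synced from the national EHR,
#'   entered during a platform encounter, or self-reported
#' @export
clinical_observation <- function(code, value, unit = NULL, effective_date,
                                 origin = c("ehr_sync", "encounter_entry", "self_reported")) {
  origin <- match.arg(origin)
  if (is.character(code)) {
    if (is.null(unit)) unit <- param_unit(code)
    code <- param_concept(code)
  }
  stopifnot(inherits(code, "coded_concept"), is.numeric(value), is.finite(value))
  if (is.null(unit)) stop("unit required for quantitative observation")
  structure(list(code = code, value = as.numeric(value), unit = unit,
                 effective_date = as.Date(effective_date), origin = origin),
            class = "clinical_observation")
}

#' Coded condition (diagnosis) entry
#' @param icd10_code ICD-10 code string or a `coded_concept` in the ICD-10 system
#' @param onset_date diagnosis/onset date
#' @param clinical_status `"active"` or `"resolved"`
#' @export
condition_entry <- function(icd10_code, onset_date,
                            clinical_status = c("active", "resolved")) {
  clinical_status <- match.arg(clinical_status)
  cc <- if (is.character(icd10_code)) icd10(icd10_code) else icd10_code
  stopifnot(inherits(cc, "coded_concept"))
  if (!grepl("^[A-Z][0-9]{2}", cc$code)) stop("not an ICD-10 shaped code: ", cc$code)
  structure(list(icd10 = cc, onset_date = as.Date(onset_date),
                 clinical_status = clinical_status),
            class = "condition_entry")
}

#' Medication entry with therapeutic-class tags
#' @param code medication `coded_concept`
#' @param therapeutic_classes character vector of class tags
#'   (e.g. `"antihypertensive"`, `"antidiabetic"`)
#' @param period_start start of use
#' @param period_end end of use; `NA` means ongoing
#' @export
medication_entry <- function(code, therapeutic_classes = character(),
                             period_start, period_end = as.Date(NA)) {
  stopifnot(inherits(code, "coded_concept"))
  period_start <- as.Date(period_start); period_end <- as.Date(period_end)
  if (!is.na(period_end) && period_end < period_start)
    stop("period_end precedes period_start")
  structure(list(code = code,
                 therapeutic_classes = sort(unique(as.character(therapeutic_classes))),
                 period_start = period_start, period_end = period_end),
            class = "medication_entry")
}

#' Screening/monitoring encounter record
#' @param module_id disease module identifier
#' @param encounter_type `"screening"` or `"monitoring"`
#' @param date encounter date
#' @param performer practitioner identifier
#' @param duration_minutes non-negative duration
#' @export
encounter_record <- function(module_id, encounter_type = c("screening", "monitoring"),
                             date, performer = NA_character_, duration_minutes = 0) {
  encounter_type <- match.arg(encounter_type)
  stopifnot(is.numeric(duration_minutes), duration_minutes >= 0)
  structure(list(module_id = as.character(module_id),
                 encounter_type = encounter_type, date = as.Date(date),
                 performer = as.character(performer),
                 duration_minutes = as.numeric(duration_minutes)),
            class = "encounter_record")
}

#' Treatment goal record
#'
#' A personalised target for one clinical parameter, e.g. systolic blood
#' pressure at or below 140 mmHg. Goals are suggested by decision support
#' and may be overridden by the physician.
#'
#' @param parameter `coded_concept` or parameter key
#' @param comparator `"le"`, `"ge"`, `"lt"` or `"gt"` — the direction in which
#'   an observed value counts as achieving the goal
#' @param target_value finite numeric target
#' @param unit unit string (catalogue default when `parameter` is a key)
#' @param set_date date the goal was set
#' @param set_by `"cds_suggested"` or `"physician_override"`
#' @export
goal_record <- function(parameter, comparator = c("le", "ge", "lt", "gt"),
                        target_value, unit = NULL, set_date,
                        set_by = c("cds_suggested", "physician_override")) {
  comparator <- match.arg(comparator)
  set_by <- match.arg(set_by)
  if (is.character(parameter)) {
    if (is.null(unit)) unit <- param_unit(parameter)
    parameter <- param_concept(parameter)
  }
  stopifnot(inherits(parameter, "coded_concept"),
            is.numeric(target_value), is.finite(target_value))
  if (is.null(unit)) stop("unit required")
  structure(list(parameter = parameter, comparator = comparator,
                 target_value = as.numeric(target_value), unit = unit,
                 set_date = as.Date(set_date), set_by = set_by),
            class = "goal_record")
}

CAREPLAN_ACTIVITY_KINDS <- c("medication_order", "lab_order", "referral",
                             "lifestyle_recommendation", "follow_up_appointment",
                             "education_material")

#' Care-plan activity
#' @param kind one of the platform activity kinds
#' @param payload a `coded_concept` describing the activity content
#' @param text free-text instruction
#' @param due_date optional due date; required for follow-up appointments
#' @export
care_plan_activity <- function(kind, payload, text = "", due_date = as.Date(NA)) {
  kind <- match.arg(kind, CAREPLAN_ACTIVITY_KINDS)
  stopifnot(inherits(payload, "coded_concept"))
  due_date <- as.Date(due_date)
  if (kind == "follow_up_appointment" && is.na(due_date))
    stop("follow_up_appointment activity requires a due_date")
  structure(list(kind = kind, payload = payload, text = as.character(text),
                 due_date = due_date),
            class = "care_plan_activity")
}

#' Care-plan record
#' @param patient_id patient identifier
#' @param encounter_ref identifier of the encounter that produced the plan
#' @param goals list of [goal_record()]s
#' @param activities list of [care_plan_activity()]s
#' @export
care_plan_record <- function(patient_id, encounter_ref, goals = list(),
                             activities = list()) {
  stopifnot(all(vapply(goals, inherits, TRUE, "goal_record")),
            all(vapply(activities, inherits, TRUE, "care_plan_activity")))
  structure(list(patient_id = as.character(patient_id),
                 encounter_ref = as.character(encounter_ref),
                 goals = goals, activities = activities),
            class = "care_plan_record")
}

#' One citizen's longitudinal record
#'
#' The container every engine operates on: demographics plus collections of
#' conditions, medications, observations, encounters, goals and care plans,
#' as synchronised from the national record or accumulated during platform
#' encounters.
#'
#' @param patient a [patient_record()]
#' @param conditions,medications,observations,encounters,goals,care_plans lists
#' @return object of class `patient_dataset`
#' @export
patient_dataset <- function(patient, conditions = list(), medications = list(),
                            observations = list(), encounters = list(),
                            goals = list(), care_plans = list()) {
  ds <- structure(list(patient = patient, conditions = conditions,
                       medications = medications, observations = observations,
                       encounters = encounters, goals = goals,
                       care_plans = care_plans),
                  class = "patient_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a patient dataset's structural invariants
#'
#' Checks element classes, that contained care plans reference the dataset's
#' patient, and that no observation carries a non-finite value. Called by the
#' constructor and by the bundle writer.
#'
#' @param ds a `patient_dataset`
#' @return `ds`, invisibly; stops with a message listing all violations
#' @export
validate_dataset <- function(ds) {
  problems <- character()
  chk <- function(items, cls) all(vapply(items, inherits, TRUE, cls))
  if (!inherits(ds$patient, "patient_record")) problems <- c(problems, "patient is not a patient_record")
  if (!chk(ds$conditions, "condition_entry")) problems <- c(problems, "conditions contain non-condition entries")
  if (!chk(ds$medications, "medication_entry")) problems <- c(problems, "medications contain non-medication entries")
  if (!chk(ds$observations, "clinical_observation")) problems <- c(problems, "observations contain non-observation entries")
  if (!chk(ds$encounters, "encounter_record")) problems <- c(problems, "encounters contain non-encounter entries")
  if (!chk(ds$goals, "goal_record")) problems <- c(problems, "goals contain non-goal entries")
  if (!chk(ds$care_plans, "care_plan_record")) problems <- c(problems, "care_plans contain non-care-plan entries")
  if (length(problems) == 0L) {
    bad_plan <- vapply(ds$care_plans, function(p) p$patient_id != ds$patient$patient_id, TRUE)
    if (any(bad_plan)) problems <- c(problems, "care plan references a different patient")
  }
  if (length(problems)) stop("invalid patient_dataset: ", paste(problems, collapse = "; "))
  invisible(ds)
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat(sprintf("Patient %s (%s, born %s)\n", x$patient$patient_id,
              x$patient$sex, format(x$patient$birth_date)))
  cat(sprintf("  %d conditions, %d medications, %d observations, %d encounters, %d goals, %d care plans\n",
              length(x$conditions), length(x$medications), length(x$observations),
              length(x$encounters), length(x$goals), length(x$care_plans)))
  invisible(x)
}

#' Latest observation of a parameter, with freshness
#'
#' Returns the observation of `code` with the greatest effective date not
#' after `as_of`, flagged `fresh` or `expired` against a validity period in
#' whole calendar months. The platform enforces parameter recency this way:
#' an expired value is still shown (prefilled) but flagged for renewal.
#' An observation is `expired` when its age strictly exceeds
#' `validity_months`; absence of any observation dated at or before `as_of`
#' yields `freshness = "absent"`.
#'
#' @param dataset a `patient_dataset`
#' @param code parameter key, or a `coded_concept`
#' @param as_of reference date
#' @param validity_months validity period in months; `NULL` means never expires
#' @return list with `observation` (or `NULL`) and `freshness`
#'   (`"fresh"`, `"expired"`, `"absent"`)
#' @export
latest_observation <- function(dataset, code, as_of, validity_months = NULL) {
  as_of <- as.Date(as_of)
  cc <- if (is.character(code)) param_concept(code) else code
  hits <- Filter(function(o) o$code$system == cc$system && o$code$code == cc$code &&
                   o$effective_date <= as_of, dataset$observations)
  if (length(hits) == 0L)
    return(list(observation = NULL, freshness = "absent"))
  dates <- as.Date(vapply(hits, function(o) as.character(o$effective_date), ""))
  obs <- hits[[which.max(as.integer(dates))]]
  freshness <- "fresh"
  if (!is.null(validity_months) && !is.na(validity_months)) {
    age <- months_between(obs$effective_date, as_of)
    if (age > validity_months) freshness <- "expired"
  }
  list(observation = obs, freshness = freshness)
}

# record identity keys used for incremental merge -------------------------

record_identity <- function(x) {
  switch(class(x)[1L],
    condition_entry = paste("cond", x$icd10$code, as_iso_date(x$onset_date)),
    medication_entry = paste("med", x$code$system, x$code$code, as_iso_date(x$period_start)),
    clinical_observation = paste("obs", x$code$system, x$code$code,
                                 as_iso_date(x$effective_date), x$origin),
    encounter_record = paste("enc", x$module_id, x$encounter_type,
                             as_iso_date(x$date), x$performer),
    goal_record = paste("goal", x$parameter$system, x$parameter$code,
                        as_iso_date(x$set_date)),
    care_plan_record = paste("plan", x$encounter_ref),
    stop("no identity for class ", class(x)[1L])
  )
}

merge_collection <- function(base, delta) {
  out <- base
  keys <- vapply(out, record_identity, "")
  for (item in delta) {
    k <- record_identity(item)
    i <- match(k, keys)
    if (is.na(i)) {
      out[[length(out) + 1L]] <- item
      keys <- c(keys, k)
    } else {
      out[[i]] <- item  # delta holds the newer version of the same record
    }
  }
  out
}

#' Incremental synchronisation merge
#'
#' Merges a freshly synchronised delta into a base dataset for the same
#' patient. Records are unioned; when base and delta contain the same record
#' identity (code + date, see details), the delta's version — the newer sync —
#' replaces the base's. The merge is idempotent and order-insensitive for
#' disjoint deltas.
#'
#' Identity is per record type: observations by (code system, code,
#' effective date, origin); conditions by (ICD-10, onset date); medications
#' by (code, period start); encounters by (module, type, date, performer);
#' goals by (parameter, set date); care plans by encounter reference.
#'
#' @param base,delta `patient_dataset`s for the same patient
#' @return merged `patient_dataset`
#' @export
merge_incremental <- function(base, delta) {
  if (base$patient$patient_id != delta$patient$patient_id)
    stop("cannot merge datasets of different patients: ",
         base$patient$patient_id, " vs ", delta$patient$patient_id)
  patient_dataset(
    patient = delta$patient,
    conditions = merge_collection(base$conditions, delta$conditions),
    medications = merge_collection(base$medications, delta$medications),
    observations = merge_collection(base$observations, delta$observations),
    encounters = merge_collection(base$encounters, delta$encounters),
    goals = merge_collection(base$goals, delta$goals),
    care_plans = merge_collection(base$care_plans, delta$care_plans)
  )
}

# convenience used across engines -----------------------------------------

has_active_condition <- function(dataset, prefixes, as_of = NULL) {
  any(vapply(dataset$conditions, function(co) {
    co$clinical_status == "active" &&
      (is.null(as_of) || co$onset_date <= as.Date(as_of)) &&
      any(startsWith(co$icd10$code, prefixes))
  }, TRUE))
}

on_medication_class <- function(dataset, tag, as_of) {
  as_of <- as.Date(as_of)
  any(vapply(dataset$medications, function(m) {
    tag %in% m$therapeutic_classes && m$period_start <= as_of &&
      (is.na(m$period_end) || m$period_end >= as_of)
  }, TRUE))
}
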