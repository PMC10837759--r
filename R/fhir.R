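# FHIR R4 JSON serialisation of the patient data model.
#
# The bundle writer emits `Bundle` documents of type "collection" holding the
# supported resource types (Patient, Condition, Observation,
# MedicationStatement, Encounter, Goal, CarePlan); the reader is tolerant:
# unsupported resource types are skipped and counted. Platform-specific
# content with no first-class FHIR element (observation origin, therapeutic
# class tags, activity kind) travels in `urn:dmp:*` extensions so that
# read(write(x)) is the identity on supported fields.

EXT_ORIGIN <- "urn:dmp:observation-origin"
EXT_CLASS <- "urn:dmp:therapeutic-class"
EXT_KIND <- "urn:dmp:activity-kind"
EXT_GOAL_SOURCE <- "urn:dmp:goal-source"
SYS_MODULE <- "urn:dmp:module"
SYS_ENCTYPE <- "urn:dmp:encounter-type"

comparator_fhir <- c(le = "<=", ge = ">=", lt = "<", gt = ">")
fhir_comparator <- c("<=" = "le", ">=" = "ge", "<" = "lt", ">" = "gt")

# R4 CarePlan.activity.detail.kind value set, by platform activity kind
detail_kind_fhir <- c(medication_order = "MedicationRequest",
                      lab_order = "ServiceRequest",
                      referral = "ServiceRequest",
                      lifestyle_recommendation = "Task",
                      follow_up_appointment = "Appointment",
                      education_material = "CommunicationRequest")

coding_json <- function(cc) list(system = cc$system, code = cc$code, display = cc$display)
coding_from_json <- function(j) coded_concept(j$system, j$code, j$display %||% j$code)
`%||%` <- function(a, b) if (is.null(a)) b else a

# --- resource writers -----------------------------------------------------

patient_json <- function(p) {
  out <- list(resourceType = "Patient", id = p$patient_id,
              gender = p$sex, birthDate = as_iso_date(p$birth_date))
  if (!is.na(p$assigned_fmp))
    out$generalPractitioner <- list(list(identifier = list(value = p$assigned_fmp)))
  out
}

condition_json <- function(x, pid, id) {
  list(resourceType = "Condition", id = id,
       clinicalStatus = list(coding = list(list(
         system = "http://terminology.hl7.org/CodeSystem/condition-clinical",
         code = x$clinical_status))),
       code = list(coding = list(coding_json(x$icd10))),
       subject = list(reference = paste0("Patient/", pid)),
       onsetDateTime = as_iso_date(x$onset_date))
}

observation_json <- function(x, pid, id) {
  list(resourceType = "Observation", id = id, status = "final",
       extension = list(list(url = EXT_ORIGIN, valueCode = x$origin)),
       code = list(coding = list(coding_json(x$code))),
       subject = list(reference = paste0("Patient/", pid)),
       effectiveDateTime = as_iso_date(x$effective_date),
       valueQuantity = list(value = x$value, unit = x$unit))
}

medication_json <- function(x, pid, id) {
  period <- list(start = as_iso_date(x$period_start))
  if (!is.na(x$period_end)) period$end <- as_iso_date(x$period_end)
  out <- list(resourceType = "MedicationStatement", id = id,
              status = if (is.na(x$period_end)) "active" else "completed",
              medicationCodeableConcept = list(coding = list(coding_json(x$code))),
              subject = list(reference = paste0("Patient/", pid)),
              effectivePeriod = period)
  if (length(x$therapeutic_classes))
    out$extension <- lapply(x$therapeutic_classes,
                            function(tag) list(url = EXT_CLASS, valueCode = tag))
  out
}

encounter_json <- function(x, pid, id) {
  out <- list(resourceType = "Encounter", id = id, status = "finished",
              class = list(system = "http://terminology.hl7.org/CodeSystem/v3-ActCode",
                           code = "AMB"),
              type = list(list(coding = list(list(system = SYS_ENCTYPE,
                                                  code = x$encounter_type)))),
              serviceType = list(coding = list(list(system = SYS_MODULE,
                                                    code = x$module_id))),
              subject = list(reference = paste0("Patient/", pid)),
              period = list(start = as_iso_date(x$date)),
              length = list(value = x$duration_minutes, unit = "min"))
  if (!is.na(x$performer))
    out$participant <- list(list(individual = list(identifier = list(value = x$performer))))
  out
}

goal_json <- function(x, pid, id) {
  list(resourceType = "Goal", id = id, lifecycleStatus = "active",
       extension = list(list(url = EXT_GOAL_SOURCE, valueCode = x$set_by)),
       description = list(text = x$parameter$display),
       subject = list(reference = paste0("Patient/", pid)),
       startDate = as_iso_date(x$set_date),
       target = list(list(measure = list(coding = list(coding_json(x$parameter))),
                          detailQuantity = list(value = x$target_value, unit = x$unit,
                                                comparator = unname(comparator_fhir[x$comparator])))))
}

activity_json <- function(a) {
  detail <- list(kind = unname(detail_kind_fhir[a$kind]),
                 extension = list(list(url = EXT_KIND, valueCode = a$kind)),
                 code = list(coding = list(coding_json(a$payload)), text = a$text),
                 status = "not-started")
  if (!is.na(a$due_date)) detail$scheduledString <- as_iso_date(a$due_date)
  list(detail = detail)
}

careplan_json <- function(plan, id = "careplan-1", contained_goals = TRUE) {
  out <- list(resourceType = "CarePlan", id = id, status = "active", intent = "plan",
              subject = list(reference = paste0("Patient/", plan$patient_id)),
              encounter = list(reference = paste0("Encounter/", plan$encounter_ref)))
  if (length(plan$goals)) {
    gids <- sprintf("goal-%d", seq_along(plan$goals))
    if (contained_goals) {
      out$contained <- Map(goal_json, plan$goals, pid = plan$patient_id, id = gids)
      out$goal <- lapply(gids, function(g) list(reference = paste0("#", g)))
    } else {
      out$goal <- lapply(gids, function(g) list(reference = paste0("Goal/", g)))
    }
  }
  out$activity <- lapply(plan$activities, activity_json)
  out
}

# --- resource readers -----------------------------------------------------

read_patient <- function(r) {
  fmp <- NA_character_
  gp <- r$generalPractitioner
  if (!is.null(gp) && length(gp)) fmp <- gp[[1L]]$identifier$value %||% NA_character_
  patient_record(r$id, r$birthDate, r$gender, fmp)
}

read_condition <- function(r) {
  condition_entry(coding_from_json(r$code$coding[[1L]]),
                  substr(r$onsetDateTime, 1L, 10L),
                  r$clinicalStatus$coding[[1L]]$code)
}

ext_values <- function(r, url) {
  vals <- character()
  for (e in r$extension %||% list()) if (identical(e$url, url)) vals <- c(vals, e$valueCode)
  vals
}

read_observation <- function(r) {
  origin <- ext_values(r, EXT_ORIGIN)
  clinical_observation(coding_from_json(r$code$coding[[1L]]),
                       r$valueQuantity$value, r$valueQuantity$unit,
                       substr(r$effectiveDateTime, 1L, 10L),
                       if (length(origin)) origin[1L] else "ehr_sync")
}

read_medication <- function(r) {
  medication_entry(coding_from_json(r$medicationCodeableConcept$coding[[1L]]),
                   ext_values(r, EXT_CLASS),
                   r$effectivePeriod$start,
                   r$effectivePeriod$end %||% NA)
}

read_encounter <- function(r) {
  perf <- NA_character_
  if (!is.null(r$participant) && length(r$participant))
    perf <- r$participant[[1L]]$individual$identifier$value %||% NA_character_
  encounter_record(r$serviceType$coding[[1L]]$code,
                   r$type[[1L]]$coding[[1L]]$code,
                   substr(r$period$start, 1L, 10L), perf,
                   r$length$value %||% 0)
}

read_goal <- function(r) {
  tgt <- r$target[[1L]]
  src <- ext_values(r, EXT_GOAL_SOURCE)
  goal_record(coding_from_json(tgt$measure$coding[[1L]]),
              unname(fhir_comparator[tgt$detailQuantity$comparator]),
              tgt$detailQuantity$value, tgt$detailQuantity$unit,
              r$startDate, if (length(src)) src[1L] else "cds_suggested")
}

read_activity <- function(a) {
  d <- a$detail
  kind <- ext_values(d, EXT_KIND)
  care_plan_activity(if (length(kind)) kind[1L] else "lifestyle_recommendation",
                     coding_from_json(d$code$coding[[1L]]),
                     d$code$text %||% "",
                     d$scheduledString %||% NA)
}

read_careplan <- function(r) {
  pid <- sub("^Patient/", "", r$subject$reference)
  eref <- sub("^Encounter/", "", r$encounter$reference %||% "")
  goals <- lapply(r$contained %||% list(), read_goal)
  care_plan_record(pid, eref, goals, lapply(r$activity %||% list(), read_activity))
}

SUPPORTED_RESOURCES <- c("Patient", "Condition", "Observation",
                         "MedicationStatement", "Encounter", "Goal", "CarePlan")

#' Read a FHIR R4 bundle into a patient dataset
#'
#' Accepts a file path, a JSON string, or an already-parsed list. The bundle
#' must contain exactly one `Patient` resource; all supported resource types
#' are mapped, anything else is skipped with a warning carrying the skip
#' count (also available as `attr(x, "skipped")`).
#'
#' @param document path, JSON string, or parsed bundle list
#' @return a [patient_dataset()]
#' @export
read_bundle <- function(document) {
  doc <- parse_json_document(document)
  if (!identical(doc$resourceType, "Bundle")) stop("document is not a FHIR Bundle")
  entries <- doc$entry %||% list()
  patients <- list(); conditions <- list(); observations <- list()
  medications <- list(); encounters <- list(); goals <- list(); plans <- list()
  skipped <- 0L
  for (i in seq_along(entries)) {
    r <- entries[[i]]$resource
    rt <- r$resourceType %||% ""
    parsed <- tryCatch(switch(rt,
      Patient = { patients[[length(patients) + 1L]] <- read_patient(r); TRUE },
      Condition = { conditions[[length(conditions) + 1L]] <- read_condition(r); TRUE },
      Observation = { observations[[length(observations) + 1L]] <- read_observation(r); TRUE },
      MedicationStatement = { medications[[length(medications) + 1L]] <- read_medication(r); TRUE },
      Encounter = { encounters[[length(encounters) + 1L]] <- read_encounter(r); TRUE },
      Goal = { goals[[length(goals) + 1L]] <- read_goal(r); TRUE },
      CarePlan = { plans[[length(plans) + 1L]] <- read_careplan(r); TRUE },
      NA),
      error = function(e) stop("malformed resource at entry ", i, " (", rt, "): ",
                               conditionMessage(e), call. = FALSE))
    if (is.na(parsed)) skipped <- skipped + 1L
  }
  if (length(patients) != 1L)
    stop("bundle must contain exactly one Patient resource, found ", length(patients))
  if (skipped > 0L)
    warning(skipped, " unsupported resource(s) skipped", call. = FALSE)
  ds <- patient_dataset(patients[[1L]], conditions, medications, observations,
                        encounters, goals, plans)
  if (skipped > 0L) attr(ds, "skipped") <- skipped
  ds
}

parse_json_document <- function(document) {
  if (is.list(document)) return(document)
  if (is.character(document) && length(document) == 1L) {
    txt <- if (file.exists(document)) paste(readLines(document, warn = FALSE), collapse = "\n")
           else document
    return(jsonlite::fromJSON(txt, simplifyVector = FALSE))
  }
  stop("cannot interpret document input")
}

#' Write a patient dataset as a FHIR R4 bundle
#'
#' @param dataset a valid `patient_dataset`
#' @param path optional file path; when given the JSON is written there and
#'   the path returned invisibly, otherwise the bundle list is returned
#' @return bundle as a list (or path, invisibly)
#' @export
write_bundle <- function(dataset, path = NULL) {
  validate_dataset(dataset)
  pid <- dataset$patient$patient_id
  mk <- function(items, f, prefix) {
    if (length(items) == 0L) return(list())
    Map(function(x, i) list(resource = f(x, pid, sprintf("%s-%d", prefix, i))),
        items, seq_along(items))
  }
  entries <- c(list(list(resource = patient_json(dataset$patient))),
               mk(dataset$conditions, condition_json, "cond"),
               mk(dataset$observations, observation_json, "obs"),
               mk(dataset$medications, medication_json, "med"),
               mk(dataset$encounters, encounter_json, "enc"),
               mk(dataset$goals, goal_json, "goal"),
               Map(function(p, i) list(resource = careplan_json(p, sprintf("plan-%d", i))),
                   dataset$care_plans, seq_along(dataset$care_plans)))
  bundle <- list(resourceType = "Bundle", type = "collection",
                 entry = unname(entries))
  if (is.null(path)) return(bundle)
  writeLines(jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' Export a care plan as a standalone FHIR R4 CarePlan document
#'
#' Goals are embedded as contained `Goal` resources and referenced from
#' `CarePlan.goal`; each activity becomes one `CarePlan.activity` with the
#' platform activity kind mapped onto the R4 `detail.kind` value set.
#'
#' @param plan a [care_plan_record()]
#' @param path optional output file
#' @return CarePlan document as a list (or path, invisibly)
#' @export
export_care_plan <- function(plan, path = NULL) {
  if (!inherits(plan, "care_plan_record")) stop("not a care_plan_record")
  doc <- careplan_json(plan)
  if (is.null(path)) return(doc)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' Structural validation of a FHIR R4 CarePlan document
#'
#' A dependency-free structural validator encoding the R4 `CarePlan` resource
#' definition: required elements (`status`, `intent`, `subject`), bound value
#' sets for `status`, `intent` and `activity.detail.kind`, reference shapes,
#' well-formed contained `Goal` resources, and date syntax on scheduled
#' activities. It re-parses serialised JSON, so it checks the document, not
#' the in-memory object that produced it.
#'
#' @param document path, JSON string, or parsed CarePlan list
#' @return list with `valid` (logical) and `problems` (character)
#' @export
validate_careplan_document <- function(document) {
  doc <- parse_json_document(document)
  p <- character()
  req <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  req(identical(doc$resourceType, "CarePlan"), "resourceType must be 'CarePlan'")
  req(is.character(doc$status %||% NULL) &&
        doc$status %in% c("draft", "active", "on-hold", "revoked", "completed",
                          "entered-in-error", "unknown"),
      "status missing or not in the R4 request-status value set")
  req(is.character(doc$intent %||% NULL) &&
        doc$intent %in% c("proposal", "plan", "order", "option"),
      "intent missing or not in the R4 care-plan-intent value set")
  req(is.list(doc$subject) && is.character(doc$subject$reference %||% NULL),
      "subject.reference required")
  for (g in doc$goal %||% list())
    req(is.character(g$reference %||% NULL), "goal entries must be references")
  contained_ids <- vapply(doc$contained %||% list(),
                          function(r) as.character(r$id %||% ""), "")
  for (g in doc$goal %||% list()) {
    ref <- g$reference %||% ""
    if (startsWith(ref, "#"))
      req(substring(ref, 2L) %in% contained_ids,
          paste0("goal reference ", ref, " has no contained resource"))
  }
  for (r in doc$contained %||% list()) {
    req(identical(r$resourceType, "Goal"), "contained resources must be Goals")
    req(is.character(r$lifecycleStatus %||% NULL), "contained Goal lacks lifecycleStatus")
    req(length(r$target %||% list()) >= 1L, "contained Goal lacks a target")
  }
  acts <- doc$activity %||% list()
  for (i in seq_along(acts)) {
    d <- acts[[i]]$detail
    req(is.list(d), sprintf("activity[%d] lacks detail", i))
    if (!is.list(d)) next
    req(is.character(d$status %||% NULL) &&
          d$status %in% c("not-started", "scheduled", "in-progress", "on-hold",
                          "completed", "cancelled", "stopped", "unknown",
                          "entered-in-error"),
        sprintf("activity[%d].detail.status invalid", i))
    if (!is.null(d$kind))
      req(d$kind %in% c("Appointment", "CommunicationRequest", "DeviceRequest",
                        "MedicationRequest", "NutritionOrder", "Task",
                        "ServiceRequest", "VisionPrescription"),
          sprintf("activity[%d].detail.kind outside the R4 value set", i))
    if (!is.null(d$scheduledString))
      req(grepl("^\\d{4}-\\d{2}-\\d{2}$", d$scheduledString),
          sprintf("activity[%d] scheduledString is not an ISO date", i))
  }
  list(valid = length(p) == 0L, problems = p)
}
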