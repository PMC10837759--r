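# CDS Hooks document contract over the rule families.
#
# Discovery lists one service per rule family with a prefetch template; an
# invocation carries the hook name, a context, and a prefetch holding a FHIR
# bundle of the patient's record. The service layer parses the prefetch with
# read_bundle, runs the *same* library function a direct caller would use,
# and serialises the resulting cards in CDS Hooks card shape (summary,
# detail, indicator, source, suggestions) — transport adds nothing.

CDS_SERVICES <- data.frame(
  id = c("cvd-risk-score", "diagnosis-recommendation", "lab-panel",
         "lab-based-referral", "goal-recommendation", "medication-advice",
         "preventive-referral", "follow-up-interval", "module-transition"),
  title = c("Cardiovascular risk scoring",
            "Diagnosis recommendations",
            "Required lab and measurement panel",
            "Lab-driven specialist referral",
            "Personalised treatment goals",
            "Medication suggestions and contraindication screening",
            "Preventive consultation referrals",
            "Follow-up visit scheduling",
            "Care-pathway module transitions"),
  hook = c("patient-view", "order-select", "patient-view", "patient-view",
           "patient-view", "order-select", "patient-view", "patient-view",
           "patient-view"),
  stringsAsFactors = FALSE)

#' CDS Hooks discovery document
#'
#' Lists the nine decision-support services, one per rule family, each with
#' its hook and a prefetch template requesting the patient's record bundle.
#'
#' @return list shaped like a CDS Hooks discovery response
#' @export
cds_discovery <- function() {
  list(services = lapply(seq_len(nrow(CDS_SERVICES)), function(i) {
    list(id = CDS_SERVICES$id[i],
         title = CDS_SERVICES$title[i],
         hook = CDS_SERVICES$hook[i],
         description = CDS_SERVICES$title[i],
         prefetch = list(patientBundle = "Patient/{{context.patientId}}/$everything"))
  }))
}

card_to_hooks_json <- function(card) {
  indicator <- if (card$kind == "contraindication_warning") "warning" else "info"
  out <- list(summary = substr(card$rationale, 1L, 140L),
              detail = card$rationale,
              indicator = indicator,
              source = list(label = paste0("dmpkit rule ", card$rule_id)))
  sug <- list(label = card$rationale)
  if (inherits(card$payload$concept, "coded_concept"))
    sug$actions <- list(list(type = "create",
                             description = card$rationale,
                             resourceCoding = coding_json(card$payload$concept)))
  extra <- card$payload[setdiff(names(card$payload), "concept")]
  out$extension <- list(`urn:dmp:card` = c(list(rule_id = card$rule_id,
                                                kind = card$kind), extra))
  out$suggestions <- list(sug)
  out
}

#' Invoke a decision-support service on a CDS Hooks request
#'
#' Validates the request shape (hook, context with `patientId`, prefetch),
#' parses the prefetch bundle into a patient dataset, runs the corresponding
#' library rule family, and returns a CDS Hooks response holding the cards.
#' A request with an empty or missing prefetch yields data-request cards,
#' never a failure.
#'
#' @param service_id one of the ids in [cds_discovery()]
#' @param request path, JSON string, or parsed request list
#' @param registry module registry supplying rule content
#' @param as_of evaluation date (a `context$asOf` in the request wins)
#' @return list shaped like a CDS Hooks cards response
#' @export
cds_invoke <- function(service_id, request, registry = builtin_defaults(),
                       as_of = Sys.Date()) {
  if (!service_id %in% CDS_SERVICES$id)
    stop("unknown service: ", service_id, " (not-found)")
  req <- parse_json_document(request)
  chk <- validate_hooks_request(req)
  if (!chk$valid)
    stop("invalid CDS Hooks request: ", paste(chk$problems, collapse = "; "))
  if (!is.null(req$context$asOf)) as_of <- as.Date(req$context$asOf)
  dataset <- NULL
  pf <- req$prefetch$patientBundle
  if (!is.null(pf) && length(pf$entry %||% list()) > 0L)
    dataset <- suppressWarnings(read_bundle(pf))
  if (is.null(dataset))
    return(list(cards = list(list(
      summary = "Patient record required",
      detail = "No patient data in prefetch: supply the patient bundle to evaluate this service",
      indicator = "info",
      source = list(label = "dmpkit")))))
  cards <- cds_service_cards(service_id, dataset, registry, as_of,
                             context = req$context)
  list(cards = lapply(cards, card_to_hooks_json))
}

# the single dispatch point shared by the service layer and by tests that
# compare service output against the library layer
cds_service_cards <- function(service_id, dataset, registry, as_of,
                              context = list()) {
  module_id <- context$moduleId %||% "hypertension"
  module <- registry$modules[[module_id]] %||% registry$modules[[1L]]
  track <- context$track %||% "monitoring"
  switch(service_id,
    "cvd-risk-score" = {
      sbp <- latest_observation(dataset, "sbp", as_of)$observation
      tchol <- latest_observation(dataset, "tchol", as_of)$observation
      age <- age_at(dataset$patient$birth_date, as_of)
      if (is.null(sbp) || is.null(tchol) || age < 30 || age > 90)
        return(required_lab_panel(dataset,
                                  restrict_validity(module, c("sbp", "tchol")), as_of))
      smoker <- isTRUE(context$smoker %||% FALSE)
      list(risk_score_card(cvd_risk_score(age, dataset$patient$sex, smoker,
                                          sbp$value, tchol$value)))
    },
    "diagnosis-recommendation" = recommend_diagnosis(list(), module, dataset, as_of),
    "lab-panel" = required_lab_panel(dataset, module, as_of),
    "lab-based-referral" = Filter(function(cd) cd$rule_id == "egfr_nephrology_referral",
                                  referral_advice(dataset, module, as_of, track)),
    "goal-recommendation" = recommend_goals(dataset, module, as_of,
                                            risk = context$riskCategory %||% NULL),
    "medication-advice" = medication_advice(dataset, module,
                                            unlist(context$candidateClasses %||% character()),
                                            as_of),
    "preventive-referral" = Filter(function(cd) cd$rule_id != "egfr_nephrology_referral",
                                   referral_advice(dataset, module, as_of, track)),
    "follow-up-interval" = list(follow_up_interval(module, track, as_of,
                                                   context$riskCategory %||% NA_character_)$card),
    "module-transition" = module_transition_check(dataset, module, as_of,
                                                  track = track))
}

restrict_validity <- function(module, keys) {
  module$validity_periods <- module$validity_periods[
    intersect(names(module$validity_periods), keys)]
  if (length(module$validity_periods) == 0L)
    module$validity_periods <- stats::setNames(as.list(rep(12, length(keys))), keys)
  module
}

#' Structural validation of a CDS Hooks request
#' @param request parsed request list
#' @return list with `valid` and `problems`
#' @export
validate_hooks_request <- function(request) {
  p <- character()
  if (!is.character(request$hook %||% NULL)) p <- c(p, "hook name required")
  if (!is.character(request$hookInstance %||% NULL)) p <- c(p, "hookInstance required")
  ctx <- request$context
  if (!is.list(ctx) || !is.character(ctx$patientId %||% NULL))
    p <- c(p, "context.patientId required")
  if (!is.null(request$prefetch) && !is.list(request$prefetch))
    p <- c(p, "prefetch must be an object")
  list(valid = length(p) == 0L, problems = p)
}

#' Structural validation of a CDS Hooks cards response
#'
#' Encodes the CDS Hooks card schema: a `cards` array in which every card
#' has a `summary` of at most 140 characters, an `indicator` from
#' info/warning/critical, and a `source` with a `label`; suggestions, when
#' present, must carry labels.
#'
#' @param response parsed response list (or JSON text/path)
#' @return list with `valid` and `problems`
#' @export
validate_hooks_response <- function(response) {
  resp <- parse_json_document(response)
  p <- character()
  if (!is.list(resp$cards)) p <- c(p, "cards array required")
  for (i in seq_along(resp$cards %||% list())) {
    cd <- resp$cards[[i]]
    if (!is.character(cd$summary %||% NULL) || nchar(cd$summary) > 140L)
      p <- c(p, sprintf("card[%d]: summary missing or over 140 characters", i))
    if (!is.character(cd$indicator %||% NULL) ||
        !cd$indicator %in% c("info", "warning", "critical"))
      p <- c(p, sprintf("card[%d]: indicator invalid", i))
    if (!is.list(cd$source) || !is.character(cd$source$label %||% NULL))
      p <- c(p, sprintf("card[%d]: source.label required", i))
    for (s in cd$suggestions %||% list())
      if (!is.character(s$label %||% NULL))
        p <- c(p, sprintf("card[%d]: suggestion without label", i))
  }
  list(valid = length(p) == 0L, problems = p)
}

#' Build a CDS Hooks request document for a patient
#'
#' Convenience for tests and the command line: wraps a dataset's bundle in a
#' request with the given context.
#'
#' @param dataset a `patient_dataset`
#' @param hook hook name
#' @param context extra context fields (patientId is filled automatically)
#' @return request list
#' @export
hooks_request <- function(dataset, hook = "patient-view", context = list()) {
  context$patientId <- dataset$patient$patient_id
  list(hook = hook,
       hookInstance = paste0("inst-", dataset$patient$patient_id),
       context = context,
       prefetch = list(patientBundle = write_bundle(dataset)))
}
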