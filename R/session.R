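# Encounter sessions: executing a module's page flow for one patient.
#
# Sessions are immutable values: submit_page and friends return an updated
# session, so replays and tests are trivially reproducible. A session walks
# the flow from its entry page; each submitted page evaluates its attached
# CDS rules and the flow's transition predicates (first match wins) until
# TERMINAL, after which complete_encounter assembles the care plan from the
# accepted cards plus the mandatory follow-up appointment.

#' Start a screening/monitoring encounter
#'
#' Verifies eligibility for the requested track (naming the violated
#' predicates otherwise) and opens a session at the flow's entry page with
#' every prefill-enabled parameter populated from the latest stored
#' observation, carrying its freshness flag so expired values are shown but
#' flagged for renewal.
#'
#' @param dataset a `patient_dataset`
#' @param module a [disease_module()]
#' @param registry the [module_registry()] holding the module's flow
#' @param track `"screening"` or `"monitoring"`
#' @param as_of encounter date
#' @param performer practitioner id recorded on the resulting encounter
#' @param risk_category optional current risk category
#' @return an `encounter_session`
#' @export
start_encounter <- function(dataset, module, registry,
                            track = c("screening", "monitoring"),
                            as_of, performer = NA_character_,
                            risk_category = NA_character_) {
  track <- match.arg(track)
  as_of <- as.Date(as_of)
  dec <- evaluate_eligibility(dataset, module, as_of, risk_category)
  if (!identical(dec$track, track))
    stop("patient not eligible for ", module$module_id, " ", track,
         " at ", as_iso_date(as_of), ":\n  ", paste(dec$reasons, collapse = "\n  "))
  flow <- registry$flows[[module$flow_ref]]
  if (is.null(flow)) stop("module flow '", module$flow_ref, "' not in registry")
  prefills <- list()
  for (pg in flow$pages) for (p in pg$required_parameters) {
    if (!isTRUE(p$prefill) || !is.null(prefills[[p$code]])) next
    validity <- p$validity_months %||% module$validity_periods[[p$code]]
    hit <- latest_observation(dataset, p$code, as_of, validity)
    if (!is.null(hit$observation))
      prefills[[p$code]] <- list(value = hit$observation$value,
                                 date = hit$observation$effective_date,
                                 origin = hit$observation$origin,
                                 freshness = hit$freshness)
  }
  structure(list(session_id = sprintf("%s-%s-%s", dataset$patient$patient_id,
                                      module$module_id, as_iso_date(as_of)),
                 patient_id = dataset$patient$patient_id,
                 dataset = dataset, module = module, registry = registry,
                 track = track, as_of = as_of, performer = performer,
                 risk_category = risk_category,
                 current_page = flow$entry_page,
                 visited_pages = character(),
                 entered_values = list(), prefills = prefills,
                 emitted_cards = list(), status = "in_progress"),
            class = "encounter_session")
}

#' @export
print.encounter_session <- function(x, ...) {
  cat(sprintf("Encounter session %s (%s %s, %s): page %s, %d cards\n",
              x$session_id, x$module$module_id, x$track, x$status,
              x$current_page, length(x$emitted_cards)))
  invisible(x)
}

session_flow <- function(session) session$registry$flows[[session$module$flow_ref]]

# values visible to transition predicates / page rules: entered first, then
# fresh-or-expired prefills (a physician-entered value always wins)
session_visible_values <- function(session) {
  vals <- lapply(session$prefills, `[[`, "value")
  for (k in names(session$entered_values)) vals[[k]] <- session$entered_values[[k]]$value
  vals
}

#' Submit the current page of a session
#'
#' `values` supplies the page's required parameters, as plain numerics (in
#' the catalogue unit) or `list(value=, unit=)` pairs; a mismatched unit is
#' an error, an unknown parameter a schema error. Parameters neither entered
#' nor prefilled may be deferred explicitly via `defer`. Entered values are
#' timestamped with the session date and origin `encounter_entry`. The
#' page's attached CDS rules are then evaluated (appending cards) and the
#' first matching transition decides the next page.
#'
#' @param session an in-progress `encounter_session`
#' @param values named list of entered values
#' @param defer character vector of parameter keys explicitly left blank
#' @return updated session; `session$current_page` is `"TERMINAL"` once the
#'   flow exits, and `attr(,"new_cards")` holds the cards this submission
#'   emitted
#' @export
submit_page <- function(session, values = list(), defer = character()) {
  if (session$status != "in_progress") stop("session is not in progress")
  flow <- session_flow(session)
  page <- flow$pages[[session$current_page]]
  if (is.null(page)) stop("session is at an unknown page: ", session$current_page)
  catalog_keys <- param_catalog()$key
  for (k in names(values)) {
    if (!k %in% catalog_keys) stop("unknown parameter: ", k)
    v <- values[[k]]
    if (is.list(v)) {
      if (!is.null(v$unit) && v$unit != param_unit(k))
        stop("unit mismatch for ", k, ": got '", v$unit, "', expected '", param_unit(k), "'")
      v <- v$value
    }
    if (!is.numeric(v) || !is.finite(v)) stop("non-finite value for ", k)
    session$entered_values[[k]] <- list(value = as.numeric(v),
                                        date = session$as_of,
                                        origin = "encounter_entry")
  }
  required <- vapply(page$required_parameters, `[[`, "", "code")
  covered <- union(names(session$entered_values), names(session$prefills))
  missing <- setdiff(required, union(covered, defer))
  if (length(missing))
    stop("page '", page$page_id, "' requires: ", paste(missing, collapse = ", "),
         " (enter or defer explicitly)")
  # page-attached CDS rules
  new_cards <- list()
  vis <- session_visible_values(session)
  for (rid in page$cds_rules) {
    rule <- find_rule(session$module, rid)
    if (is.null(rule)) next
    new_cards <- c(new_cards, evaluate_page_rule(rule, session, vis))
  }
  session$emitted_cards <- c(session$emitted_cards, new_cards)
  session$visited_pages <- c(session$visited_pages, page$page_id)
  # first-match transition
  nxt <- NULL
  for (tr in flow$transitions) {
    if (tr$from != page$page_id) next
    ok <- is.null(tr$predicate) ||
      eval_predicate(tr$predicate,
                     predicate_context(session$dataset, session$as_of,
                                       session$risk_category, vis))
    if (ok) { nxt <- tr$to; break }
  }
  if (is.null(nxt)) stop("no transition matched from page '", page$page_id, "'")
  session$current_page <- nxt
  attr(session, "new_cards") <- new_cards
  session
}

find_rule <- function(module, id) {
  for (r in module$cds_rules) if (identical(r$id, id)) return(r)
  NULL
}

evaluate_page_rule <- function(rule, session, visible_values) {
  switch(rule$family,
    diagnosis = recommend_diagnosis(visible_values, rule_module_subset(session$module, rule),
                                    session$dataset, session$as_of),
    module_transition = {
      cards <- module_transition_check(session$dataset, session$module,
                                       session$as_of, visible_values,
                                       session$track)
      Filter(function(cd) cd$rule_id == rule$id, cards)
    },
    preventive_referral = Filter(function(cd) cd$rule_id == rule$id,
                                 referral_advice(session$dataset, session$module,
                                                 session$as_of, session$track)),
    list())
}

# narrow a module to one rule so family evaluators emit only that rule's cards
rule_module_subset <- function(module, rule) {
  module$cds_rules <- list(rule)
  module
}

#' Accept or reject emitted cards
#'
#' The physician always reviews decision-support output: only accepted cards
#' flow into the care plan, and overridden goals are recorded as
#' `physician_override` downstream.
#'
#' @param session an `encounter_session`
#' @param rule_ids ids of cards to mark
#' @param status `"accepted"` or `"rejected"`
#' @return updated session
#' @export
review_cards <- function(session, rule_ids, status = c("accepted", "rejected")) {
  status <- match.arg(status)
  session$emitted_cards <- lapply(session$emitted_cards, function(cd) {
    if (cd$rule_id %in% rule_ids) cd$accepted <- status
    cd
  })
  session
}

#' Complete an encounter session
#'
#' Requires the flow to have reached TERMINAL. Assembles the care plan from
#' the accepted cards — goals from goal cards, referral / lab-order /
#' lifestyle activities from their cards — plus the mandatory follow-up
#' appointment dated by the module's interval rule; records the encounter;
#' writes the entered values into the dataset as `encounter_entry`
#' observations; and recomputes the schedule of every module affected by an
#' accepted transition prompt.
#'
#' @param session a session whose `current_page` is `"TERMINAL"`
#' @param accept_pending treat still-pending cards as accepted (convenient
#'   for non-interactive replays)
#' @param duration_minutes encounter duration to record
#' @return list with `care_plan`, `encounter`, `dataset` (updated),
#'   `schedule_updates` (per-module [next_due()] results after the
#'   encounter), `transition_prompts` (accepted prompts) and `session`
#'   (status `"completed"`)
#' @export
complete_encounter <- function(session, accept_pending = TRUE,
                               duration_minutes = 1.1) {
  if (session$status != "in_progress") stop("session already ", session$status)
  if (!identical(session$current_page, "TERMINAL"))
    stop("session has not reached TERMINAL (at page '", session$current_page, "')")
  cards <- session$emitted_cards
  if (accept_pending)
    cards <- lapply(cards, function(cd) {
      if (cd$accepted == "pending") cd$accepted <- "accepted"
      cd
    })
  accepted <- Filter(function(cd) cd$accepted == "accepted", cards)

  enc <- encounter_record(session$module$module_id, session$track,
                          session$as_of, session$performer, duration_minutes)
  enc_ref <- sprintf("%s-%s", session$module$module_id, as_iso_date(session$as_of))

  goals <- lapply(Filter(function(cd) cd$kind == "goal_suggestion", accepted),
                  goal_card_to_record)
  activities <- list()
  for (cd in accepted) {
    act <- switch(cd$kind,
      referral_suggestion = care_plan_activity("referral", cd$payload$concept, cd$rationale),
      lab_order = care_plan_activity("lab_order", cd$payload$concept, cd$rationale),
      medication_suggestion = care_plan_activity("medication_order", cd$payload$concept, cd$rationale),
      NULL)
    if (!is.null(act)) activities[[length(activities) + 1L]] <- act
  }
  fu <- follow_up_interval(session$module, session$track, session$as_of,
                           session$risk_category)
  activities[[length(activities) + 1L]] <- care_plan_activity(
    "follow_up_appointment",
    coded_concept(SYS_MODULE, session$module$module_id,
                  paste(session$module$module_id, session$track, "follow-up")),
    fu$card$rationale, due_date = as.Date(fu$card$payload$due_date))

  plan <- care_plan_record(session$patient_id, enc_ref, goals, activities)

  ds <- session$dataset
  for (k in names(session$entered_values)) {
    ev <- session$entered_values[[k]]
    ds$observations[[length(ds$observations) + 1L]] <-
      clinical_observation(k, ev$value, effective_date = ev$date,
                           origin = "encounter_entry")
  }
  ds$encounters[[length(ds$encounters) + 1L]] <- enc
  ds$goals <- c(ds$goals, goals)
  ds$care_plans[[length(ds$care_plans) + 1L]] <- plan

  # schedules affected: this module plus any accepted transition-prompt target
  prompts <- Filter(function(cd) cd$kind == "module_transition_prompt", accepted)
  affected <- unique(c(session$module$module_id,
                       vapply(prompts, function(cd) cd$payload$concept$code, "")))
  schedule_updates <- list()
  for (mid in affected) {
    m <- session$registry$modules[[mid]]
    if (is.null(m)) next
    schedule_updates[[mid]] <- next_due(ds, m, session$as_of, session$risk_category)
  }

  session$status <- "completed"
  session$emitted_cards <- cards
  list(care_plan = plan, encounter = enc, dataset = ds,
       schedule_updates = schedule_updates, transition_prompts = prompts,
       session = session)
}

#' Run a scripted (non-interactive) encounter
#'
#' Drives a session page by page, on each page supplying whichever of the
#' scripted `answers` the page requires (entries the page does not ask for
#' are ignored; required parameters with no scripted answer and no prefill
#' are deferred). Used for replay from the command line and for bulk
#' simulation.
#'
#' @inheritParams start_encounter
#' @param answers named list key -> numeric of scripted entries
#' @return the [complete_encounter()] result
#' @export
run_encounter <- function(dataset, module, registry, track, as_of,
                          answers = list(), performer = NA_character_,
                          risk_category = NA_character_) {
  session <- start_encounter(dataset, module, registry, track, as_of,
                             performer, risk_category)
  flow <- session_flow(session)
  steps <- 0L
  while (session$current_page != "TERMINAL") {
    page <- flow$pages[[session$current_page]]
    req <- vapply(page$required_parameters, `[[`, "", "code")
    supplied <- answers[intersect(req, names(answers))]
    deferred <- setdiff(req, union(names(supplied), names(session$prefills)))
    session <- submit_page(session, supplied, defer = deferred)
    steps <- steps + 1L
    if (steps > length(flow$pages))
      stop("flow did not terminate within ", length(flow$pages), " steps")
  }
  complete_encounter(session)
}
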