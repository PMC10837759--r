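# Page flows: the state machines behind screening/monitoring encounters.
#
# National care pathways decompose into common steps (physical examination,
# history review, lab review, diagnosis, goal setting, treatment planning,
# ...). A flow is a set of pages — one per step — plus an ordered transition
# list: from a page, the first transition whose predicate holds (evaluated
# over the values entered so far) decides the next page; every page must end
# with an unconditional catch-all so execution is total and deterministic.
# TERMINAL is the single exit.

PAGE_STEP_KINDS <- c("physical_examination", "medical_history", "risk_assessment",
                     "medication_review", "lab_review", "diagnosis", "goal_setting",
                     "pharmacological_plan", "nonpharmacological_plan",
                     "scaled_assessment")

#' Page definition
#' @param page_id unique page id within its flow
#' @param step_kind one of the common care-pathway step kinds
#' @param required_parameters list of `list(code, validity_months, prefill)`
#'   entries naming the parameters collected on the page
#' @param cds_rules ids of module CDS rules evaluated when the page is
#'   submitted
#' @export
page_def <- function(page_id, step_kind, required_parameters = list(),
                     cds_rules = character()) {
  step_kind <- match.arg(step_kind, PAGE_STEP_KINDS)
  required_parameters <- lapply(required_parameters, function(p) {
    if (is.character(p)) p <- list(code = p)
    list(code = p$code,
         validity_months = if (is.null(p$validity_months)) NULL else as.numeric(p$validity_months),
         prefill = isTRUE(p$prefill %||% TRUE))
  })
  structure(list(page_id = page_id, step_kind = step_kind,
                 required_parameters = required_parameters,
                 cds_rules = as.character(cds_rules)),
            class = "page_def")
}

#' Page flow
#' @param flow_id flow identifier
#' @param entry_page id of the first page
#' @param pages list of [page_def()]s
#' @param transitions ordered list of `list(from, predicate, to)`; `predicate
#'   = NULL` means always; `to = "TERMINAL"` exits the flow
#' @export
page_flow <- function(flow_id, entry_page, pages, transitions) {
  names(pages) <- vapply(pages, `[[`, "", "page_id")
  transitions <- lapply(transitions, function(tr)
    list(from = tr$from,
         predicate = if (is.null(tr$predicate)) NULL else as_predicate(tr$predicate),
         to = tr$to))
  structure(list(flow_id = flow_id, entry_page = entry_page,
                 pages = pages, transitions = transitions),
            class = "page_flow")
}

flow_params <- function(flow) {
  unique(unlist(lapply(flow$pages, function(pg)
    vapply(pg$required_parameters, `[[`, "", "code")), use.names = FALSE))
}

#' Validate a page flow
#'
#' Reports: unreachable pages; cycles (which would allow non-terminating
#' paths); pages without a final unconditional transition; transitions from
#' or to unknown pages; transition predicates referencing parameters no page
#' declares.
#'
#' @param flow a [page_flow()]
#' @return list with `valid` and `problems`
#' @export
validate_flow <- function(flow) {
  p <- character()
  ids <- names(flow$pages)
  if (!flow$entry_page %in% ids)
    p <- c(p, sprintf("entry page '%s' not defined", flow$entry_page))
  froms <- vapply(flow$transitions, `[[`, "", "from")
  tos <- vapply(flow$transitions, `[[`, "", "to")
  for (i in seq_along(flow$transitions)) {
    if (!froms[i] %in% ids) p <- c(p, sprintf("transition %d from unknown page '%s'", i, froms[i]))
    if (!tos[i] %in% c(ids, "TERMINAL")) p <- c(p, sprintf("transition %d to unknown page '%s'", i, tos[i]))
  }
  # every page needs an unconditional catch-all as its last transition
  for (id in ids) {
    mine <- which(froms == id)
    if (length(mine) == 0L) { p <- c(p, sprintf("page '%s' has no outgoing transition", id)); next }
    last <- flow$transitions[[mine[length(mine)]]]
    if (!is.null(last$predicate) && !identical(last$predicate$atom, "always"))
      p <- c(p, sprintf("page '%s' lacks a final catch-all transition", id))
  }
  # reachability from entry
  if (flow$entry_page %in% ids) {
    seen <- flow$entry_page
    frontier <- seen
    while (length(frontier)) {
      nxt <- unique(tos[froms %in% frontier])
      nxt <- setdiff(intersect(nxt, ids), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    unreachable <- setdiff(ids, seen)
    if (length(unreachable))
      p <- c(p, sprintf("unreachable page(s): %s", paste(unreachable, collapse = ", ")))
  }
  # cycle detection on the page graph: cycles permit non-terminating paths
  edges <- unique(data.frame(from = froms, to = tos, stringsAsFactors = FALSE))
  edges <- edges[edges$to != "TERMINAL", , drop = FALSE]
  remaining <- ids
  repeat {
    # a page is removable when all its outgoing edges leave the remaining set
    removable <- remaining[vapply(remaining, function(id)
      !any(edges$from == id & edges$to %in% remaining), TRUE)]
    if (length(removable) == 0L) break
    remaining <- setdiff(remaining, removable)
  }
  if (length(remaining))
    p <- c(p, sprintf("cycle among pages: %s (non-terminating paths possible)",
                      paste(sort(remaining), collapse = ", ")))
  # transition predicates may only reference declared parameters
  declared <- flow_params(flow)
  for (i in seq_along(flow$transitions)) {
    pr <- flow$transitions[[i]]$predicate
    if (is.null(pr)) next
    refs <- predicate_obs_refs(pr)
    undeclared <- setdiff(refs, declared)
    if (length(undeclared))
      p <- c(p, sprintf("transition %d references undeclared parameter(s): %s",
                        i, paste(undeclared, collapse = ", ")))
    p <- c(p, validate_predicate(pr, sprintf("transition %d", i)))
  }
  list(valid = length(p) == 0L, problems = p)
}

predicate_obs_refs <- function(pred) {
  pred <- as_predicate(pred)
  if (!is.null(pred$all)) return(unique(unlist(lapply(pred$all, predicate_obs_refs))))
  if (!is.null(pred$any)) return(unique(unlist(lapply(pred$any, predicate_obs_refs))))
  if (!is.null(pred$not)) return(predicate_obs_refs(pred$not))
  if (identical(pred$atom, "observation_cmp")) return(pred$code)
  character()
}

flow_to_list <- function(flow) {
  list(flow_id = flow$flow_id, entry_page = flow$entry_page,
       pages = lapply(unname(flow$pages), function(pg)
         list(page_id = pg$page_id, step_kind = pg$step_kind,
              required_parameters = pg$required_parameters,
              cds_rules = as.list(pg$cds_rules))),
       transitions = lapply(flow$transitions, function(tr)
         list(from = tr$from,
              predicate = if (is.null(tr$predicate)) NULL else predicate_to_list(tr$predicate),
              to = tr$to)))
}

flow_from_list <- function(x) {
  page_flow(x$flow_id, x$entry_page,
            lapply(x$pages, function(pg)
              page_def(pg$page_id, pg$step_kind, pg$required_parameters %||% list(),
                       unlist(pg$cds_rules %||% list()) %||% character())),
            lapply(x$transitions, function(tr)
              list(from = tr$from,
                   predicate = if (is.null(tr$predicate)) NULL else predicate_from_list(tr$predicate),
                   to = tr$to)))
}

#' Built-in page flows
#'
#' The flows behind the five default modules. The hypertension screening
#' flow is the most structured: an examination page with office blood
#' pressure, a confirmation measurement when the first reading is elevated,
#' a lab-review page whose fasting-glucose check can prompt a diabetes
#' screening, a diagnosis step reached only on confirmed elevation, then
#' goal setting and lifestyle planning. Only elements the pathway
#' documentation guarantees are encoded; page ordering beyond that is
#' illustrative configuration.
#'
#' @return named list of [page_flow()]s
#' @export
builtin_flows <- function() {
  elevated_bp <- p_any(p_observation("sbp", ">=", 140), p_observation("dbp", ">=", 90))
  hypertension_screening <- page_flow(
    "hypertension_screening", "exam",
    pages = list(
      page_def("exam", "physical_examination",
               list(list(code = "sbp", validity_months = 6),
                    list(code = "dbp", validity_months = 6),
                    list(code = "bmi", validity_months = 12))),
      page_def("bp_confirm", "physical_examination",
               list(list(code = "sbp", validity_months = 6, prefill = FALSE),
                    list(code = "dbp", validity_months = 6, prefill = FALSE)),
               cds_rules = "htn_confirmed_bp_dx"),
      page_def("labs", "lab_review",
               list(list(code = "fpg", validity_months = 12)),
               cds_rules = "fpg_diabetes_prompt"),
      page_def("dx", "diagnosis"),
      page_def("goals", "goal_setting"),
      page_def("lifestyle", "nonpharmacological_plan")),
    transitions = list(
      list(from = "exam", predicate = elevated_bp, to = "bp_confirm"),
      list(from = "exam", predicate = NULL, to = "labs"),
      list(from = "bp_confirm", predicate = NULL, to = "labs"),
      list(from = "labs", predicate = elevated_bp, to = "dx"),
      list(from = "labs", predicate = NULL, to = "lifestyle"),
      list(from = "dx", predicate = NULL, to = "goals"),
      list(from = "goals", predicate = NULL, to = "lifestyle"),
      list(from = "lifestyle", predicate = NULL, to = "TERMINAL")))

  diabetes_flow <- page_flow(
    "diabetes_flow", "history",
    pages = list(
      page_def("history", "medical_history"),
      page_def("labs", "lab_review",
               list(list(code = "fpg", validity_months = 12),
                    list(code = "hba1c", validity_months = 6)),
               cds_rules = "dm_fpg_dx"),
      page_def("dx", "diagnosis"),
      page_def("goals", "goal_setting"),
      page_def("plan", "nonpharmacological_plan")),
    transitions = list(
      list(from = "history", predicate = NULL, to = "labs"),
      list(from = "labs", predicate = p_observation("fpg", ">=", 126), to = "dx"),
      list(from = "labs", predicate = NULL, to = "goals"),
      list(from = "dx", predicate = NULL, to = "goals"),
      list(from = "goals", predicate = NULL, to = "plan"),
      list(from = "plan", predicate = NULL, to = "TERMINAL")))

  cvd_risk_flow <- page_flow(
    "cvd_risk_flow", "risk",
    pages = list(
      page_def("risk", "risk_assessment",
               list(list(code = "sbp", validity_months = 6),
                    list(code = "tchol", validity_months = 12))),
      page_def("goals", "goal_setting"),
      page_def("plan", "nonpharmacological_plan")),
    transitions = list(
      list(from = "risk", predicate = NULL, to = "goals"),
      list(from = "goals", predicate = NULL, to = "plan"),
      list(from = "plan", predicate = NULL, to = "TERMINAL")))

  obesity_flow <- page_flow(
    "obesity_flow", "exam",
    pages = list(
      page_def("exam", "physical_examination",
               list(list(code = "bmi", validity_months = 12),
                    list(code = "weight", validity_months = 12),
                    list(code = "waist", validity_months = 12)),
               cds_rules = "ob_bmi_dx"),
      page_def("dx", "diagnosis"),
      page_def("plan", "nonpharmacological_plan")),
    transitions = list(
      list(from = "exam", predicate = p_observation("bmi", ">=", 30), to = "dx"),
      list(from = "exam", predicate = NULL, to = "plan"),
      list(from = "dx", predicate = NULL, to = "plan"),
      list(from = "plan", predicate = NULL, to = "TERMINAL")))

  older_adult_flow <- page_flow(
    "older_adult_flow", "assessment",
    pages = list(
      page_def("assessment", "scaled_assessment",
               list(list(code = "weight", validity_months = 12),
                    list(code = "bmi", validity_months = 12))),
      page_def("meds", "medication_review"),
      page_def("plan", "nonpharmacological_plan")),
    transitions = list(
      list(from = "assessment", predicate = NULL, to = "meds"),
      list(from = "meds", predicate = NULL, to = "plan"),
      list(from = "plan", predicate = NULL, to = "TERMINAL")))

  list(hypertension_screening = hypertension_screening,
       diabetes_flow = diabetes_flow,
       cvd_risk_flow = cvd_risk_flow,
       obesity_flow = obesity_flow,
       older_adult_flow = older_adult_flow)
}
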