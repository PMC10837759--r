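# Eligibility and scheduling: which track a patient is on for each disease
# module, when the next encounter is due, and module-level target lists.

#' Evaluate a patient's track for a disease module
#'
#' Monitoring takes precedence over screening: a diagnosed patient is never
#' re-screened for the same disease. The decision carries a reason line for
#' every predicate evaluated, so target-list membership is explainable.
#'
#' @param dataset a `patient_dataset`
#' @param module a [disease_module()]
#' @param as_of reference date
#' @param risk_category current risk category (needed by risk-keyed atoms)
#' @return list with `module_id`, `track` (`"screening"`, `"monitoring"`,
#'   `"none"`) and `reasons`
#' @export
evaluate_eligibility <- function(dataset, module, as_of, risk_category = NA_character_) {
  ctx <- predicate_context(dataset, as_of, risk_category)
  mon <- eval_predicate(module$monitoring_eligibility, ctx)
  scr <- eval_predicate(module$screening_eligibility, ctx)
  track <- if (mon) "monitoring" else if (scr) "screening" else "none"
  reasons <- c(
    sprintf("monitoring %s: %s", if (mon) "satisfied" else "not satisfied",
            describe_predicate(module$monitoring_eligibility)),
    sprintf("screening %s: %s", if (scr) "satisfied" else "not satisfied",
            describe_predicate(module$screening_eligibility)))
  list(module_id = module$module_id, track = track, reasons = reasons)
}

#' Next-due schedule status for a module
#'
#' The due date is the date of the last completed encounter of the decided
#' track plus the applicable recall interval (risk-keyed intervals fall back
#' to the default when the risk category is unknown). A patient with no
#' prior encounter of the track is due immediately. A patient is `due_now`
#' on the due date itself and `overdue` strictly after it.
#'
#' @inheritParams evaluate_eligibility
#' @return list with `module_id`, `track`, `due_date` (or `NA`) and
#'   `status` (`due_now`, `overdue`, `up_to_date`, `not_eligible`)
#' @export
next_due <- function(dataset, module, as_of, risk_category = NA_character_) {
  as_of <- as.Date(as_of)
  dec <- evaluate_eligibility(dataset, module, as_of, risk_category)
  if (dec$track == "none")
    return(list(module_id = module$module_id, track = "none",
                due_date = as.Date(NA), status = "not_eligible"))
  prior <- Filter(function(e) e$module_id == module$module_id &&
                    e$encounter_type == dec$track && e$date <= as_of,
                  dataset$encounters)
  if (length(prior) == 0L)
    return(list(module_id = module$module_id, track = dec$track,
                due_date = as.Date(NA), status = "due_now"))
  last_date <- max(as.Date(vapply(prior, function(e) as.character(e$date), "")))
  rule <- if (dec$track == "screening") module$screening_interval else module$monitoring_interval
  due <- add_months(last_date, resolve_interval(rule, risk_category))
  status <- if (as_of < due) "up_to_date" else if (as_of == due) "due_now" else "overdue"
  list(module_id = module$module_id, track = dec$track, due_date = due, status = status)
}

#' Build per-module target population lists
#'
#' Evaluates every patient against every registered module and returns, per
#' (module, track), the eligible patients with their schedule status, sorted
#' overdue first, then by ascending due date (patients never seen, with no
#' due date, come before dated entries within their status), then by patient
#' id for determinism.
#'
#' @param population list of `patient_dataset`s
#' @param registry a validated [module_registry()]
#' @param as_of reference date
#' @param risk_categories optional named character vector patient_id -> risk
#'   category
#' @return named list `"module/track"` -> data.frame(patient_id, due_date,
#'   status)
#' @export
build_target_lists <- function(population, registry, as_of,
                               risk_categories = character()) {
  as_of <- as.Date(as_of)
  rows <- list()
  for (ds in population) {
    pid <- ds$patient$patient_id
    risk <- if (pid %in% names(risk_categories)) risk_categories[[pid]] else NA_character_
    for (m in registry$modules) {
      st <- next_due(ds, m, as_of, risk)
      if (st$track == "none") next
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, module = m$module_id, track = st$track,
        due_date = st$due_date, status = st$status, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(structure(list(), names = character()))
  df <- do.call(rbind, rows)
  out <- list()
  for (key in sort(unique(paste(df$module, df$track, sep = "/")))) {
    part <- df[paste(df$module, df$track, sep = "/") == key, , drop = FALSE]
    status_rank <- match(part$status, c("overdue", "due_now", "up_to_date"))
    # within a status, undated (never seen) entries sort before dated ones
    out[[key]] <- part[order(status_rank,
                             ifelse(is.na(part$due_date), -Inf, as.numeric(part$due_date)),
                             part$patient_id), , drop = FALSE]
    rownames(out[[key]]) <- NULL
  }
  out
}
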