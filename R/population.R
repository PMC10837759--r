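# Population tracking: coverage, achievement, encounter and goal statistics.
#
# All published platform tables use one rounding convention — percentages
# rounded half-up to 1 decimal, the per-patient encounter mean to 2 — and
# every aggregate rate is recomputed from summed counts, never from averaged
# percentages. The count-level functions below therefore reproduce each
# printed table value exactly from its printed counts, and the log-level
# functions build those counts from raw encounter logs.

#' Round half-up
#'
#' Decimal rounding where ties go away from zero (so 0.25 to 1 decimal is
#' 0.3), unlike R's banker's rounding. A tiny guard absorbs binary
#' floating-point noise on exact-looking decimals.
#'
#' @param x numeric
#' @param digits decimal places
#' @export
round_half_up <- function(x, digits = 0) {
  scaled <- round(x * 10^digits, 9)  # strip representation noise first
  sign(x) * floor(abs(scaled) + 0.5) / 10^digits
}

#' Percentage with the platform rounding convention
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places. A
#' zero denominator is an undefined rate and yields `NA` (rendered as
#' absent, never as 0).
#'
#' @param numerator,denominator counts
#' @param decimals decimal places (default 1, the convention for all rates)
#' @return numeric percent, or `NA_real_` when undefined
#' @export
percent <- function(numerator, denominator, decimals = 1) {
  out <- round_half_up(100 * numerator / denominator, decimals)
  den <- rep_len(denominator, length(out))
  out[!is.na(den) & den <= 0] <- NA_real_
  out
}

#' Coverage from counts
#'
#' @param counts data.frame with columns `module`, `track`, `target_count`,
#'   `covered_count`
#' @return the same frame with `coverage_percent` appended
#' @export
coverage_table <- function(counts) {
  counts$coverage_percent <- percent(counts$covered_count, counts$target_count)
  counts
}

#' Coverage of target populations from an encounter log
#'
#' Covered = unique patients with at least one encounter of the (module,
#' track); the denominators are the target-list sizes. A patient appearing
#' in both tracks of a module over time counts in each track separately.
#'
#' @param target_lists output of [build_target_lists()] (or any named list
#'   `"module/track"` -> data.frame with a `patient_id` column)
#' @param encounter_log data.frame with columns `patient_id`, `module`,
#'   `track`, `date`
#' @return data.frame(module, track, target_count, covered_count,
#'   coverage_percent)
#' @export
coverage <- function(target_lists, encounter_log) {
  rows <- lapply(names(target_lists), function(key) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1L]]
    targets <- target_lists[[key]]$patient_id
    covered <- unique(encounter_log$patient_id[
      encounter_log$module == parts[1L] & encounter_log$track == parts[2L] &
        encounter_log$patient_id %in% targets])
    data.frame(module = parts[1L], track = parts[2L],
               target_count = length(targets), covered_count = length(covered),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(module = character(), track = character(),
                      target_count = integer(), covered_count = integer(),
                      coverage_percent = numeric()))
  coverage_table(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Monthly achievement rates
#'
#' Performed = encounters in the month per (module, track); rates are
#' per-row percentages and the overall rate recombines the *summed* counts
#' (never the averaged percentages).
#'
#' @param monthly_targets data.frame(module, track, target)
#' @param encounter_log data.frame with `module`, `track`, `date`
#' @param month month as `"YYYY-MM"`
#' @return list with `table` (targets + performed + achievement_percent) and
#'   `overall` (percent from summed counts)
#' @export
achievement <- function(monthly_targets, encounter_log, month) {
  in_month <- format(as.Date(encounter_log$date), "%Y-%m") == month
  performed <- integer(nrow(monthly_targets))
  for (i in seq_len(nrow(monthly_targets)))
    performed[i] <- sum(in_month &
                          encounter_log$module == monthly_targets$module[i] &
                          encounter_log$track == monthly_targets$track[i])
  monthly_targets$performed <- performed
  achievement_from_counts(monthly_targets)
}

#' Achievement rates from counts
#' @param counts data.frame(module, track, target, performed)
#' @return list with `table` and `overall`
#' @export
achievement_from_counts <- function(counts) {
  counts$achievement_percent <- percent(counts$performed, counts$target)
  list(table = counts,
       overall = percent(sum(counts$performed), sum(counts$target)))
}

#' Encounter summary from counts
#'
#' Per-module screening/monitoring/total counts with their shares of each
#' column total, plus the mean number of encounters per unique patient
#' (half-up, 2 decimals).
#'
#' @param counts data.frame(module, screening, monitoring) of encounter
#'   counts (`NA` where a module has no track)
#' @param unique_patients unique patient count for the mean (optional)
#' @return list with `table` (counts + `*_share` columns), `totals`, and
#'   `mean_encounters_per_patient` (or `NA` when no patient count given)
#' @export
encounter_summary_from_counts <- function(counts, unique_patients = NA) {
  counts$total <- rowSums(counts[, c("screening", "monitoring")], na.rm = TRUE)
  tot_s <- sum(counts$screening, na.rm = TRUE)
  tot_m <- sum(counts$monitoring, na.rm = TRUE)
  tot <- sum(counts$total)
  counts$screening_share <- percent(counts$screening, tot_s)
  counts$monitoring_share <- percent(counts$monitoring, tot_m)
  counts$total_share <- percent(counts$total, tot)
  mean_pp <- if (is.na(unique_patients) || unique_patients == 0) NA_real_
             else round_half_up(tot / unique_patients, 2)
  list(table = counts,
       totals = c(screening = tot_s, monitoring = tot_m, total = tot),
       mean_encounters_per_patient = mean_pp)
}

#' Encounter summary from a log
#'
#' @param encounter_log data.frame with `patient_id`, `module`, `track`
#' @return as [encounter_summary_from_counts()], plus `unique_patients` and
#'   `sex_shares` when the log carries a `sex` column
#' @export
encounter_summary <- function(encounter_log) {
  if (nrow(encounter_log) == 0L)
    return(list(table = data.frame(), totals = c(screening = 0, monitoring = 0, total = 0),
                mean_encounters_per_patient = NA_real_, unique_patients = 0L))
  mods <- sort(unique(encounter_log$module))
  counts <- data.frame(module = mods,
                       screening = vapply(mods, function(m)
                         sum(encounter_log$module == m & encounter_log$track == "screening"), 0),
                       monitoring = vapply(mods, function(m)
                         sum(encounter_log$module == m & encounter_log$track == "monitoring"), 0),
                       stringsAsFactors = FALSE, row.names = NULL)
  uniq <- length(unique(encounter_log$patient_id))
  out <- encounter_summary_from_counts(counts, uniq)
  out$unique_patients <- uniq
  if ("sex" %in% names(encounter_log)) {
    first <- encounter_log[!duplicated(encounter_log$patient_id), ]
    out$sex_shares <- c(female = percent(sum(first$sex == "female"), uniq),
                        male = percent(sum(first$sex == "male"), uniq))
  }
  out
}

#' Treatment-goal achievement rates
#'
#' A goal is *assessed* when an observation of its parameter dated after the
#' goal was set (and not after `as_of`) exists — i.e. the parameter was
#' re-measured at a subsequent encounter; goals never reassessed stay out of
#' the denominator. An assessed goal is *achieved* when the latest such
#' observation satisfies the goal comparator against the target.
#'
#' @param population list of `patient_dataset`s (goals are read from each
#'   dataset)
#' @param as_of reference date
#' @return data.frame(parameter, assessed, achieved, achievement_percent)
#'   with one row per goal parameter, sorted by parameter key
#' @export
goal_achievement <- function(population, as_of) {
  as_of <- as.Date(as_of)
  assessed <- list(); achieved <- list()
  bump <- function(env, key) { env[[key]] <- (env[[key]] %||% 0L) + 1L; env }
  for (ds in population) {
    for (g in ds$goals) {
      if (g$set_date > as_of) next
      key <- param_key_for(g$parameter$system, g$parameter$code)
      if (is.na(key)) key <- g$parameter$code
      later <- Filter(function(o) o$code$system == g$parameter$system &&
                        o$code$code == g$parameter$code &&
                        o$effective_date > g$set_date &&
                        o$effective_date <= as_of, ds$observations)
      if (length(later) == 0L) next
      dates <- as.Date(vapply(later, function(o) as.character(o$effective_date), ""))
      obs <- later[[which.max(as.integer(dates))]]
      assessed <- bump(assessed, key)
      op <- c(le = "<=", ge = ">=", lt = "<", gt = ">")[[g$comparator]]
      if (cmp(obs$value, op, g$target_value)) achieved <- bump(achieved, key)
    }
  }
  params <- sort(names(assessed))
  data.frame(parameter = params,
             assessed = vapply(params, function(k) assessed[[k]], 0L),
             achieved = vapply(params, function(k) achieved[[k]] %||% 0L, 0L),
             achievement_percent = vapply(params, function(k)
               percent(achieved[[k]] %||% 0L, assessed[[k]]), 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Practitioner panel view
#'
#' Restricts the global target lists to one practitioner's panel and flags
#' the practitioner exempt when the panel exceeds 4000 citizens (heavy
#' workload exemption). An unknown practitioner id yields empty lists with a
#' notice.
#'
#' @param fmp_id practitioner identifier
#' @param population list of `patient_dataset`s
#' @param registry a [module_registry()]
#' @param as_of reference date
#' @return list with `panel_size`, `exempt`, `lists` (as
#'   [build_target_lists()], panel-restricted) and `notice`
#' @export
panel_view <- function(fmp_id, population, registry, as_of) {
  panel <- Filter(function(ds) identical(ds$patient$assigned_fmp, fmp_id), population)
  if (length(panel) == 0L)
    return(list(panel_size = 0L, exempt = FALSE, lists = list(),
                notice = sprintf("no patients assigned to practitioner '%s'", fmp_id)))
  list(panel_size = length(panel),
       exempt = length(panel) > 4000L,
       lists = build_target_lists(panel, registry, as_of),
       notice = NULL)
}
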