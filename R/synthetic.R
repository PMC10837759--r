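# Seeded synthetic primary-care cohorts.
#
# The generator emulates what a national EHR sync would deliver for a
# primary-care panel: demographics with a middle-aged concentration, chronic
# diagnoses assigned by age-banded prevalence, medication classes given
# diagnosis, and longitudinal observations with truncated-normal noise whose
# means shift with disease status. Everything is driven by R's Mersenne-
# Twister stream from a single integer seed, so identical configurations
# regenerate byte-identical cohorts on any platform.

#' Cohort generator configuration
#'
#' Defaults define the study conditions used throughout the package's tests:
#' sex ratio 56.2 percent female (matching the platform's reported user
#' population), ages normal(52, 16) truncated to 18–95, age-banded
#' prevalence for hypertension / diabetes / obesity, treatment probability
#' 0.85 (antihypertensive) and 0.8 (antidiabetic) given diagnosis, two
#' observation waves in the 24 months before the reference date, and recall
#' adherence 0.7.
#'
#' @param n cohort size (> 0)
#' @param seed integer seed; all randomness flows from it
#' @param as_of cohort reference date
#' @param female_share probability a patient is female
#' @param age_mean,age_sd,age_min,age_max truncated-normal age distribution
#' @param prevalence named list disease -> c(band1, band2, band3) giving
#'   prevalence in the 18–39, 40–59 and 60+ age bands
#' @param med_given_dx named list disease -> probability of the matching
#'   medication class given diagnosis
#' @param obs_prob probability each observation wave includes each parameter
#' @param adherence probability a due patient attends a recall
#' @return validated config list of class `cohort_config`
#' @export
cohort_config <- function(n, seed, as_of = as.Date("2023-06-01"),
                          female_share = 0.562,
                          age_mean = 52, age_sd = 16, age_min = 18, age_max = 95,
                          prevalence = list(hypertension = c(0.08, 0.25, 0.45),
                                            diabetes = c(0.03, 0.12, 0.22),
                                            obesity = c(0.15, 0.25, 0.28)),
                          med_given_dx = list(hypertension = 0.85, diabetes = 0.80),
                          obs_prob = 0.85, adherence = 0.7) {
  cfg <- list(n = as.integer(n), seed = as.integer(seed), as_of = as.Date(as_of),
              female_share = female_share, age_mean = age_mean, age_sd = age_sd,
              age_min = age_min, age_max = age_max, prevalence = prevalence,
              med_given_dx = med_given_dx, obs_prob = obs_prob,
              adherence = adherence)
  probs <- c(female_share, unlist(prevalence), unlist(med_given_dx), obs_prob, adherence)
  if (cfg$n <= 0L) stop("n must be positive")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(vapply(prevalence, length, 0L) != 3L))
    stop("prevalence entries must give 3 age-band values")
  structure(cfg, class = "cohort_config")
}

DISEASE_ICD10 <- c(hypertension = "I10", diabetes = "E11", obesity = "E66")
DISEASE_MEDCLASS <- c(hypertension = "antihypertensive", diabetes = "antidiabetic")

age_band <- function(age) ifelse(age < 40, 1L, ifelse(age < 60, 2L, 3L))

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# physiologic observation model: mean/sd by disease status, truncation bounds
obs_model <- function(key, diseased) {
  switch(key,
    sbp = c(if (diseased["hypertension"]) 148 else 122, 12, 80, 230),
    dbp = c(if (diseased["hypertension"]) 90 else 76, 8, 45, 130),
    fpg = c(if (diseased["diabetes"]) 150 else 92, if (diseased["diabetes"]) 30 else 9, 55, 400),
    hba1c = c(if (diseased["diabetes"]) 7.8 else 5.3, if (diseased["diabetes"]) 1.2 else 0.3, 3.5, 15),
    bmi = c(if (diseased["obesity"]) 33.5 else 25.5, if (diseased["obesity"]) 2.8 else 2.8, 16, 60),
    tchol = c(5.1, 1.0, 2.2, 11),
    ldl = c(3.1, 0.8, 0.6, 8),
    hdl = c(1.25, 0.3, 0.4, 3.4),
    tg = c(1.7, 0.6, 0.3, 8),
    weight = c(if (diseased["obesity"]) 95 else 74, 10, 40, 200),
    egfr = NULL,  # handled with an age trend
    stop("no observation model for ", key))
}

#' Generate a synthetic population
#'
#' @param config a [cohort_config()]
#' @return list of `patient_dataset`s, one per citizen, with a `config`
#'   attribute
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- config$n
  as_of <- config$as_of
  ages <- round(rtrunc_norm(n, config$age_mean, config$age_sd,
                            config$age_min, config$age_max))
  sexes <- ifelse(stats::runif(n) < config$female_share, "female", "male")
  fmp_ids <- sprintf("fmp-%03d", 1L + (seq_len(n) - 1L) %/% 2000L)
  keys <- c("sbp", "dbp", "fpg", "hba1c", "bmi", "tchol", "ldl", "hdl", "tg", "weight")
  population <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("p%06d", i)
    # birth date offset within the year so birthdays are spread out
    birth <- add_months(as_of, -(12L * ages[i]) - sample(0:11, 1L))
    patient <- patient_record(pid, birth, sexes[i], fmp_ids[i])
    band <- age_band(ages[i])
    diseased <- vapply(names(config$prevalence), function(d)
      stats::runif(1) < config$prevalence[[d]][band], TRUE)
    names(diseased) <- names(config$prevalence)
    for (d in setdiff(names(DISEASE_ICD10), names(diseased)))
      diseased[d] <- FALSE
    conditions <- list(); medications <- list()
    for (d in names(diseased)[diseased]) {
      onset <- add_months(as_of, -sample(6:120, 1L))
      conditions[[length(conditions) + 1L]] <- condition_entry(DISEASE_ICD10[[d]], onset)
      p_med <- config$med_given_dx[[d]] %||% 0
      if (stats::runif(1) < p_med)
        medications[[length(medications) + 1L]] <- medication_entry(
          coded_concept(SYS_DMP, paste0("med-", DISEASE_MEDCLASS[[d]]), DISEASE_MEDCLASS[[d]]),
          DISEASE_MEDCLASS[[d]], onset)
    }
    observations <- list()
    for (months_back in c(14L, 2L)) {
      eff <- add_months(as_of, -months_back)
      for (key in keys) {
        if (stats::runif(1) >= config$obs_prob) next
        m <- obs_model(key, diseased)
        val <- round(rtrunc_norm(1L, m[1], m[2], m[3], m[4]),
                     if (key %in% c("sbp", "dbp", "fpg", "weight")) 0 else 1)
        observations[[length(observations) + 1L]] <-
          clinical_observation(key, val, effective_date = eff, origin = "ehr_sync")
      }
      if (stats::runif(1) < config$obs_prob) {
        egfr <- round(rtrunc_norm(1L, 105 - 0.45 * ages[i], 13, 10, 140))
        observations[[length(observations) + 1L]] <-
          clinical_observation("egfr", egfr, effective_date = eff, origin = "ehr_sync")
      }
    }
    population[[i]] <- patient_dataset(patient, conditions, medications, observations)
  }
  attr(population, "config") <- config
  population
}

#' Simulate an encounter log over a period
#'
#' Month by month from `months` before the configuration's reference date,
#' every patient due for a module track (per the eligibility engine, on the
#' first day of the month) attends with probability `adherence`; attended
#' encounters are appended to the patient's record, so recall scheduling
#' compounds realistically. Monthly targets are the due counts before the
#' adherence draw.
#'
#' @param population output of [generate_population()] (its `config`
#'   attribute supplies seed and adherence unless `config` is given)
#' @param months number of simulated months
#' @param registry module registry (defaults to [builtin_defaults()])
#' @param config optional [cohort_config()] override
#' @return list with `encounter_log` (data.frame patient_id, module, track,
#'   date, sex, performer), `monthly_targets` (data.frame month, module,
#'   track, target) and `population` (records updated with the simulated
#'   encounters)
#' @export
generate_encounter_log <- function(population, months,
                                   registry = builtin_defaults(),
                                   config = attr(population, "config")) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed + 1L, kind = "Mersenne-Twister", normal.kind = "Inversion")
  log_rows <- list(); target_rows <- list()
  start <- add_months(config$as_of, -months)
  for (k in seq_len(months)) {
    month_date <- add_months(start, k)
    for (i in seq_along(population)) {
      ds <- population[[i]]
      for (m in registry$modules) {
        st <- next_due(ds, m, month_date)
        if (!st$status %in% c("due_now", "overdue")) next
        target_rows[[length(target_rows) + 1L]] <-
          data.frame(month = format(month_date, "%Y-%m"), module = m$module_id,
                     track = st$track, stringsAsFactors = FALSE)
        if (stats::runif(1) < config$adherence) {
          day <- sample.int(27L, 1L)
          enc_date <- as.Date(format(month_date, "%Y-%m-01")) + (day - 1L)
          ds$encounters[[length(ds$encounters) + 1L]] <-
            encounter_record(m$module_id, st$track, enc_date,
                             ds$patient$assigned_fmp, round(stats::runif(1, 0.5, 3), 2))
          log_rows[[length(log_rows) + 1L]] <-
            data.frame(patient_id = ds$patient$patient_id, module = m$module_id,
                       track = st$track, date = enc_date, sex = ds$patient$sex,
                       performer = ds$patient$assigned_fmp, stringsAsFactors = FALSE)
        }
      }
      population[[i]] <- ds
    }
  }
  empty_log <- data.frame(patient_id = character(), module = character(),
                          track = character(), date = as.Date(character()),
                          sex = character(), performer = character())
  log <- if (length(log_rows)) do.call(rbind, c(log_rows, list(make.row.names = FALSE))) else empty_log
  targets <- if (length(target_rows)) {
    tr <- do.call(rbind, c(target_rows, list(make.row.names = FALSE)))
    agg <- stats::aggregate(rep(1L, nrow(tr)),
                            by = list(month = tr$month, module = tr$module, track = tr$track),
                            FUN = sum)
    names(agg)[4L] <- "target"
    agg[order(agg$month, agg$module, agg$track), , drop = FALSE]
  } else data.frame(month = character(), module = character(),
                    track = character(), target = integer())
  rownames(targets) <- NULL
  list(encounter_log = log, monthly_targets = targets, population = population)
}
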