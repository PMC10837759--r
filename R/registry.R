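# Disease-module registry: declarative per-disease rule sets.
#
# A module definition carries everything the engines need for one disease:
# who is eligible for screening vs monitoring, how often each track recurs
# (possibly keyed by risk category or control status), how long each clinical
# parameter stays valid, which page flow an encounter follows, and which
# decision-support rules apply. Definitions round-trip through YAML so rule
# content is configuration, not code.

#' Recall-interval rule
#'
#' Maps a context key (risk category, control status) to a recall interval in
#' months. A `"default"` key is mandatory and is used when the context is
#' unknown — e.g. a risk-keyed screening interval falls back to the default
#' until a risk score has been computed.
#'
#' @param ... named intervals in months, e.g. `default = 24, high = 12`
#' @export
interval_rule <- function(...) {
  iv <- list(...)
  if (length(iv) == 1L && is.list(iv[[1L]]) && is.null(names(iv))) iv <- iv[[1L]]
  iv <- lapply(iv, as.numeric)
  if (!"default" %in% names(iv)) stop("interval rule requires a 'default' key")
  if (any(vapply(iv, function(x) !is.finite(x) || x <= 0, TRUE)))
    stop("all intervals must be positive")
  structure(iv, class = "interval_rule")
}

#' Resolve an interval for a context key
#' @param rule an [interval_rule()]
#' @param key context key (risk category etc.) or `NA`
#' @return interval in months
#' @export
resolve_interval <- function(rule, key = NA_character_) {
  if (!is.na(key) && key %in% names(rule)) return(rule[[key]])
  rule[["default"]]
}

#' Disease-module definition
#'
#' @param module_id module identifier (`hypertension`, `diabetes`, `cvd_risk`,
#'   `obesity`, `older_adult`, or any extension id)
#' @param screening_eligibility,monitoring_eligibility predicates (see
#'   [predicates]); a diagnosed patient must never satisfy both — monitoring
#'   takes precedence and the registry validator samples for overlap
#' @param screening_interval,monitoring_interval [interval_rule()]s in months
#' @param validity_periods named numeric vector/list, parameter key -> months
#' @param flow_ref id of the page flow encounters of this module follow
#' @param cds_rules list of rule descriptors (see [cds_rule()])
#' @export
disease_module <- function(module_id, screening_eligibility, monitoring_eligibility,
                           screening_interval, monitoring_interval,
                           validity_periods = list(), flow_ref,
                           cds_rules = list()) {
  structure(list(module_id = module_id,
                 screening_eligibility = as_predicate(screening_eligibility),
                 monitoring_eligibility = as_predicate(monitoring_eligibility),
                 screening_interval = screening_interval,
                 monitoring_interval = monitoring_interval,
                 validity_periods = lapply(validity_periods, as.numeric),
                 flow_ref = flow_ref,
                 cds_rules = cds_rules),
            class = "disease_module")
}

#' Module registry
#' @param modules list of [disease_module()]s
#' @param flows list of page flows (see [page_flow()])
#' @export
module_registry <- function(modules = list(), flows = list()) {
  names(modules) <- vapply(modules, `[[`, "", "module_id")
  names(flows) <- vapply(flows, `[[`, "", "flow_id")
  structure(list(modules = modules, flows = flows, registry_version = 1L),
            class = "module_registry")
}

#' @export
print.module_registry <- function(x, ...) {
  cat(sprintf("Module registry (v%d): %d modules, %d flows\n",
              x$registry_version, length(x$modules), length(x$flows)))
  for (m in x$modules)
    cat(sprintf("  %-12s screening: %s\n  %-12s monitoring: %s\n",
                m$module_id, describe_predicate(m$screening_eligibility),
                "", describe_predicate(m$monitoring_eligibility)))
  invisible(x)
}

#' Validate a module registry
#'
#' Checks: every `flow_ref` resolves, every flow passes [validate_flow()],
#' intervals are positive with a default key, validity periods are positive,
#' every predicate atom is resolvable, and (by sampling synthetic patient
#' states) screening and monitoring eligibility are mutually exclusive.
#'
#' @param registry a [module_registry()]
#' @param sample_overlap number of sampled patient states per module for the
#'   disjointness check (0 disables)
#' @return `registry`, invisibly; stops listing all problems otherwise
#' @export
validate_registry <- function(registry, sample_overlap = 50L) {
  probs <- character()
  for (m in registry$modules) {
    w <- m$module_id
    if (!m$flow_ref %in% names(registry$flows))
      probs <- c(probs, sprintf("%s: dangling flow_ref '%s'", w, m$flow_ref))
    for (nm in c("screening_interval", "monitoring_interval")) {
      iv <- m[[nm]]
      if (!inherits(iv, "interval_rule"))
        probs <- c(probs, sprintf("%s: %s is not an interval rule", w, nm))
      else if (any(unlist(iv) <= 0))
        probs <- c(probs, sprintf("%s: %s has a non-positive interval", w, nm))
    }
    bad_vp <- vapply(m$validity_periods, function(v) !is.finite(v) || v <= 0, TRUE)
    if (any(bad_vp))
      probs <- c(probs, sprintf("%s: non-positive validity period for %s", w,
                                paste(names(m$validity_periods)[bad_vp], collapse = ",")))
    unknown_vp <- setdiff(names(m$validity_periods), param_catalog()$key)
    if (length(unknown_vp))
      probs <- c(probs, sprintf("%s: validity period for unknown parameter %s", w,
                                paste(unknown_vp, collapse = ",")))
    probs <- c(probs, validate_predicate(m$screening_eligibility, paste0(w, "/screening")))
    probs <- c(probs, validate_predicate(m$monitoring_eligibility, paste0(w, "/monitoring")))
  }
  for (fl in registry$flows) {
    rep <- validate_flow(fl)
    if (!rep$valid)
      probs <- c(probs, sprintf("flow %s: %s", fl$flow_id,
                                paste(rep$problems, collapse = "; ")))
  }
  if (length(probs) == 0L && sample_overlap > 0L) {
    for (m in registry$modules) {
      overlaps <- overlap_sample(m, n = sample_overlap)
      if (overlaps > 0L)
        probs <- c(probs, sprintf(
          "%s: screening and monitoring eligibility overlap on %d/%d sampled states",
          m$module_id, overlaps, sample_overlap))
    }
  }
  if (length(probs)) stop("invalid registry:\n  ", paste(probs, collapse = "\n  "))
  invisible(registry)
}

# sample random-but-reproducible patient states and count states satisfying
# both tracks; uses a private RNG stream so validation never disturbs the
# caller's seed
overlap_sample <- function(module, n = 50L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(20260101L, kind = "Mersenne-Twister")
  as_of <- as.Date("2023-06-01")
  count <- 0L
  for (i in seq_len(n)) {
    ds <- random_patient_state(as_of)
    ctx <- predicate_context(ds, as_of,
                             risk_category = sample(c(NA, "low", "moderate", "high", "very_high"), 1L))
    if (eval_predicate(module$screening_eligibility, ctx) &&
        eval_predicate(module$monitoring_eligibility, ctx)) count <- count + 1L
  }
  count
}

random_patient_state <- function(as_of) {
  age <- sample(18:90, 1L)
  ds <- patient_dataset(patient_record("ov", add_months(as_of, -12L * age), sample(c("female", "male"), 1L)))
  pool <- c("I10", "I11", "E10", "E11", "E66", "N18")
  for (cd in pool[stats::runif(length(pool)) < 0.25])
    ds$conditions[[length(ds$conditions) + 1L]] <- condition_entry(cd, add_months(as_of, -sample(1:60, 1L)))
  if (stats::runif(1) < 0.4)
    ds$medications[[length(ds$medications) + 1L]] <- medication_entry(
      coded_concept(SYS_DMP, "med-aht", "antihypertensive"), "antihypertensive",
      add_months(as_of, -12L))
  if (stats::runif(1) < 0.4)
    ds$medications[[length(ds$medications) + 1L]] <- medication_entry(
      coded_concept(SYS_DMP, "med-adm", "antidiabetic"), "antidiabetic",
      add_months(as_of, -12L))
  for (key in c("bmi", "sbp", "fpg")) if (stats::runif(1) < 0.8)
    ds$observations[[length(ds$observations) + 1L]] <- clinical_observation(
      key, switch(key, bmi = stats::runif(1, 17, 45), sbp = stats::runif(1, 95, 190),
                  fpg = stats::runif(1, 70, 220)),
      effective_date = add_months(as_of, -sample(0:6, 1L)), origin = "ehr_sync")
  ds
}

# --- serialisation --------------------------------------------------------

module_to_list <- function(m) {
  list(module_id = m$module_id,
       screening_eligibility = predicate_to_list(m$screening_eligibility),
       monitoring_eligibility = predicate_to_list(m$monitoring_eligibility),
       screening_interval = unclass(m$screening_interval),
       monitoring_interval = unclass(m$monitoring_interval),
       validity_periods = m$validity_periods,
       flow_ref = m$flow_ref,
       cds_rules = lapply(m$cds_rules, unclass))
}

registry_to_list <- function(registry) {
  list(registry_version = registry$registry_version,
       modules = lapply(unname(registry$modules), module_to_list),
       flows = lapply(unname(registry$flows), flow_to_list))
}

#' Serialise a registry to YAML
#' @param registry a [module_registry()]
#' @param path optional file path
#' @return YAML text (or path, invisibly)
#' @export
serialize_registry <- function(registry, path = NULL) {
  txt <- yaml::as.yaml(registry_to_list(registry))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Load and validate a module registry from configuration
#'
#' Accepts YAML/JSON file paths, YAML text, or pre-parsed lists; several
#' documents may be supplied and are merged (later module ids win). The
#' result is fully validated: dangling flow references, non-positive
#' intervals, unresolvable predicate atoms and non-terminating flows are all
#' reported together.
#'
#' @param documents one document or a list of documents
#' @return a validated [module_registry()]
#' @export
load_registry <- function(documents) {
  if (!is.list(documents) || !is.null(names(documents))) documents <- list(documents)
  modules <- list(); flows <- list()
  for (doc in documents) {
    parsed <- parse_registry_document(doc)
    for (ml in parsed$modules %||% list()) {
      m <- module_from_list(ml)
      modules[[m$module_id]] <- m
    }
    for (fl in parsed$flows %||% list()) {
      f <- flow_from_list(fl)
      flows[[f$flow_id]] <- f
    }
  }
  validate_registry(module_registry(unname(modules), unname(flows)))
}

parse_registry_document <- function(doc) {
  if (is.list(doc)) return(doc)
  if (is.character(doc) && length(doc) == 1L) {
    if (file.exists(doc)) {
      if (grepl("\\.json$", doc)) return(jsonlite::fromJSON(doc, simplifyVector = FALSE))
      return(yaml::read_yaml(doc))
    }
    return(yaml::yaml.load(doc))
  }
  stop("cannot interpret registry document")
}

module_from_list <- function(x) {
  need <- c("module_id", "screening_eligibility", "monitoring_eligibility",
            "screening_interval", "monitoring_interval", "flow_ref")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("module config missing fields: ", paste(missing, collapse = ", "))
  disease_module(
    module_id = x$module_id,
    screening_eligibility = predicate_from_list(x$screening_eligibility),
    monitoring_eligibility = predicate_from_list(x$monitoring_eligibility),
    screening_interval = interval_rule(x$screening_interval),
    monitoring_interval = interval_rule(x$monitoring_interval),
    validity_periods = x$validity_periods %||% list(),
    flow_ref = x$flow_ref,
    cds_rules = lapply(x$cds_rules %||% list(), function(r) do.call(cds_rule, r))
  )
}

# --- built-in defaults ----------------------------------------------------

#' Built-in default disease modules
#'
#' The five modules the national platform launched with, with every rule the
#' platform documentation states encoded as-is:
#'
#' * diabetes screening: age strictly over 40 without an active diabetes
#'   diagnosis (ICD-10 E10–E14), recall every 36 months; monitoring for
#'   diagnosed patients every 6 months.
#' * hypertension monitoring: active I10–I15 diagnosis *and* ongoing
#'   antihypertensive medication, recall every 3 months; screening of
#'   undiagnosed adults every 12 months.
#' * cardiovascular risk: screening recall keyed by risk category — 24 months
#'   at low risk, 12 months at high risk; patients scored very high move to
#'   the monitoring track (every 6 months).
#' * obesity: screening of adults without an obesity diagnosis; primary-care
#'   monitoring only for uncomplicated obesity — patients with BMI above 40,
#'   or BMI in (30, 40] together with a configured comorbidity (default
#'   E10–E14, I10–I15), are managed in secondary care and excluded here.
#' * older-adult monitoring from age 65 (no screening track).
#'
#' Where the platform documentation states no interval, a field-conventional
#' default is used (see the methods vignette).
#'
#' @return a validated [module_registry()] with 5 modules
#' @export
builtin_defaults <- function() {
  vp_common <- list(sbp = 6, dbp = 6, bmi = 12, weight = 12, height = 60,
                    waist = 12, fpg = 12, tchol = 12, ldl = 12, hdl = 12,
                    tg = 12, egfr = 12)
  hypertension <- disease_module(
    "hypertension",
    screening_eligibility = p_all(p_age(">", 18), p_not(p_condition("I10-I15"))),
    monitoring_eligibility = p_all(p_condition("I10-I15"), p_medication("antihypertensive")),
    screening_interval = interval_rule(default = 12),
    monitoring_interval = interval_rule(default = 3),
    validity_periods = vp_common,
    flow_ref = "hypertension_screening",
    cds_rules = list(
      cds_rule("htn_confirmed_bp_dx", "diagnosis",
               when = p_all(p_observation("sbp", ">=", 140), p_observation("dbp", ">=", 90)),
               icd10 = "I10", label = "Essential (primary) hypertension",
               requires = c("sbp", "dbp")),
      cds_rule("fpg_diabetes_prompt", "module_transition",
               when = p_observation("fpg", ">", 110), target_module = "diabetes",
               unless_monitored = "diabetes", requires = "fpg"))
  )
  diabetes <- disease_module(
    "diabetes",
    screening_eligibility = p_all(p_age(">", 40), p_not(p_condition("E10-E14"))),
    monitoring_eligibility = p_condition("E10-E14"),
    screening_interval = interval_rule(default = 36),
    monitoring_interval = interval_rule(default = 6),
    validity_periods = c(vp_common, list(hba1c = 6)),
    flow_ref = "diabetes_flow",
    cds_rules = list(
      cds_rule("dm_fpg_dx", "diagnosis",
               when = p_observation("fpg", ">=", 126),
               icd10 = "E11", label = "Type 2 diabetes mellitus",
               requires = "fpg"),
      cds_rule("dm_retinopathy_check", "preventive_referral",
               specialty = "ophthalmology", every_months = 12,
               label = "Yearly retinopathy check"))
  )
  cvd_risk <- disease_module(
    "cvd_risk",
    screening_eligibility = p_all(p_age(">", 40), p_not(p_risk("very_high"))),
    monitoring_eligibility = p_risk("very_high"),
    screening_interval = interval_rule(default = 24, low = 24, moderate = 24,
                                       high = 12),
    monitoring_interval = interval_rule(default = 6),
    validity_periods = c(vp_common, list(score10y = 24)),
    flow_ref = "cvd_risk_flow",
    cds_rules = list()
  )
  obesity <- disease_module(
    "obesity",
    screening_eligibility = p_all(p_age(">", 18), p_not(p_condition("E66"))),
    monitoring_eligibility = p_all(
      p_condition("E66"),
      p_observation("bmi", "<=", 40, validity_months = 12),
      p_not(p_all(p_observation("bmi", ">", 30, validity_months = 12),
                  p_condition(c("E10-E14", "I10-I15"))))),
    screening_interval = interval_rule(default = 12),
    monitoring_interval = interval_rule(default = 3),
    validity_periods = vp_common,
    flow_ref = "obesity_flow",
    cds_rules = list(
      cds_rule("ob_bmi_dx", "diagnosis",
               when = p_observation("bmi", ">=", 30),
               icd10 = "E66", label = "Obesity", requires = "bmi"))
  )
  older_adult <- disease_module(
    "older_adult",
    screening_eligibility = p_never(),
    monitoring_eligibility = p_age(">=", 65),
    screening_interval = interval_rule(default = 12),
    monitoring_interval = interval_rule(default = 6),
    validity_periods = vp_common,
    flow_ref = "older_adult_flow",
    cds_rules = list()
  )
  validate_registry(module_registry(
    list(hypertension, diabetes, cvd_risk, obesity, older_adult),
    builtin_flows()
  ))
}
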