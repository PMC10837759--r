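# Shared fixture builders: small deterministic patients assembled in code.

AS_OF <- as.Date("2023-06-01")

make_patient <- function(id = "p1", age = 50, sex = "female", fmp = "fmp-001",
                         conditions = character(), med_classes = character(),
                         obs = list(), as_of = AS_OF) {
  ds <- patient_dataset(patient_record(id, add_months(as_of, -12L * age), sex, fmp))
  for (cd in conditions)
    ds$conditions[[length(ds$conditions) + 1L]] <-
      condition_entry(cd, add_months(as_of, -24L))
  for (cls in med_classes)
    ds$medications[[length(ds$medications) + 1L]] <- medication_entry(
      coded_concept("urn:dmp:code", paste0("med-", cls), cls), cls,
      add_months(as_of, -24L))
  for (o in obs)
    ds$observations[[length(ds$observations) + 1L]] <- clinical_observation(
      o$key, o$value,
      effective_date = o$date %||% add_months(as_of, -(o$months_ago %||% 1L)),
      origin = o$origin %||% "ehr_sync")
  ds
}

obs_spec <- function(key, value, months_ago = 1L, date = NULL, origin = NULL) {
  list(key = key, value = value, months_ago = months_ago, date = date,
       origin = origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small seeded cohort and simulated encounter log reused across tests
test_cohort <- local({
  cache <- NULL
  function(n = 200, seed = 7L) {
    if (is.null(cache))
      cache <<- generate_population(cohort_config(n = n, seed = seed))
    cache
  }
})

test_sim <- local({
  cache <- NULL
  function(months = 6) {
    if (is.null(cache))
      cache <<- generate_encounter_log(test_cohort(), months, builtin_defaults())
    cache
  }
})
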