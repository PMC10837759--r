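reg <- builtin_defaults()

test_that("flow validator accepts trivial flows and the shipped defaults", {
  single <- page_flow("f", "only",
                      pages = list(page_def("only", "medical_history")),
                      transitions = list(list(from = "only", predicate = NULL, to = "TERMINAL")))
  expect_true(validate_flow(single)$valid)
  for (fl in builtin_flows()) {
    rep <- validate_flow(fl)
    expect_true(rep$valid, info = fl$flow_id)
  }
})

test_that("flow validator reports cycles, unreachable pages and undeclared parameters", {
  looping <- page_flow("loop", "a",
    pages = list(page_def("a", "medical_history"), page_def("b", "lab_review")),
    transitions = list(list(from = "a", predicate = NULL, to = "b"),
                       list(from = "b", predicate = NULL, to = "a")))
  rep <- validate_flow(looping)
  expect_false(rep$valid)
  expect_match(paste(rep$problems, collapse = " "), "cycle")

  orphan <- page_flow("orphan", "a",
    pages = list(page_def("a", "medical_history"), page_def("b", "lab_review")),
    transitions = list(list(from = "a", predicate = NULL, to = "TERMINAL"),
                       list(from = "b", predicate = NULL, to = "TERMINAL")))
  expect_match(paste(validate_flow(orphan)$problems, collapse = " "), "unreachable")

  undeclared <- page_flow("und", "a",
    pages = list(page_def("a", "medical_history")),
    transitions = list(list(from = "a", predicate = p_observation("fpg", ">", 110), to = "TERMINAL"),
                       list(from = "a", predicate = NULL, to = "TERMINAL")))
  expect_match(paste(validate_flow(undeclared)$problems, collapse = " "), "undeclared")

  no_catchall <- page_flow("nc", "a",
    pages = list(page_def("a", "lab_review", list(list(code = "fpg")))),
    transitions = list(list(from = "a", predicate = p_observation("fpg", ">", 110), to = "TERMINAL")))
  expect_match(paste(validate_flow(no_catchall)$problems, collapse = " "), "catch-all")
})

test_that("sessions prefill from the record with freshness flags and refuse ineligible patients", {
  ht <- reg$modules$hypertension
  fresh <- make_patient(age = 45, obs = list(obs_spec("sbp", 128, months_ago = 1),
                                             obs_spec("dbp", 82, months_ago = 1)))
  s <- start_encounter(fresh, ht, reg, "screening", AS_OF)
  expect_equal(s$prefills$sbp$value, 128)
  expect_equal(s$prefills$sbp$freshness, "fresh")

  stale <- make_patient(age = 45, obs = list(obs_spec("fpg", 118, months_ago = 20)))
  s2 <- start_encounter(stale, ht, reg, "screening", AS_OF)
  expect_equal(s2$prefills$fpg$freshness, "expired")

  diagnosed <- make_patient(age = 45, conditions = "I10", med_classes = "antihypertensive")
  expect_error(start_encounter(diagnosed, ht, reg, "screening", AS_OF), "not eligible")
})

test_that("page submission enforces units, known parameters, and required coverage", {
  ht <- reg$modules$hypertension
  ds <- make_patient(age = 45)
  s <- start_encounter(ds, ht, reg, "screening", AS_OF)
  expect_error(submit_page(s, list(sbp = list(value = 130, unit = "kPa"))), "unit mismatch")
  expect_error(submit_page(s, list(nonsense = 4)), "unknown parameter")
  expect_error(submit_page(s, list(sbp = 130)), "requires")
  s2 <- submit_page(s, list(sbp = 130, dbp = 80), defer = "bmi")
  expect_equal(s2$current_page, "labs")
})

test_that("transitions take the first matching branch and entered values shadow prefills", {
  ht <- reg$modules$hypertension
  # prefilled normal BP would go straight to labs, but the entered elevated
  # value must drive the transition
  ds <- make_patient(age = 45, obs = list(obs_spec("sbp", 120, months_ago = 1),
                                          obs_spec("dbp", 78, months_ago = 1),
                                          obs_spec("bmi", 27, months_ago = 1)))
  s <- start_encounter(ds, ht, reg, "screening", AS_OF)
  s <- submit_page(s, list(sbp = 155, dbp = 96))
  expect_equal(s$current_page, "bp_confirm")
  # confirmation page emits the hypertension diagnosis suggestion
  s <- submit_page(s, list(sbp = 150, dbp = 95))
  cards <- attr(s, "new_cards")
  expect_true(any(vapply(cards, function(cd) cd$kind == "diagnosis_suggestion", TRUE)))
  expect_equal(cards[[1]]$payload$concept$code, "I10")
})

test_that("the fasting-glucose boundary on the diabetes prompt is strict", {
  ht <- reg$modules$hypertension
  run_fpg <- function(fpg) {
    ds <- make_patient(age = 45)
    res <- run_encounter(ds, ht, reg, "screening", AS_OF,
                         answers = list(sbp = 120, dbp = 78, bmi = 27, fpg = fpg))
    any(vapply(res$session$emitted_cards,
               function(cd) cd$kind == "module_transition_prompt" &&
                 cd$rule_id == "fpg_diabetes_prompt", TRUE))
  }
  expect_true(run_fpg(120))
  expect_true(run_fpg(110.5))
  expect_false(run_fpg(110))  # "exceeds 110" is strict
  expect_false(run_fpg(100))
})

test_that("no diabetes prompt for patients already monitored for diabetes", {
  ht <- reg$modules$hypertension
  ds <- make_patient(age = 45, conditions = "E11")
  cards <- module_transition_check(ds, ht, AS_OF, session_values = list(fpg = 115))
  expect_length(Filter(function(cd) cd$rule_id == "fpg_diabetes_prompt", cards), 0L)
})

test_that("completion assembles the care plan, records the encounter, and updates schedules", {
  ht <- reg$modules$hypertension
  ds <- make_patient(age = 45)
  res <- run_encounter(ds, ht, reg, "screening", AS_OF,
                       answers = list(sbp = 120, dbp = 80, bmi = 27, fpg = 120))
  # mandatory follow-up appointment with the screening interval
  fu <- Filter(function(a) a$kind == "follow_up_appointment", res$care_plan$activities)
  expect_length(fu, 1L)
  expect_equal(fu[[1]]$due_date, add_months(AS_OF, 12))
  expect_equal(res$encounter$module_id, "hypertension")
  # entered values persisted as encounter_entry observations
  entered <- Filter(function(o) o$origin == "encounter_entry", res$dataset$observations)
  expect_setequal(vapply(entered, function(o) dmpkit:::param_key_for(o$code$system, o$code$code), ""),
                  c("sbp", "dbp", "bmi", "fpg"))
  # accepted diabetes prompt: diabetes screening becomes due_now
  expect_equal(res$schedule_updates$diabetes$status, "due_now")
  expect_equal(res$schedule_updates$hypertension$status, "up_to_date")
  # completing twice is a state error
  expect_error(complete_encounter(res$session), "already completed")
})

test_that("rejected cards stay out of the care plan", {
  ht <- reg$modules$hypertension
  ds <- make_patient(age = 45)
  s <- start_encounter(ds, ht, reg, "screening", AS_OF)
  s <- submit_page(s, list(sbp = 150, dbp = 95), defer = "bmi")
  s <- submit_page(s, list(sbp = 150, dbp = 95))
  s <- submit_page(s, list(fpg = 100))
  s <- review_cards(s, "htn_confirmed_bp_dx", "rejected")
  while (s$current_page != "TERMINAL") s <- submit_page(s)
  res <- complete_encounter(s)
  expect_length(Filter(function(a) a$kind != "follow_up_appointment",
                       res$care_plan$activities), 0L)
})

test_that("every session over every shipped flow terminates within the page budget", {
  pop <- test_cohort()[1:40]
  set.seed(99)
  for (ds in pop) {
    for (m in reg$modules) {
      dec <- evaluate_eligibility(ds, m, AS_OF)
      if (dec$track == "none") next
      answers <- list(sbp = runif(1, 90, 200), dbp = runif(1, 50, 120),
                      bmi = runif(1, 18, 45), fpg = runif(1, 60, 250),
                      hba1c = runif(1, 4, 12), tchol = runif(1, 3, 9),
                      weight = runif(1, 50, 140), waist = runif(1, 60, 140))
      res <- run_encounter(ds, m, reg, dec$track, AS_OF, answers = answers)
      expect_equal(res$session$status, "completed")
    }
  }
})
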