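reg <- builtin_defaults()

# independent step-by-step re-derivation of the Weibull risk, written against
# the published formula rather than the package implementation
oracle_score <- function(age, sex, smoker, sbp, chol, table) {
  risk_for <- function(ep) {
    s <- table$survival
    alpha <- s$alpha[s$sex == sex & s$endpoint == ep]
    p <- s$p[s$sex == sex & s$endpoint == ep]
    h <- table$loghr
    b_smoke <- h$smoker[h$endpoint == ep]
    b_sbp <- h$sbp[h$endpoint == ep]
    b_chol <- h$tchol[h$endpoint == ep]
    w <- b_chol * (chol - 6) + b_sbp * (sbp - 120) + b_smoke * as.numeric(smoker)
    s_now <- exp(-(exp(alpha)) * (age - 20)^p)^exp(w)
    s_10 <- exp(-(exp(alpha)) * ((age + 10) - 20)^p)^exp(w)
    1 - s_10 / s_now
  }
  min(100, 100 * (risk_for("chd") + risk_for("non_chd")))
}

test_that("risk score matches the independent Weibull derivation to 1e-9 relative", {
  table <- score_demo_coefficients()
  grid <- expand.grid(age = c(40, 50, 55, 60, 65), sex = c("female", "male"),
                      smoker = c(FALSE, TRUE), sbp = c(120, 140, 160, 180, 200),
                      chol = c(4, 5, 6, 7, 8), stringsAsFactors = FALSE)
  grid <- grid[seq(1, nrow(grid), length.out = 120), ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- cvd_risk_score(g$age, g$sex, g$smoker, g$sbp, g$chol, table)$ten_year_risk_percent
    want <- oracle_score(g$age, g$sex, g$smoker, g$sbp, g$chol, table)
    expect_lt(abs(got - want) / max(want, 1e-12), 1e-9)
  }
})

test_that("risk is monotone in age, pressure, cholesterol and smoking", {
  for (sex in c("female", "male")) {
    ages <- 40:65
    risks <- vapply(ages, function(a)
      cvd_risk_score(a, sex, FALSE, 140, 6)$ten_year_risk_percent, 0)
    expect_true(all(diff(risks) >= 0))
    sbps <- seq(100, 200, by = 10)
    risks <- vapply(sbps, function(s)
      cvd_risk_score(55, sex, FALSE, s, 6)$ten_year_risk_percent, 0)
    expect_true(all(diff(risks) >= 0))
    chols <- seq(3, 9, by = 0.5)
    risks <- vapply(chols, function(ch)
      cvd_risk_score(55, sex, FALSE, 140, ch)$ten_year_risk_percent, 0)
    expect_true(all(diff(risks) >= 0))
    expect_gte(cvd_risk_score(55, sex, TRUE, 140, 6)$ten_year_risk_percent,
               cvd_risk_score(55, sex, FALSE, 140, 6)$ten_year_risk_percent)
  }
})

test_that("risk inputs are range-checked and categories follow the cut points", {
  expect_error(cvd_risk_score(25, "male", FALSE, 140, 6), "age")
  expect_error(cvd_risk_score(55, "male", FALSE, 300, 6), "sbp")
  expect_error(cvd_risk_score(55, "male", FALSE, 140, 20), "cholesterol")
  r_low <- cvd_risk_score(40, "female", FALSE, 110, 4)
  expect_equal(r_low$category, "low")
  r_high <- cvd_risk_score(65, "male", TRUE, 180, 8)
  expect_true(r_high$category %in% c("high", "very_high"))
  expect_true(r_high$ten_year_risk_percent >= 5)
})

test_that("unit conversions use the standard molar factors", {
  expect_equal(convert_glucose(110, "mmol/L"), 110 / 18.018)
  expect_equal(convert_glucose(convert_glucose(123, "mmol/L"), "mg/dL"), 123)
  expect_equal(convert_cholesterol(232, "mmol/L"), 232 / 38.67)
})

test_that("diagnosis rules emit coded cards, nothing on normal values, and data requests on missing input", {
  ht <- reg$modules$hypertension
  ds <- make_patient(age = 50)
  cards <- recommend_diagnosis(list(sbp = 150, dbp = 95), ht, ds, AS_OF)
  expect_length(cards, 1L)
  expect_equal(cards[[1]]$kind, "diagnosis_suggestion")
  expect_equal(cards[[1]]$payload$concept$code, "I10")

  expect_length(recommend_diagnosis(list(sbp = 120, dbp = 78), ht, ds, AS_OF), 0L)

  missing <- recommend_diagnosis(list(), ht, ds, AS_OF)
  expect_true(all(vapply(missing, function(cd) cd$kind == "lab_order", TRUE)))
  expect_gte(length(missing), 1L)
})

test_that("lab panel lists exactly the expired/absent parameters (oracle check)", {
  dm <- reg$modules$diabetes
  ds <- make_patient(age = 50, obs = list(
    obs_spec("fpg", 100, months_ago = 2),     # fresh (12 mo validity)
    obs_spec("hba1c", 6.1, months_ago = 10),  # expired (6 mo validity)
    obs_spec("sbp", 120, months_ago = 1)))    # fresh
  cards <- required_lab_panel(ds, dm, AS_OF)
  keys <- vapply(cards, function(cd) dmpkit:::param_key_for(cd$payload$concept$system,
                                                            cd$payload$concept$code), "")
  # oracle: brute-force expiry scan over the configured validity periods
  oracle <- character()
  for (key in names(dm$validity_periods)) {
    hit <- latest_observation(ds, key, AS_OF)
    status <- if (is.null(hit$observation)) "absent"
      else if (months_between(hit$observation$effective_date, AS_OF) > dm$validity_periods[[key]]) "expired"
      else "fresh"
    if (status != "fresh") oracle <- c(oracle, key)
  }
  expect_setequal(keys, oracle)
  expect_true("hba1c" %in% keys)
  expect_false("fpg" %in% keys)

  all_fresh <- make_patient(age = 50, obs = lapply(names(dm$validity_periods),
                                                   function(k) obs_spec(k, 10, months_ago = 1)))
  expect_length(required_lab_panel(all_fresh, dm, AS_OF), 0L)
})

test_that("goal recommendations include glycaemic goals for diabetics and tighten LDL with risk", {
  dm <- reg$modules$diabetes
  diabetic <- make_patient(age = 60, conditions = "E11")
  cards <- recommend_goals(diabetic, dm, AS_OF)
  keys <- vapply(cards, function(cd) dmpkit:::param_key_for(cd$payload$concept$system,
                                                            cd$payload$concept$code), "")
  expect_true(all(c("hba1c", "fpg", "sbp", "dbp", "ldl") %in% keys))

  healthy <- make_patient(age = 60)
  keys_h <- vapply(recommend_goals(healthy, dm, AS_OF),
                   function(cd) dmpkit:::param_key_for(cd$payload$concept$system,
                                                       cd$payload$concept$code), "")
  expect_false("hba1c" %in% keys_h)

  ldl_target <- function(risk) {
    cards <- recommend_goals(healthy, dm, AS_OF, risk = risk)
    for (cd in cards) if (cd$payload$concept$code == param_concept("ldl")$code)
      return(cd$payload$target)
  }
  expect_true(ldl_target("very_high") <= ldl_target("high"))
  expect_true(ldl_target("high") <= ldl_target("low"))
})

test_that("goal cards round-trip into goal records", {
  ds <- make_patient(age = 60, conditions = "E11")
  for (cd in recommend_goals(ds, reg$modules$diabetes, AS_OF)) {
    g <- goal_card_to_record(cd)
    expect_s3_class(g, "goal_record")
    expect_identical(g$parameter, cd$payload$concept)
    expect_equal(g$target_value, cd$payload$target)
    expect_equal(g$comparator, cd$payload$comparator)
  }
})

test_that("medication advice flags contraindications by active comorbidity (oracle check)", {
  ht <- reg$modules$hypertension
  tbl <- default_contraindications()
  asthmatic <- make_patient(age = 50, conditions = c("I10", "J45"))
  cards <- medication_advice(asthmatic, ht, c("beta_blocker", "thiazide"), AS_OF)
  kinds <- vapply(cards, `[[`, "", "kind")
  expect_equal(kinds, c("contraindication_warning", "medication_suggestion"))
  expect_match(cards[[1]]$rationale, "asthma")

  clean <- make_patient(age = 50, conditions = "I10")
  kinds2 <- vapply(medication_advice(clean, ht, c("beta_blocker", "thiazide"), AS_OF),
                   `[[`, "", "kind")
  expect_true(all(kinds2 == "medication_suggestion"))

  # randomized condition sets vs a brute-force table scan
  set.seed(11)
  pool <- c("I10", "J45", "N18", "M10", "E11", "K21")
  for (rep in 1:50) {
    conds <- sample(pool, sample.int(4L, 1L))
    ds <- make_patient(age = 50, conditions = conds)
    for (cls in tbl$class) {
      got <- medication_advice(ds, ht, cls, AS_OF)[[1]]$kind
      expect_conflict <- any(vapply(seq_len(nrow(tbl)), function(i)
        tbl$class[i] == cls && any(startsWith(conds, tbl$icd10_prefix[i])), TRUE))
      expect_equal(got == "contraindication_warning", expect_conflict)
    }
  }
})

test_that("eGFR referral boundary is strict and retinopathy recall is yearly", {
  dm <- reg$modules$diabetes
  egfr_cards <- function(value) {
    ds <- make_patient(age = 60, conditions = "E11",
                       obs = list(obs_spec("egfr", value, months_ago = 1)))
    Filter(function(cd) cd$rule_id == "egfr_nephrology_referral",
           referral_advice(ds, dm, AS_OF))
  }
  expect_length(egfr_cards(55), 1L)
  expect_length(egfr_cards(59.9), 1L)
  expect_length(egfr_cards(60), 0L)   # strict "below 60"
  expect_length(egfr_cards(75), 0L)

  # expired eGFR must not trigger the referral
  stale <- make_patient(age = 60, conditions = "E11",
                        obs = list(obs_spec("egfr", 50, months_ago = 20)))
  expect_length(Filter(function(cd) cd$rule_id == "egfr_nephrology_referral",
                       referral_advice(stale, dm, AS_OF)), 0L)

  with_referral <- function(months_ago) {
    ds <- make_patient(age = 60, conditions = "E11")
    enc_date <- add_months(AS_OF, -months_ago)
    ds$encounters[[1]] <- encounter_record("diabetes", "monitoring", enc_date)
    ds$care_plans[[1]] <- care_plan_record(
      ds$patient$patient_id, sprintf("diabetes-%s", format(enc_date)),
      activities = list(care_plan_activity(
        "referral", coded_concept("urn:dmp:code", "specialty-ophthalmology", "Ophthalmology"),
        "retinopathy check")))
    Filter(function(cd) cd$rule_id == "dm_retinopathy_check",
           referral_advice(ds, dm, AS_OF, track = "monitoring"))
  }
  expect_length(with_referral(14), 1L)  # older than a year: due again
  expect_length(with_referral(6), 0L)   # recent: no card
})

test_that("follow-up intervals resolve by risk with default fallback", {
  cv <- reg$modules$cvd_risk
  expect_equal(follow_up_interval(cv, "screening", AS_OF, "low")$months, 24)
  expect_equal(follow_up_interval(cv, "screening", AS_OF, "high")$months, 12)
  expect_equal(follow_up_interval(cv, "screening", AS_OF)$months, 24)
  ht <- reg$modules$hypertension
  fu <- follow_up_interval(ht, "monitoring", AS_OF)
  expect_equal(fu$months, 3)
  expect_equal(fu$card$payload$due_date, "2023-09-01")
})

test_that("the cardiovascular-module prompt fires for over-40s without a risk score", {
  ht <- reg$modules$hypertension
  no_score <- make_patient(age = 45)
  cards <- module_transition_check(no_score, ht, AS_OF, track = "monitoring")
  expect_true(any(vapply(cards, function(cd) cd$rule_id == "missing_cvd_risk_prompt", TRUE)))

  scored <- make_patient(age = 45, obs = list(obs_spec("score10y", 3, months_ago = 6)))
  cards2 <- module_transition_check(scored, ht, AS_OF, track = "monitoring")
  expect_false(any(vapply(cards2, function(cd) cd$rule_id == "missing_cvd_risk_prompt", TRUE)))

  young <- make_patient(age = 38)
  cards3 <- module_transition_check(young, ht, AS_OF, track = "monitoring")
  expect_false(any(vapply(cards3, function(cd) cd$rule_id == "missing_cvd_risk_prompt", TRUE)))

  # prompt is tied to monitoring encounters of hypertension/diabetes
  cards4 <- module_transition_check(no_score, reg$modules$obesity, AS_OF, track = "monitoring")
  expect_false(any(vapply(cards4, function(cd) cd$rule_id == "missing_cvd_risk_prompt", TRUE)))
})

test_that("rule families are pure: identical inputs give identical card lists", {
  ds <- make_patient(age = 60, conditions = "E11",
                     obs = list(obs_spec("egfr", 55, months_ago = 1)))
  dm <- reg$modules$diabetes
  expect_identical(referral_advice(ds, dm, AS_OF), referral_advice(ds, dm, AS_OF))
  expect_identical(recommend_goals(ds, dm, AS_OF), recommend_goals(ds, dm, AS_OF))
  expect_identical(required_lab_panel(ds, dm, AS_OF), required_lab_panel(ds, dm, AS_OF))
})

test_that("discovery lists nine services and invocation matches the library layer", {
  disc <- cds_discovery()
  expect_length(disc$services, 9L)
  expect_true(all(vapply(disc$services, function(s) nzchar(s$id) && nzchar(s$hook), TRUE)))

  ds <- make_patient(age = 60, conditions = "E11",
                     obs = list(obs_spec("egfr", 55, months_ago = 1)))
  req <- hooks_request(ds, context = list(moduleId = "diabetes", track = "monitoring"))
  resp <- cds_invoke("lab-based-referral", req, reg, as_of = AS_OF)
  expect_length(resp$cards, 1L)
  expect_true(validate_hooks_response(resp)$valid)

  lib_cards <- Filter(function(cd) cd$rule_id == "egfr_nephrology_referral",
                      referral_advice(ds, reg$modules$diabetes, AS_OF, "monitoring"))
  lib_json <- jsonlite::toJSON(lapply(lib_cards, dmpkit:::card_to_hooks_json),
                               auto_unbox = TRUE, digits = NA)
  srv_json <- jsonlite::toJSON(resp$cards, auto_unbox = TRUE, digits = NA)
  expect_identical(as.character(srv_json), as.character(lib_json))
})

test_that("invocation handles empty prefetch and malformed requests gracefully", {
  resp <- cds_invoke("lab-panel", list(hook = "patient-view", hookInstance = "i1",
                                       context = list(patientId = "p1"),
                                       prefetch = list()), reg, as_of = AS_OF)
  expect_gte(length(resp$cards), 1L)
  expect_true(validate_hooks_response(resp)$valid)

  expect_error(cds_invoke("lab-panel", list(context = list()), reg), "invalid CDS Hooks request")
  expect_error(cds_invoke("nonexistent-service", list(), reg), "unknown service")
})
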