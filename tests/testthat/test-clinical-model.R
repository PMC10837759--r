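test_that("bundle reader maps supported resources and rejects bad patient counts", {
  ds <- make_patient("p1", obs = list(obs_spec("sbp", 130), obs_spec("fpg", 95)))
  bundle <- write_bundle(ds)
  back <- read_bundle(bundle)
  expect_length(back$observations, 2L)
  expect_identical(back, ds)

  no_patient <- list(resourceType = "Bundle", type = "collection", entry = list())
  expect_error(read_bundle(no_patient), "exactly one Patient")
  expect_error(read_bundle(list(resourceType = "Patient")), "not a FHIR Bundle")
})

test_that("unsupported resource types are skipped with a warning, not an error", {
  ds <- make_patient("p1")
  bundle <- write_bundle(ds)
  bundle$entry <- c(bundle$entry, list(list(resource = list(resourceType = "Claim", id = "c1"))))
  expect_warning(back <- read_bundle(bundle), "1 unsupported")
  expect_identical(attr(back, "skipped"), 1L)
  expect_identical(back$patient, ds$patient)
})

test_that("write-read round trip is the identity on seeded synthetic datasets", {
  pop <- test_cohort()[1:100]
  for (ds in pop) expect_identical(read_bundle(write_bundle(ds)), ds)
})

test_that("round trip survives JSON text serialisation", {
  ds <- make_patient("p9", conditions = "I10", med_classes = "antihypertensive",
                     obs = list(obs_spec("sbp", 142)))
  ds$goals[[1]] <- goal_record("sbp", "le", 140, set_date = AS_OF)
  ds$care_plans[[1]] <- care_plan_record("p9", "hypertension-2023-06-01",
    goals = list(goal_record("sbp", "le", 140, set_date = AS_OF)),
    activities = list(care_plan_activity("referral",
                                         coded_concept("urn:dmp:code", "specialty-nephrology", "Nephrology"),
                                         "eGFR below 60")))
  txt <- jsonlite::toJSON(write_bundle(ds), auto_unbox = TRUE, digits = NA)
  expect_identical(read_bundle(as.character(txt)), ds)
})

test_that("incremental merge is idempotent, identity on empty delta, and keeps newer versions", {
  ds <- make_patient("p1", conditions = "E11",
                     obs = list(obs_spec("fpg", 130, months_ago = 3)))
  empty <- make_patient("p1")
  expect_identical(merge_incremental(ds, empty)$observations, ds$observations)
  expect_identical(merge_incremental(ds, ds), ds)

  # same identity (code, date, origin), new value: delta wins
  delta <- make_patient("p1", obs = list(obs_spec("fpg", 135, months_ago = 3)))
  merged <- merge_incremental(ds, delta)
  expect_length(merged$observations, 1L)
  expect_equal(merged$observations[[1]]$value, 135)

  # different date: both kept
  delta2 <- make_patient("p1", obs = list(obs_spec("fpg", 120, months_ago = 1)))
  expect_length(merge_incremental(ds, delta2)$observations, 2L)

  expect_error(merge_incremental(ds, make_patient("other")), "different patients")
})

test_that("merge is order-insensitive for disjoint deltas", {
  base <- make_patient("p1")
  d1 <- make_patient("p1", obs = list(obs_spec("sbp", 120, months_ago = 2)))
  d2 <- make_patient("p1", obs = list(obs_spec("dbp", 80, months_ago = 2)))
  a <- merge_incremental(merge_incremental(base, d1), d2)
  b <- merge_incremental(merge_incremental(base, d2), d1)
  key <- function(ds) sort(vapply(ds$observations, function(o) o$code$code, ""))
  expect_identical(key(a), key(b))
})

test_that("latest observation respects as_of, picks the maximum date, and ages freshness", {
  ds <- make_patient("p1", obs = list(
    obs_spec("fpg", 100, date = as.Date("2022-01-01")),
    obs_spec("fpg", 110, date = as.Date("2023-01-01")),
    obs_spec("fpg", 140, date = as.Date("2024-01-01"))))  # future relative to as_of
  hit <- latest_observation(ds, "fpg", as.Date("2023-06-01"), validity_months = 12)
  expect_equal(hit$observation$value, 110)
  expect_equal(hit$freshness, "fresh")
  hit3 <- latest_observation(ds, "fpg", as.Date("2023-06-01"), validity_months = 3)
  expect_equal(hit3$observation$value, 110)
  expect_equal(hit3$freshness, "expired")
  expect_equal(latest_observation(ds, "hba1c", as.Date("2023-06-01"))$freshness, "absent")
  # age of exactly the validity period is still fresh ("exceeds" is strict)
  hit5 <- latest_observation(ds, "fpg", as.Date("2023-06-01"), validity_months = 5)
  expect_equal(hit5$freshness, "fresh")
})

test_that("care plan export validates structurally and degenerate plans stay valid", {
  plan <- care_plan_record("p1", "enc-1",
    goals = list(goal_record("ldl", "le", 2.6, set_date = AS_OF)),
    activities = list(
      care_plan_activity("referral", coded_concept("urn:dmp:code", "specialty-nephrology", "Nephrology"), "r"),
      care_plan_activity("follow_up_appointment", coded_concept("urn:dmp:module", "diabetes", "fu"),
                         "next visit", due_date = AS_OF + 90)))
  doc <- export_care_plan(plan)
  expect_length(doc$activity, 2L)
  expect_length(doc$goal, 1L)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  v <- validate_careplan_document(as.character(txt))
  expect_true(v$valid)

  empty_plan <- care_plan_record("p1", "enc-1")
  v2 <- validate_careplan_document(export_care_plan(empty_plan))
  expect_true(v2$valid)

  expect_error(care_plan_activity("follow_up_appointment",
                                  coded_concept("x", "y"), "no due date"),
               "due_date")
})

test_that("the careplan validator rejects broken documents", {
  plan <- care_plan_record("p1", "enc-1")
  doc <- export_care_plan(plan)
  doc$status <- "bogus"
  expect_false(validate_careplan_document(doc)$valid)
  doc2 <- export_care_plan(plan)
  doc2$subject <- NULL
  expect_false(validate_careplan_document(doc2)$valid)
})

test_that("record constructors enforce their invariants", {
  expect_error(icd10("10I"), "not a valid ICD-10")
  expect_error(clinical_observation("sbp", Inf, effective_date = AS_OF), "finite")
  expect_error(medication_entry(coded_concept("s", "c"), "x",
                                period_start = AS_OF, period_end = AS_OF - 1),
               "precedes")
  expect_error(patient_record("p", AS_OF, "other"), "arg")
  expect_error(encounter_record("m", "screening", AS_OF, duration_minutes = -1))
})
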