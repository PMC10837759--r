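reg <- builtin_defaults()

test_that("percent applies half-up rounding and treats zero denominators as undefined", {
  expect_equal(percent(1, 2), 50.0)
  expect_equal(percent(1, 8, 1), 12.5)
  expect_equal(percent(25, 1000, 1), 2.5)
  expect_equal(percent(125, 1000, 0), 13)     # half-up, not banker's
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(4.585, 2), 4.59)
  expect_true(is.na(percent(5, 0)))
})

test_that("published coverage counts reproduce the published rates", {
  counts <- reported_counts("coverage")
  tab <- coverage_table(counts)
  expect_equal(tab$coverage_percent,
               c(22.3, 27.3, 24.4, 49.9, 23.6, 32.6, 19.2, 28.6, 12.0))
})

test_that("published monthly counts reproduce achievement rates and the overall rate from sums", {
  counts <- reported_counts("achievement")
  ach <- achievement_from_counts(counts)
  expect_equal(ach$table$achievement_percent,
               c(20.4, 14.8, 22.3, 95.8, 74.6, 13.1, 35.3, 39.6, 10.2))
  expect_equal(ach$overall, 23.1)
  # the overall rate must come from summed counts, not averaged percents
  expect_false(isTRUE(all.equal(ach$overall,
                                round_half_up(mean(ach$table$achievement_percent), 1))))
})

test_that("published encounter counts reproduce shares and the per-patient mean", {
  counts <- reported_counts("encounters")
  summ <- encounter_summary_from_counts(counts, unique_patients = 16058904)
  expect_equal(summ$table$total_share, c(35.1, 25.5, 19.0, 18.4, 2.0))
  expect_equal(summ$table$screening_share[1:4], c(30.7, 39.9, 19.7, 9.7))
  expect_equal(summ$table$monitoring_share, c(42.2, 2.8, 17.8, 32.2, 5.1))
  expect_equal(unname(summ$totals["total"]), 73715269)
  expect_equal(summ$mean_encounters_per_patient, 4.59)
})

test_that("log-based coverage counts unique patients per track (oracle check)", {
  pop <- test_cohort()
  sim <- test_sim()
  lists <- build_target_lists(pop, reg, AS_OF)
  cov <- coverage(lists, sim$encounter_log)
  # brute force with explicit set construction
  for (i in seq_len(nrow(cov))) {
    key <- paste(cov$module[i], cov$track[i], sep = "/")
    seen <- character()
    for (j in seq_len(nrow(sim$encounter_log))) {
      row <- sim$encounter_log[j, ]
      if (row$module == cov$module[i] && row$track == cov$track[i] &&
          row$patient_id %in% lists[[key]]$patient_id)
        seen <- union(seen, row$patient_id)
    }
    expect_equal(cov$covered_count[i], length(seen))
    expect_equal(cov$coverage_percent[i],
                 percent(length(seen), nrow(lists[[key]])))
  }
  # a patient with repeated encounters counts once
  expect_true(all(cov$covered_count <= cov$target_count))
})

test_that("coverage is monotone as encounters are appended", {
  pop <- test_cohort()
  sim <- test_sim()
  lists <- build_target_lists(pop, reg, AS_OF)
  log <- sim$encounter_log[order(sim$encounter_log$date), ]
  half <- coverage(lists, log[seq_len(nrow(log) %/% 2), ])
  full <- coverage(lists, log)
  m <- merge(half, full, by = c("module", "track"))
  expect_true(all(m$covered_count.y >= m$covered_count.x))
})

test_that("monthly achievement counts encounters in the month per module/track", {
  log <- data.frame(
    patient_id = c("a", "b", "c", "d"),
    module = c("diabetes", "diabetes", "diabetes", "hypertension"),
    track = c("screening", "screening", "monitoring", "screening"),
    date = as.Date(c("2023-01-05", "2023-01-20", "2023-02-01", "2023-01-10")))
  targets <- data.frame(module = c("diabetes", "hypertension"),
                        track = c("screening", "screening"),
                        target = c(4L, 2L))
  ach <- achievement(targets, log, "2023-01")
  expect_equal(ach$table$performed, c(2L, 1L))
  expect_equal(ach$table$achievement_percent, c(50.0, 50.0))
  expect_equal(ach$overall, percent(3, 6))
  zero <- achievement(targets, log[0, ], "2023-01")
  expect_equal(zero$table$achievement_percent, c(0, 0))
})

test_that("encounter summary from a log computes shares, uniqueness and sex split", {
  log <- data.frame(
    patient_id = c("a", "a", "b", "c"),
    module = c("hypertension", "hypertension", "diabetes", "hypertension"),
    track = c("screening", "monitoring", "screening", "screening"),
    date = AS_OF, sex = c("female", "female", "male", "female"))
  summ <- encounter_summary(log)
  expect_equal(summ$unique_patients, 3L)
  expect_equal(unname(summ$totals["total"]), 4)
  expect_equal(summ$mean_encounters_per_patient, round_half_up(4 / 3, 2))
  expect_equal(summ$sex_shares[["female"]], percent(2, 3))
  ht_row <- summ$table[summ$table$module == "hypertension", ]
  expect_equal(ht_row$total_share, percent(3, 4))

  empty <- encounter_summary(log[0, ])
  expect_true(is.na(empty$mean_encounters_per_patient))
})

test_that("single patient, single encounter: share 100.0 and mean 1.00", {
  log <- data.frame(patient_id = "a", module = "diabetes", track = "screening",
                    date = AS_OF)
  summ <- encounter_summary(log)
  expect_equal(summ$table$total_share, 100.0)
  expect_equal(summ$mean_encounters_per_patient, 1.00)
})

test_that("goal achievement assesses only reassessed goals and honours comparators", {
  ds <- make_patient("p1", age = 60)
  ds$goals <- list(
    goal_record("sbp", "le", 140, set_date = AS_OF - 200),   # reassessed, achieved
    goal_record("ldl", "le", 2.6, set_date = AS_OF - 200),   # reassessed, missed
    goal_record("hba1c", "le", 7, set_date = AS_OF - 200))   # never reassessed
  ds$observations <- list(
    clinical_observation("sbp", 135, effective_date = AS_OF - 100, origin = "encounter_entry"),
    clinical_observation("ldl", 3.2, effective_date = AS_OF - 100, origin = "encounter_entry"),
    clinical_observation("hba1c", 6.5, effective_date = AS_OF - 300, origin = "ehr_sync"))
  tab <- goal_achievement(list(ds), AS_OF)
  expect_setequal(tab$parameter, c("sbp", "ldl"))  # hba1c not in the denominator
  expect_equal(tab$achieved[tab$parameter == "sbp"], 1L)
  expect_equal(tab$achieved[tab$parameter == "ldl"], 0L)
  expect_equal(tab$achievement_percent[tab$parameter == "sbp"], 100.0)
})

test_that("goal achievement agrees with a brute-force scan over a synthetic cohort", {
  pop <- test_cohort()[1:60]
  set.seed(31)
  for (i in seq_along(pop)) {
    ds <- pop[[i]]
    if (runif(1) < 0.6) {
      ds$goals[[length(ds$goals) + 1L]] <- goal_record("sbp", "le", 140, set_date = AS_OF - 300)
      if (runif(1) < 0.7)
        ds$observations[[length(ds$observations) + 1L]] <- clinical_observation(
          "sbp", round(runif(1, 110, 180)), effective_date = AS_OF - 50,
          origin = "encounter_entry")
    }
    pop[[i]] <- ds
  }
  tab <- goal_achievement(pop, AS_OF)
  # brute force
  assessed <- 0L; achieved <- 0L
  sbp_cc <- param_concept("sbp")
  for (ds in pop) for (g in ds$goals) {
    if (g$parameter$code != sbp_cc$code) next
    later <- Filter(function(o) o$code$code == sbp_cc$code &&
                      o$effective_date > g$set_date & o$effective_date <= AS_OF,
                    ds$observations)
    if (length(later) == 0L) next
    assessed <- assessed + 1L
    vals <- vapply(later, `[[`, 0, "value")
    dts <- vapply(later, function(o) as.integer(o$effective_date), 0L)
    if (vals[which.max(dts)] <= g$target_value) achieved <- achieved + 1L
  }
  row <- tab[tab$parameter == "sbp", ]
  expect_equal(row$assessed, assessed)
  expect_equal(row$achieved, achieved)
})

test_that("panel view restricts lists to the practitioner and flags heavy panels exempt", {
  pop <- test_cohort()
  fmp <- pop[[1]]$patient$assigned_fmp
  pv <- panel_view(fmp, pop, reg, AS_OF)
  expect_false(pv$exempt)
  expect_gt(pv$panel_size, 0L)
  global <- build_target_lists(pop, reg, AS_OF)
  panel_ids <- vapply(Filter(function(d) identical(d$patient$assigned_fmp, fmp), pop),
                      function(d) d$patient$patient_id, "")
  for (key in names(pv$lists))
    expect_setequal(pv$lists[[key]]$patient_id,
                    intersect(global[[key]]$patient_id, panel_ids))

  unknown <- panel_view("fmp-does-not-exist", pop, reg, AS_OF)
  expect_equal(unknown$panel_size, 0L)
  expect_match(unknown$notice, "no patients")

  # exemption boundary: panels over 4000 are exempt
  big <- lapply(seq_len(4001L), function(i) {
    patient_dataset(patient_record(sprintf("x%04d", i), as.Date("1970-01-01"),
                                   "female", "fmp-big"))
  })
  pv_big <- panel_view("fmp-big", big, module_registry(), AS_OF)
  expect_true(pv_big$exempt)
})
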