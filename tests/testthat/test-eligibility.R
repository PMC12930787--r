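test_that("inclusion uses strict 1500 g / 32 week thresholds and the 120-day window", {
  pts <- dplyr::bind_rows(
    make_patient("A", birth_weight = 1499L, gestational_weeks = 33L,
                 gestational_days = 0L),
    make_patient("B", birth_weight = 1500L, gestational_weeks = 32L,
                 gestational_days = 0L),
    make_patient("C", birth_weight = 1500L, gestational_weeks = 31L,
                 gestational_days = 6L),
    make_patient("D", birth_weight = 900L, admission_date = d0 + 121L,
                 end_date = d0 + 150L, admission_type = "transfer_later"),
    make_patient("E", birth_weight = 900L, admission_date = d0 + 120L,
                 end_date = d0 + 150L, admission_type = "transfer_later"),
    make_patient("F", birth_weight = 900L, live_born = FALSE)
  )
  res <- assess_eligibility(pts)
  expect_equal(res$included, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$exclusion_reason[res$patient_id == "B"],
               "weight_and_gestation_above_threshold")
  expect_equal(res$exclusion_reason[res$patient_id == "D"],
               "admitted_outside_window")
  expect_equal(res$exclusion_reason[res$patient_id == "F"], "not_live_born")
})

test_that("windows end at death and count every surveillance day", {
  cohort <- make_cohort(
    patients = make_patient(end_date = d0 + 29L, end_reason = "death"),
    stays = make_stay(start_date = d0, end_date = d0 + 29L)
  )
  w <- surveillance_windows(cohort)
  expect_equal(w$summary$patient_days, 30L)
  expect_equal(w$summary$end_reason, "death")
  expect_equal(range(w$days$date), c(d0, d0 + 29L))
})

test_that("absences up to 48 h are bridged, longer ones end the episode", {
  # days 1-10 and 12-20: one absent day (24 h) -> merged, 19 patient-days
  merged <- make_cohort(
    patients = make_patient(end_date = d0 + 19L),
    stays = dplyr::bind_rows(
      make_stay(start_date = d0, end_date = d0 + 9L),
      make_stay(start_date = d0 + 11L, end_date = d0 + 19L)
    )
  )
  w <- surveillance_windows(merged)
  expect_equal(w$summary$patient_days, 19L)
  expect_false((d0 + 10L) %in% w$days$date)

  # two absent days (48 h) still merge
  merged2 <- make_cohort(
    patients = make_patient(end_date = d0 + 19L),
    stays = dplyr::bind_rows(
      make_stay(start_date = d0, end_date = d0 + 9L),
      make_stay(start_date = d0 + 12L, end_date = d0 + 19L)
    )
  )
  expect_equal(surveillance_windows(merged2)$summary$patient_days, 18L)

  # days 1-10 then 14-20: three absent days (> 48 h) -> episode ends day 10
  split <- make_cohort(
    patients = make_patient(end_date = d0 + 19L),
    stays = dplyr::bind_rows(
      make_stay(start_date = d0, end_date = d0 + 9L),
      make_stay(start_date = d0 + 13L, end_date = d0 + 19L)
    )
  )
  expect_warning(w3 <- surveillance_windows(split), "outside the surveillance")
  expect_equal(w3$summary$patient_days, 10L)
  expect_equal(w3$summary$window_end, d0 + 9L)
  expect_equal(w3$summary$end_reason, "discharge_or_transfer")
})

test_that("gap length agrees with an hour-enumeration oracle at day granularity", {
  # absence of g full days == 24*g hours; merge iff <= 48
  for (g in 0:4) {
    cohort <- make_cohort(
      patients = make_patient(end_date = d0 + 14L + g),
      stays = dplyr::bind_rows(
        make_stay(start_date = d0, end_date = d0 + 4L),
        make_stay(start_date = d0 + 5L + g, end_date = d0 + 14L + g)
      )
    )
    gap_hours <- 24 * g
    w <- suppressWarnings(surveillance_windows(cohort))
    if (gap_hours <= 48) {
      expect_equal(w$summary$patient_days, 15L, info = paste("gap", g))
    } else {
      expect_equal(w$summary$patient_days, 5L, info = paste("gap", g))
    }
  }
})

test_that("window computation is invariant to stay row order", {
  stays <- dplyr::bind_rows(
    make_stay(start_date = d0 + 12L, end_date = d0 + 19L),
    make_stay(start_date = d0, end_date = d0 + 9L)
  )
  cohort <- make_cohort(patients = make_patient(end_date = d0 + 19L),
                        stays = stays)
  cohort_rev <- make_cohort(patients = make_patient(end_date = d0 + 19L),
                            stays = stays[2:1, ])
  expect_equal(surveillance_windows(cohort)$days,
               surveillance_windows(cohort_rev)$days)
})

test_that("surveillance days never precede admission nor follow the end date", {
  sim <- simulate_cohort(sim_config(n_patients = 30), seed = 11)
  w <- surveillance_windows(sim$cohort)
  joined <- dplyr::left_join(w$days, sim$cohort$patients,
                             by = "patient_id")
  expect_true(all(joined$date >= joined$admission_date))
  expect_true(all(is.na(joined$end_date) | joined$date <= joined$end_date))
})
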