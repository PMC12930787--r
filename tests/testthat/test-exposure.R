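test_that("day of life is 1-based and increments across month boundaries", {
  expect_equal(day_of_life(d0, d0), 1L)
  expect_equal(day_of_life(as.Date("2025-01-05"), as.Date("2025-01-01")), 5L)
  expect_equal(day_of_life(as.Date("2025-03-02"), as.Date("2025-02-27")), 4L)
  expect_error(day_of_life(d0 - 1, d0), "precedes")
  days <- d0 + 0:40
  expect_true(all(diff(day_of_life(days, d0)) == 1L))
})

test_that("a same-day admission and discharge still counts one patient-day", {
  cohort <- make_cohort(
    patients = make_patient(end_date = d0),
    stays = make_stay(start_date = d0, end_date = d0)
  )
  expect_equal(surveillance_windows(cohort)$summary$patient_days, 1L)
})

test_that("device-days need at least 12 cumulative hours", {
  cohort <- make_cohort(
    patients = make_patient(end_date = d0 + 2L),
    exposures = dplyr::bind_rows(
      make_exposure(date = d0, cvc = 12),
      make_exposure(date = d0 + 1, cvc = 11.5),
      make_exposure(date = d0 + 2, cvc = 24)
    )
  )
  s <- exposure_summary(cohort)
  expect_equal(s$cvc_days, 2L)
  expect_equal(s$patient_days, 3L)
})

test_that("factor days follow the configured thresholds", {
  cohort <- make_cohort(
    patients = make_patient(end_date = d0 + 3L),
    exposures = dplyr::bind_rows(
      make_exposure(date = d0, kangaroo = 1.9,
                    antibiotics = "ampicillin;gentamicin"),
      make_exposure(date = d0 + 1, kangaroo = 2.0,
                    feeding = "exclusive_breast_milk", probiotic = TRUE),
      make_exposure(date = d0 + 2, feeding = "mixed_or_formula"),
      make_exposure(date = d0 + 3, antibiotics = "ampicillin")
    )
  )
  s <- exposure_summary(cohort)
  expect_equal(s$kangaroo_days, 1L)        # 1.9 h does not count, 2.0 h does
  expect_equal(s$antibiotic_days, 2L)      # one day of dual therapy counts once
  expect_equal(s$breast_milk_days, 1L)
  expect_equal(s$probiotic_days, 1L)
  sub <- substance_days(cohort)
  expect_equal(sub$days[sub$substance == "ampicillin"], 2L)
  expect_equal(sub$days[sub$substance == "gentamicin"], 1L)
})

test_that("all-formula feeding yields zero breast-milk days", {
  cohort <- make_cohort(
    patients = make_patient(end_date = d0 + 9L),
    exposures = make_exposure(date = d0 + 0:9, feeding = "mixed_or_formula")
  )
  expect_equal(exposure_summary(cohort)$breast_milk_days, 0L)
})

test_that("device-day counts match a naive per-row scan on random grids", {
  set.seed(3)
  for (rep in 1:25) {
    n <- 20L
    hours <- function() round(runif(n, 0, 24), 1)
    ex <- make_exposure(date = d0 + 0:(n - 1))
    ex$cvc_hours <- hours(); ex$pvc_hours <- hours()
    ex$inv_hours <- hours(); ex$niv_hours <- hours()
    cohort <- make_cohort(patients = make_patient(end_date = d0 + n - 1L),
                          exposures = ex)
    s <- exposure_summary(cohort)
    expect_equal(s$cvc_days, sum(ex$cvc_hours >= 12))
    expect_equal(s$pvc_days, sum(ex$pvc_hours >= 12))
    expect_equal(s$inv_days, sum(ex$inv_hours >= 12))
    expect_equal(s$niv_days, sum(ex$niv_hours >= 12))
  }
})

test_that("every factor count is bounded by patient-days on simulated cohorts", {
  sim <- simulate_cohort(sim_config(n_patients = 40), seed = 13)
  s <- exposure_summary(sim$cohort)
  for (col in c("cvc_days", "pvc_days", "inv_days", "niv_days",
                "antibiotic_days", "breast_milk_days", "probiotic_days",
                "kangaroo_days")) {
    expect_true(all(s[[col]] >= 0 & s[[col]] <= s$patient_days), info = col)
  }
})

test_that("exposure rows outside the surveillance window are ignored with a warning", {
  cohort <- make_cohort(
    patients = make_patient(end_date = d0 + 4L),
    exposures = dplyr::bind_rows(
      make_exposure(date = d0, cvc = 24),
      make_exposure(date = d0 + 10L, cvc = 24)   # after discharge
    )
  )
  expect_warning(s <- exposure_summary(cohort), "outside surveillance")
  expect_equal(s$cvc_days, 1L)
})
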