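test_that("day-of-life bands partition all days", {
  expect_equal(band_label(c(1, 3, 4, 7, 8, 14, 15, 28, 29, 400)),
               c("1-3", "1-3", "4-7", "4-7", "8-14", "8-14", "15-28",
                 "15-28", "29+", "29+"))
  edges <- c(1L, 8L, 29L)
  expect_equal(band_label(c(1, 7, 8, 28, 29), edges),
               c("1-7", "1-7", "8-28", "8-28", "29+"))
})

test_that("risk days land in the right stratum x band cells and conserve totals", {
  cohort <- make_cohort(
    patients = make_patient(birth_weight = 600L, end_date = d0 + 19L),
    stays = make_stay(end_date = d0 + 19L)
  )
  w <- surveillance_windows(cohort)
  rd <- tabulate_risk_days(w, cohort$patients, edges = c(1L, 8L, 29L))
  expect_equal(rd$patient_days[rd$stratum == "500-999 g" & rd$band == "1-7"], 7L)
  expect_equal(rd$patient_days[rd$stratum == "500-999 g" & rd$band == "8-28"], 13L)
  expect_equal(sum(rd$patient_days), 20L)

  # empty cohort: all cells zero
  rd0 <- tabulate_risk_days(surveillance_windows(neo_cohort()),
                            neo_cohort()$patients)
  expect_true(all(rd0$patient_days == 0L))

  # conservation on a random cohort
  sim <- simulate_cohort(sim_config(n_patients = 35), seed = 31)
  ws <- surveillance_windows(sim$cohort)
  rds <- tabulate_risk_days(ws, sim$cohort$patients)
  expect_equal(sum(rds$patient_days), sum(ws$summary$patient_days))
})

test_that("expected infections are linear in rates and days", {
  rd <- tidyr::expand_grid(stratum = c("<500 g", "500-999 g"),
                           band = c("1-3", "4+"))
  rd$patient_days <- c(1000L, 1500L, 2000L, 500L)
  ref <- reference_rates(dplyr::mutate(rd, rate = 0.002), edges = c(1L, 4L))
  expect_equal(expected_infections(rd, ref), 0.002 * 5000)
  ref0 <- reference_rates(dplyr::mutate(rd, rate = 0), edges = c(1L, 4L))
  expect_equal(expected_infections(rd, ref0), 0)
  # hand tally with two distinct rates
  ref2 <- reference_rates(dplyr::mutate(rd, rate = c(0.001, 0.002, 0.003, 0.004)),
                          edges = c(1L, 4L))
  expect_equal(expected_infections(rd, ref2),
               1000 * 0.001 + 1500 * 0.002 + 2000 * 0.003 + 500 * 0.004)
  # an occupied cell without a reference rate is an error naming the cell
  ref_na <- reference_rates(dplyr::mutate(rd, rate = c(NA, 0.002, 0.003, 0.004)),
                            edges = c(1L, 4L))
  expect_error(expected_infections(rd, ref_na), "<500 g, 1-3")
})

test_that("the SIR is observed over expected with guarded edge cases", {
  expect_identical(standardized_infection_ratio(10, 10)$sir, 1)
  expect_equal(standardized_infection_ratio(0, 4)$sir, 0)
  expect_equal(standardized_infection_ratio(6, 4)$sir, 1.5)
  expect_error(standardized_infection_ratio(-1, 4), "negative")
  expect_warning(res <- standardized_infection_ratio(3, 0), "incalculable")
  expect_true(is.na(res$sir))
  expect_equal(res$observed, 3L)
})

test_that("pooling reference data is idempotent and averages equal-weight units", {
  sim <- simulate_cohort(sim_config(n_patients = 40), seed = 41)
  cells <- unit_cells(sim$cohort)
  ref1 <- aggregate_reference(list(cells))
  expect_equal(ref1$rate,
               ifelse(cells$patient_days == 0, NA_real_,
                      cells$infections / cells$patient_days))

  # two units with equal denominators: pooled rate is the mean of rates
  c2 <- cells
  c2$infections <- rev(cells$infections)
  ref2 <- aggregate_reference(list(cells, c2))
  both_pos <- cells$patient_days > 0
  expect_equal(ref2$rate[both_pos],
               ((cells$infections / cells$patient_days +
                   c2$infections / c2$patient_days) / 2)[both_pos])

  # mismatched band edges refuse to pool
  c3 <- unit_cells(sim$cohort, edges = c(1L, 8L, 29L))
  expect_error(aggregate_reference(list(cells, c3)), "band edges")
})

test_that("a unit benchmarked against itself has SIR 1 in aggregate and per cell", {
  sim <- simulate_cohort(sim_config(n_patients = 60, hazards = c(
    bloodstream = 0.008, respiratory = 0.003, gastrointestinal = 0.002
  )), seed = 43)
  w <- surveillance_windows(sim$cohort)
  h <- classify_cohort(sim$cohort, windows = w)
  cells <- unit_cells(sim$cohort, w, h)
  ref <- aggregate_reference(list(cells))
  risk <- tabulate_risk_days(w, sim$cohort$patients)
  res <- standardized_infection_ratio(sum(cells$infections),
                                      expected_infections(risk, ref))
  expect_gt(res$observed, 0)
  expect_equal(res$sir, 1)
  # per-cell self-consistency wherever the cell has events
  occupied <- cells$infections > 0
  cell_sir <- cells$infections[occupied] /
    (ref$rate[occupied] * cells$patient_days[occupied])
  expect_equal(cell_sir, rep(1, sum(occupied)))
})

test_that("SIR is monotone in observed and expected", {
  expect_gt(standardized_infection_ratio(12, 10)$sir,
            standardized_infection_ratio(10, 10)$sir)
  expect_lt(standardized_infection_ratio(10, 12)$sir,
            standardized_infection_ratio(10, 10)$sir)
})
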