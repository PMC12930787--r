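defs <- default_definitions()
cat <- default_organisms()

episodes_of <- function(findings = NULL, micro = NULL) {
  f <- if (is.null(findings)) neo_cohort()$findings else findings
  m <- if (is.null(micro)) neo_cohort()$microbiology else micro
  el <- assemble_episodes(f, m, defs)
  split(el, el$episode_id)
}

test_that("episode assembly respects the gap and span limits", {
  f <- dplyr::bind_rows(
    make_finding(date = d0), make_finding(date = d0 + 2),
    make_finding(date = d0 + 4)
  )
  expect_length(episodes_of(f), 1L)   # gaps of 2 days, span 4

  f2 <- dplyr::bind_rows(make_finding(date = d0), make_finding(date = d0 + 5))
  expect_length(episodes_of(f2), 2L)  # gap of 5 > 3 days

  # elements drifting past the 10-day span break into a new episode
  f3 <- dplyr::bind_rows(lapply(seq(0, 12, by = 2),
                                function(k) make_finding(date = d0 + k)))
  eps <- episodes_of(f3)
  expect_length(eps, 2L)
})

test_that("episode partition matches the brute-force chaining oracle", {
  set.seed(11)
  for (rep in 1:50) {
    dates <- sort(d0 + sample(0:40, sample(3:15, 1), replace = TRUE))
    f <- dplyr::bind_rows(lapply(dates, function(dd) make_finding(date = dd)))
    el <- assemble_episodes(f, neo_cohort()$microbiology, defs)
    got <- as.integer(factor(el$episode_id, levels = unique(el$episode_id)))
    want <- oracle_partition(el$date, defs$parameters$episode_max_gap_days,
                             defs$parameters$episode_max_span_days)
    expect_equal(got, want)
  }
})

test_that("the infection date is the earlier of symptoms and primary-site positivity", {
  micro9 <- make_micro(date = d0 + 8)    # blood culture day 9
  f10 <- make_finding(date = d0 + 9)     # symptoms day 10
  ep <- episodes_of(f10, micro9)[[1]]
  expect_equal(determine_infection_date(ep), d0 + 8)

  micro12 <- make_micro(date = d0 + 11)
  ep2 <- episodes_of(f10, micro12)[[1]]
  expect_equal(determine_infection_date(ep2), d0 + 9)

  ep3 <- episodes_of(f10)[[1]]
  expect_equal(determine_infection_date(ep3), d0 + 9)
})

test_that("late onset means >= 72 h: day of life 4 at date granularity", {
  expect_false(is_late_onset(d0 + 2, d0))   # day of life 3
  expect_true(is_late_onset(d0 + 3, d0))    # day of life 4
  expect_true(is_late_onset(d0 + 4, d0))
  # hour arithmetic when both times are known: birth 08:00, onset 09:00 +3d = 73 h
  onset <- as.POSIXct("2025-01-04 09:00", tz = "UTC")
  expect_true(is_late_onset(onset, d0, birth_time = "08:00"))
  onset_early <- as.POSIXct("2025-01-04 07:00", tz = "UTC")  # 71 h
  expect_false(is_late_onset(onset_early, d0, birth_time = "08:00"))
})

test_that("bloodstream episodes classify by organism class with lab precedence", {
  # recognized pathogen alone suffices
  ep <- episodes_of(micro = make_micro(organism = "escherichia_coli"))[[1]]
  expect_equal(classify_episode(ep, cat, defs), "lcbsi_pathogen")

  # a commensal culture without clinical+laboratory findings is nothing
  ep2 <- episodes_of(micro = make_micro(organism = "staphylococcus_epidermidis"))[[1]]
  expect_true(is.na(classify_episode(ep2, cat, defs)))

  # commensal plus clinical and laboratory findings
  f <- dplyr::bind_rows(
    make_finding(date = d0, code = "CLIN_SEPSIS_SIGN"),
    make_finding(date = d0 + 1, code = "LAB_SEPSIS_MARKER")
  )
  ep3 <- episodes_of(f, make_micro(organism = "staphylococcus_epidermidis"))[[1]]
  expect_equal(classify_episode(ep3, cat, defs), "lcbsi_commensal")

  # same findings with no organism: clinical sepsis
  ep4 <- episodes_of(f)[[1]]
  expect_equal(classify_episode(ep4, cat, defs), "clinical_sepsis")

  # pathogen outranks commensal when both grow
  both <- dplyr::bind_rows(
    make_micro(organism = "escherichia_coli"),
    make_micro(organism = "staphylococcus_epidermidis")
  )
  ep5 <- episodes_of(f, both)[[1]]
  expect_equal(classify_episode(ep5, cat, defs), "lcbsi_pathogen")
})

test_that("pneumonia needs clinical, imaging and laboratory findings; NEC accepts surgical evidence alone", {
  resp <- dplyr::bind_rows(
    make_finding(date = d0, code = "CLIN_RESP_SIGN"),
    make_finding(date = d0 + 1, code = "PNEU_IMAGING")
  )
  expect_true(is.na(classify_episode(episodes_of(resp)[[1]], cat, defs)))
  resp_full <- dplyr::bind_rows(resp,
    make_finding(date = d0 + 1, code = "LAB_INFECTION_MARKER"))
  expect_equal(classify_episode(episodes_of(resp_full)[[1]], cat, defs),
               "pneumonia")

  expect_equal(
    classify_episode(episodes_of(make_finding(date = d0, code = "NEC_SURGICAL"))[[1]],
                     cat, defs),
    "nec"
  )
  expect_true(is.na(
    classify_episode(episodes_of(make_finding(date = d0, code = "CLIN_NEC_SIGN"))[[1]],
                     cat, defs)
  ))
})

test_that("device association needs a 3-day run ending at onset or the day before", {
  mk_ex <- function(days) make_exposure(date = d0 + days, cvc = 24)
  # CVC days 5,6,7; onset day 8 -> run ends the day before onset
  expect_equal(assess_device_association(d0 + 7, mk_ex(4:6), "lcbsi_pathogen"),
               "CVC")
  # run of two days only
  expect_equal(assess_device_association(d0 + 6, mk_ex(4:5), "lcbsi_pathogen"),
               "none")
  # run ending two days before onset does not qualify
  expect_equal(assess_device_association(d0 + 8, mk_ex(3:6), "lcbsi_pathogen"),
               "none")
  # CVC outranks PVC when both qualify
  ex <- make_exposure(date = d0 + 4:7, cvc = 24, pvc = 24)
  expect_equal(assess_device_association(d0 + 7, ex, "lcbsi_commensal"), "CVC")
  # pneumonia is assessed against ventilation, not catheters
  expect_equal(assess_device_association(d0 + 7, mk_ex(4:6), "pneumonia"),
               "none")
  ex_niv <- make_exposure(date = d0 + 4:6, niv = 24)
  expect_equal(assess_device_association(d0 + 7, ex_niv, "pneumonia"), "NIV")
})

test_that("device association matches the run-enumeration oracle on random grids", {
  set.seed(23)
  for (rep in 1:60) {
    n <- 15L
    hrs <- sample(c(0, 6, 12, 24), n, replace = TRUE)
    ex <- make_exposure(date = d0 + 0:(n - 1))
    ex$cvc_hours <- hrs
    onset <- d0 + sample(0:(n - 1), 1)
    got <- assess_device_association(onset, ex, "lcbsi_pathogen")
    want <- oracle_device_assoc(ex$date[ex$cvc_hours >= 12], onset)
    expect_equal(got == "CVC", want, info = paste("rep", rep))
  }
})

test_that("SSI attribution honours the 30-day and implant-extended 90-day windows", {
  sg <- make_surgery(date = d0 + 9)                       # surgery day 10
  sgi <- make_surgery(date = d0 + 9, implant = TRUE)
  expect_equal(attribute_ssi(d0 + 39, "superficial", sg)$surgery_id, "S1")   # 30 d after
  expect_null(attribute_ssi(d0 + 40, "superficial", sg))                     # 31 d after
  expect_equal(attribute_ssi(d0 + 79, "organ_space", sgi)$hai_type,
               "ssi_organ_space")                                            # 70 d, implant
  expect_null(attribute_ssi(d0 + 79, "organ_space", sg))                     # no implant
  expect_null(attribute_ssi(d0 + 44, "superficial", sgi))                    # no extension
  expect_equal(attribute_ssi(d0 + 99, "deep", sgi)$surgery_id, "S1")         # 90 d
  expect_null(attribute_ssi(d0 + 100, "deep", sgi))                          # 91 d
  # most recent qualifying surgery wins
  two <- dplyr::bind_rows(make_surgery("S1", date = d0),
                          make_surgery("S2", date = d0 + 5))
  expect_equal(attribute_ssi(d0 + 10, "superficial", two)$surgery_id, "S2")
})

test_that("repeat infections inside 14 days are merged, later ones are new", {
  base <- tibble::tibble(
    patient_id = "P1", body_system = "bloodstream",
    hai_type = c("lcbsi_pathogen", "lcbsi_pathogen"),
    infection_date = c(d0, d0 + 9),
    episode_start = c(d0, d0 + 9), episode_end = c(d0 + 1, d0 + 10),
    organisms = c("escherichia_coli", "klebsiella_pneumoniae"),
    resistance_markers = c(NA_character_, "3GCR")
  )
  kept <- suppress_repeats(base)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$n_merged, 1L)
  expect_equal(kept$organisms, "escherichia_coli;klebsiella_pneumoniae")
  expect_equal(kept$resistance_markers, "3GCR")

  later <- base
  later$infection_date[2] <- d0 + 14
  later$episode_start[2] <- d0 + 14
  later$episode_end[2] <- d0 + 15
  expect_equal(nrow(suppress_repeats(later)), 2L)

  # 14 days elapsed but no symptom-free day in between: still suppressed
  crowded <- later
  crowded$episode_end[1] <- d0 + 13
  expect_equal(nrow(suppress_repeats(crowded)), 1L)
})

test_that("repeat suppression equals the greedy oracle on random event streams", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    inf <- sort(d0 + sample(0:60, n))
    ends <- inf + sample(0:2, n, replace = TRUE)
    df <- tibble::tibble(
      patient_id = "P1", body_system = "bloodstream",
      hai_type = "clinical_sepsis", infection_date = inf,
      episode_start = inf, episode_end = ends,
      organisms = NA_character_, resistance_markers = NA_character_
    )
    kept <- suppress_repeats(df)
    want <- oracle_suppress(inf, inf, ends)
    expect_equal(kept$infection_date, inf[want])
  }
})

test_that("MDRO flagging unions markers over organisms", {
  expect_true(flag_mdro("MRSA"))
  expect_false(flag_mdro(NA_character_))
  expect_equal(flag_mdro(c("3GCR;carbapenem_resistant", NA, "")),
               c(TRUE, FALSE, FALSE))
})

test_that("secondary bloodstream infections link to active primaries", {
  mk <- function(type, bs, date, orgs = NA_character_) {
    tibble::tibble(
      patient_id = "P1", body_system = bs, hai_type = type,
      infection_date = date, episode_start = date, episode_end = date + 1,
      organisms = orgs, resistance_markers = NA_character_
    )
  }
  # NEC (no organisms) day 12, LCBSI day 14 -> secondary by temporal overlap
  pair <- dplyr::bind_rows(mk("nec", "gastrointestinal", d0 + 11),
                           mk("lcbsi_pathogen", "bloodstream", d0 + 13,
                              "escherichia_coli"))
  out <- link_secondary_bsi(pair)
  expect_true(out$secondary[out$hai_type == "lcbsi_pathogen"])

  # LCBSI long after the primary's active window -> primary
  late <- dplyr::bind_rows(mk("pneumonia", "respiratory", d0,
                              "escherichia_coli"),
                           mk("lcbsi_pathogen", "bloodstream", d0 + 20,
                              "escherichia_coli"))
  expect_false(link_secondary_bsi(late)$secondary[2])

  # organism mismatch with a documented primary organism -> primary
  mism <- dplyr::bind_rows(mk("pneumonia", "respiratory", d0 + 10,
                              "escherichia_coli"),
                           mk("lcbsi_pathogen", "bloodstream", d0 + 12,
                              "klebsiella_pneumoniae"))
  expect_false(link_secondary_bsi(mism)$secondary[2])
})

test_that("classification is invariant under input row shuffling", {
  sim <- simulate_cohort(sim_config(n_patients = 30, hazards = c(
    bloodstream = 0.01, respiratory = 0.004, gastrointestinal = 0.003
  )), seed = 19)
  base <- classify_cohort(sim$cohort)
  shuffled <- sim$cohort
  set.seed(1)
  for (nm in c("findings", "microbiology", "exposures", "stays")) {
    shuffled[[nm]] <- shuffled[[nm]][sample(nrow(shuffled[[nm]])), ]
  }
  expect_equal(classify_cohort(shuffled), base)
})

test_that("every counted infection is late-onset", {
  sim <- simulate_cohort(sim_config(n_patients = 60, hazards = c(
    bloodstream = 0.01, respiratory = 0.004, gastrointestinal = 0.003
  )), seed = 29)
  h <- classify_cohort(sim$cohort)
  expect_true(all(h$day_of_life >= 4))
})
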