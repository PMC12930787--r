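# Seeded synthetic-cohort generator. Produces the six input tables of a
# neonatal unit plus the planted ground truth, so that every surveillance
# rule can be exercised and recovered without real data. A single RNG
# stream (set from the seed) is consumed in a fixed order: patients in
# sequence, and per patient demographics, stay layout, day-by-day
# exposures, day-by-day infection events and noise findings, then
# surgeries and surgical site infections.

SIM_SUBSTANCES <- c("ampicillin", "gentamicin", "vancomycin", "meropenem",
                    "cefotaxime")

# Resistance markers an organism can plausibly carry in simulation.
SIM_MARKERS <- list(
  staphylococcus_aureus = "MRSA",
  escherichia_coli = c("3GCR", "carbapenem_resistant", "colistin_resistant"),
  klebsiella_pneumoniae = c("3GCR", "carbapenem_resistant"),
  enterobacter_cloacae = "3GCR",
  serratia_marcescens = "3GCR",
  pseudomonas_aeruginosa = "carbapenem_resistant",
  enterococcus_faecalis = "VRE",
  enterococcus_faecium = "VRE"
)
SIM_PATHOGENS <- c("staphylococcus_aureus", "escherichia_coli",
                   "klebsiella_pneumoniae", "enterobacter_cloacae",
                   "serratia_marcescens", "pseudomonas_aeruginosa",
                   "enterococcus_faecalis", "enterococcus_faecium",
                   "streptococcus_agalactiae", "candida_albicans")
SIM_COMMENSALS <- c("staphylococcus_epidermidis", "staphylococcus_capitis",
                    "corynebacterium_species", "micrococcus_species",
                    "bacillus_species")

#' Simulation configuration
#'
#' Parameters of the synthetic neonatal cohort. Defaults describe a
#' plausible mixed-acuity unit: the birth-weight mix is weighted towards
#' the 500-1499 g strata, stays are geometric with a mean of 30 days,
#' device use comes in multi-day runs, and per-day infection hazards are
#' on the order of a few events per 1000 patient-days, with bloodstream
#' infections the most common type. Hazards may be given as one number
#' per body system (uniform over strata and day-of-life bands) or as a
#' full `hazard_table` with columns `body_system`, `stratum`, `band`,
#' `hazard`.
#'
#' @param n_patients Number of infants.
#' @param stratum_probs Probabilities of the four birth-weight strata.
#' @param mean_los_days,min_los_days Length-of-stay distribution
#'   (geometric above the minimum).
#' @param death_prob,transfer_in_prob,absence_prob Probabilities of death
#'   as end reason, admission by later transfer, and of one short (1-2
#'   day) mid-stay absence.
#' @param device_start_prob,device_mean_duration Named per-device
#'   (`cvc`, `pvc`, `inv`, `niv`) daily start probabilities and mean run
#'   lengths in days.
#' @param antibiotic_start_prob,antibiotic_mean_duration Antibiotic
#'   course dynamics.
#' @param breast_milk_prob,probiotic_prob,kangaroo_prob Daily
#'   protective-factor probabilities.
#' @param hazards Named per-day infection hazards for `bloodstream`,
#'   `respiratory`, `gastrointestinal`.
#' @param hazard_table Optional per-cell hazard table overriding
#'   `hazards`.
#' @param bloodstream_mix Mixture over the three bloodstream infection
#'   types.
#' @param nec_surgical_evidence_prob Probability a NEC event is planted
#'   as surgical evidence alone.
#' @param device_assoc_prob Probability a bloodstream/respiratory event
#'   gets a supporting 4-day device run planted.
#' @param organism_mdro_prob Per-organism probability of a resistance
#'   marker (where the organism can carry one).
#' @param polymicrobial_prob Probability of a second organism.
#' @param surgery_prob,second_surgery_prob,implant_prob,ssi_prob Surgery
#'   frequency, implant probability, and probability an SSI follows a
#'   surgery (onset 1-40 days after it, so some fall outside the
#'   attribution window by design).
#' @param noise_finding_rate Daily probability of an isolated,
#'   non-classifiable clinical finding.
#' @param min_event_separation_days Minimum days between planted events
#'   of the same body system; at least 8 so that episode assembly cannot
#'   merge two planted events.
#' @return A list of class `neo_sim_config`.
#' @export
sim_config <- function(n_patients = 50,
                       stratum_probs = c(0.05, 0.35, 0.45, 0.15),
                       mean_los_days = 30, min_los_days = 5,
                       death_prob = 0.04, transfer_in_prob = 0.08,
                       absence_prob = 0.08,
                       device_start_prob = c(cvc = 0.06, pvc = 0.08,
                                             inv = 0.04, niv = 0.08),
                       device_mean_duration = c(cvc = 7, pvc = 4,
                                                inv = 5, niv = 6),
                       antibiotic_start_prob = 0.05,
                       antibiotic_mean_duration = 5,
                       breast_milk_prob = 0.5, probiotic_prob = 0.4,
                       kangaroo_prob = 0.3,
                       hazards = c(bloodstream = 0.004,
                                   respiratory = 0.0015,
                                   gastrointestinal = 0.001),
                       hazard_table = NULL,
                       bloodstream_mix = c(clinical_sepsis = 0.3,
                                           lcbsi_pathogen = 0.5,
                                           lcbsi_commensal = 0.2),
                       nec_surgical_evidence_prob = 0.2,
                       device_assoc_prob = 0.5,
                       organism_mdro_prob = 0.15,
                       polymicrobial_prob = 0.1,
                       surgery_prob = 0.15, second_surgery_prob = 0.2,
                       implant_prob = 0.3, ssi_prob = 0.3,
                       noise_finding_rate = 0.003,
                       min_event_separation_days = 8) {
  cfg <- as.list(environment())
  probs <- c(cfg$stratum_probs, cfg$death_prob, cfg$transfer_in_prob,
             cfg$absence_prob, cfg$device_start_prob,
             cfg$antibiotic_start_prob, cfg$breast_milk_prob,
             cfg$probiotic_prob, cfg$kangaroo_prob, cfg$bloodstream_mix,
             cfg$nec_surgical_evidence_prob, cfg$device_assoc_prob,
             cfg$organism_mdro_prob, cfg$polymicrobial_prob,
             cfg$surgery_prob, cfg$second_surgery_prob, cfg$implant_prob,
             cfg$ssi_prob, cfg$noise_finding_rate)
  if (any(probs < 0 | probs > 1)) abort("sim_config: probabilities must be in [0,1]")
  if (any(cfg$hazards < 0)) abort("sim_config: hazards must be >= 0")
  if (cfg$min_event_separation_days < 8) {
    abort("sim_config: min_event_separation_days must be >= 8 (episode assembly guard)")
  }
  structure(cfg, class = "neo_sim_config")
}

sample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

# Draw 1-2 organisms from a pool, each with an optional resistance marker
# it can plausibly carry. Returns a tibble (organism, markers-cell).
sim_organisms <- function(pool, cfg) {
  n <- 1L + (runif(1) < cfg$polymicrobial_prob)
  orgs <- sample(pool, min(n, length(pool)))
  markers <- vapply(orgs, function(o) {
    allowed <- SIM_MARKERS[[o]]
    if (!is.null(allowed) && runif(1) < cfg$organism_mdro_prob) {
      sample1(allowed)
    } else {
      NA_character_
    }
  }, character(1))
  tibble(organism = orgs, markers = unname(markers))
}

#' Generate a synthetic surveillance cohort
#'
#' Draws a complete cohort (all six input tables) plus the planted event
#' list from a [sim_config()]. Output is deterministic under the seed.
#' Infection events are emitted as criterion-code findings spanning 1-3
#' days plus, where the type requires it, primary-site microbiology (the
#' specimen may precede symptom onset by one day, exercising the
#' infection-date rule), so the classifier can rediscover every planted
#' event; device-associated events get a supporting device run ending at
#' onset.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed fixing all output.
#' @return A list of class `neo_sim`: `cohort` (a [neo_cohort()]),
#'   `truth` (planted events, see [ground_truth()]), `config`, `seed`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 10), seed = 42)
#' sim$cohort
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "neo_sim_config"))
  cfg <- config
  set.seed(as.integer(seed))
  defs <- default_definitions()
  bw_ranges <- list(c(300L, 499L), c(500L, 999L), c(1000L, 1499L), c(1500L, 1800L))
  ga_ranges <- list(c(23L, 25L), c(24L, 28L), c(26L, 31L), c(29L, 31L))
  origin <- as.Date("2024-01-01")

  patients <- list(); stays <- list(); exposures <- list()
  surgeries <- list(); findings <- list(); micro <- list(); truth <- list()
  surgery_counter <- 0L

  for (i in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%04d", i)
    s_idx <- sample.int(4L, 1L, prob = cfg$stratum_probs)
    bw <- sample1(seq(bw_ranges[[s_idx]][1], bw_ranges[[s_idx]][2]))
    ga_w <- sample1(seq(ga_ranges[[s_idx]][1], ga_ranges[[s_idx]][2]))
    ga_d <- sample1(0:6)
    sex <- sample1(SEXES)
    dm <- sample(DELIVERY_MODES, 1, prob = c(0.4, 0.3, 0.3))
    mb <- sample(1:3, 1, prob = c(0.85, 0.12, 0.03))
    birth <- origin + sample1(0:364)
    if (runif(1) < cfg$transfer_in_prob) {
      adm_type <- "transfer_later"
      admission <- birth + sample1(1:30)
    } else {
      adm_type <- "delivery_room"
      admission <- birth
    }
    los <- cfg$min_los_days +
      rgeom(1, 1 / (cfg$mean_los_days - cfg$min_los_days + 1))
    end <- admission + los - 1L
    end_reason <- if (runif(1) < cfg$death_prob) "death" else "discharge_or_transfer"

    if (runif(1) < cfg$absence_prob && los >= 12) {
      gap_start <- admission + los %/% 2
      gap_len <- sample1(1:2)
      st <- tibble(patient_id = pid,
                   start_date = c(admission, gap_start + gap_len),
                   end_date = c(gap_start - 1L, end))
    } else {
      st <- tibble(patient_id = pid, start_date = admission, end_date = end)
    }
    surv_days <- sort(unique(do.call(c, Map(seq, st$start_date, st$end_date,
                                            by = "day"))))
    nd <- length(surv_days)

    # day grid of exposures. Devices and antibiotics come in multi-day
    # runs sampled run-by-run (geometric inter-start gaps and durations);
    # feeding, probiotics and kangaroo care are independent daily draws.
    sim_run_ids <- function(nd, start_prob, mean_dur) {
      run <- integer(nd)
      pos <- 1L
      id <- 0L
      while (pos <= nd && start_prob > 0) {
        start <- pos + rgeom(1, start_prob)
        if (start > nd) break
        dur <- 1L + rgeom(1, 1 / mean_dur)
        id <- id + 1L
        run[start:min(nd, start + dur - 1L)] <- id
        pos <- start + dur
      }
      run
    }
    exg <- tibble(
      patient_id = pid, date = surv_days,
      cvc_hours = 0, pvc_hours = 0, inv_hours = 0, niv_hours = 0,
      antibiotic_substances = NA_character_,
      enteral_feeding = NA_character_, probiotic_given = NA,
      kangaroo_hours = 0
    )
    for (dev in c("cvc", "pvc", "inv", "niv")) {
      on <- sim_run_ids(nd, cfg$device_start_prob[[dev]],
                        cfg$device_mean_duration[[dev]]) > 0L
      n_on <- sum(on)
      if (n_on > 0) {
        partial <- runif(n_on) < 0.15
        hours <- ifelse(partial, sample(c(4, 8, 10), n_on, replace = TRUE), 24)
        exg[[paste0(dev, "_hours")]][on] <- hours
      }
    }
    ab_run <- sim_run_ids(nd, cfg$antibiotic_start_prob,
                          cfg$antibiotic_mean_duration)
    if (any(ab_run > 0)) {
      courses <- vapply(seq_len(max(ab_run)), function(id) {
        join_set(sample(SIM_SUBSTANCES, sample1(1:2)))
      }, character(1))
      exg$antibiotic_substances[ab_run > 0] <- courses[ab_run[ab_run > 0]]
    }
    bm <- runif(nd) < cfg$breast_milk_prob
    alt <- sample(c("mixed_or_formula", "none"), nd, replace = TRUE,
                  prob = c(0.8, 0.2))
    exg$enteral_feeding <- ifelse(bm, "exclusive_breast_milk", alt)
    exg$probiotic_given <- runif(nd) < cfg$probiotic_prob
    kc <- runif(nd) < cfg$kangaroo_prob
    exg$kangaroo_hours <- ifelse(kc, round(runif(nd, 0.5, 5), 1), 0)

    # infection events and noise, day by day
    next_allowed <- c(bloodstream = surv_days[1], respiratory = surv_days[1],
                      gastrointestinal = surv_days[1],
                      surgical_site = surv_days[1])
    pf <- list(); pm <- list(); ptruth <- list()
    plant <- function(bs, type, onset, depth = NA_character_,
                      surgery_id = NA_character_) {
      spread_days <- as.Date(intersect(seq(onset, onset + sample1(0:2),
                                           by = "day"), surv_days),
                             origin = "1970-01-01")
      el_dates <- as.Date(character(0))
      add_finding <- function(code, date) {
        cr <- defs$criteria[[code]]
        pf[[length(pf) + 1L]] <<- tibble(
          patient_id = pid, date = date, category = cr$category,
          criterion_code = code, body_system = cr$body_system
        )
        el_dates <<- c(el_dates, date)
      }
      add_micro <- function(orgs, specimen, specimen_type) {
        pm[[length(pm) + 1L]] <<- tibble(
          patient_id = pid, specimen_date = specimen,
          specimen_type = specimen_type, organism = orgs$organism,
          resistance_markers = ifelse(is.na(orgs$markers), NA_character_,
                                      orgs$markers)
        )
        el_dates <<- c(el_dates, specimen)
      }
      specimen <- as.Date(NA)
      orgs <- tibble(organism = character(0), markers = character(0))
      symptom_onset <- as.Date(NA)
      if (bs == "bloodstream") {
        if (type != "lcbsi_pathogen" || runif(1) < 0.8) {
          add_finding("CLIN_SEPSIS_SIGN", onset)
          symptom_onset <- onset
        }
        if (type != "lcbsi_pathogen") {
          add_finding("LAB_SEPSIS_MARKER", sample1(spread_days))
        } else if (!is.na(symptom_onset) && runif(1) < 0.5) {
          add_finding("LAB_SEPSIS_MARKER", sample1(spread_days))
        }
        if (type != "clinical_sepsis") {
          pool <- if (type == "lcbsi_pathogen") SIM_PATHOGENS else SIM_COMMENSALS
          orgs <- sim_organisms(pool, cfg)
          cand <- onset + sample1(-1:1)
          specimen <- if (cand %in% surv_days) cand else onset
          add_micro(orgs, specimen, "blood")
        }
      } else if (bs == "respiratory") {
        add_finding("CLIN_RESP_SIGN", onset)
        symptom_onset <- onset
        add_finding("PNEU_IMAGING", sample1(spread_days))
        add_finding("LAB_INFECTION_MARKER", sample1(spread_days))
        if (runif(1) < 0.5) {
          orgs <- sim_organisms(SIM_PATHOGENS, cfg)
          specimen <- sample1(spread_days)
          add_micro(orgs, specimen, "respiratory")
        }
      } else if (bs == "gastrointestinal") {
        if (type == "nec_surgical") {
          add_finding("NEC_SURGICAL", onset)
          symptom_onset <- onset    # no clinical finding: date rule falls back
          type <- "nec"
        } else {
          add_finding("CLIN_NEC_SIGN", onset)
          symptom_onset <- onset
          add_finding("NEC_RADIOLOGY", sample1(spread_days))
        }
      } else if (bs == "surgical_site") {
        code <- switch(depth, superficial = "SSI_LOCAL_SIGN",
                       deep = "SSI_DEEP_SIGN", organ_space = "SSI_ORGAN_SIGN")
        add_finding(code, onset)
        symptom_onset <- onset
        if (length(spread_days) > 1 && runif(1) < 0.5) {
          add_finding(code, spread_days[2])
        }
        if (runif(1) < 0.5) {
          orgs <- sim_organisms(SIM_PATHOGENS, cfg)
          specimen <- sample1(spread_days)
          add_micro(orgs, specimen, "wound")
        }
      }
      # supporting device run ending at onset, for device-assessable types
      device_planted <- "none"
      if (bs %in% c("bloodstream", "respiratory") &&
          runif(1) < cfg$device_assoc_prob) {
        dev <- if (bs == "bloodstream") {
          if (runif(1) < 0.7) "cvc" else "pvc"
        } else {
          if (runif(1) < 0.7) "inv" else "niv"
        }
        run <- seq(onset - 3L, onset, by = "day")
        if (all(run %in% surv_days)) {
          exg[[paste0(dev, "_hours")]][match(run, exg$date)] <<- 24
          device_planted <- toupper(dev)
        }
      }
      ptruth[[length(ptruth) + 1L]] <<- tibble(
        patient_id = pid, body_system = bs, planted_type = type,
        depth = depth, onset_date = onset, symptom_onset_date = symptom_onset,
        primary_specimen_date = specimen,
        last_element_date = max(el_dates),
        organisms = join_set(orgs$organism),
        markers = join_set(orgs$markers[!is.na(orgs$markers)]),
        device_planted = device_planted, surgery_id = surgery_id
      )
    }

    # candidate event days from vectorized per-day hazard draws, then a
    # chronological pass enforcing the same-system separation rule
    stratum <- STRATA[s_idx]
    bandv <- band_label(day_of_life(surv_days, birth))
    cand <- list()
    for (bs in c("bloodstream", "respiratory", "gastrointestinal")) {
      hazv <- if (!is.null(cfg$hazard_table)) {
        ht <- cfg$hazard_table
        hz <- ht$hazard[match(paste(bs, stratum, bandv),
                              paste(ht$body_system, ht$stratum, ht$band))]
        ifelse(is.na(hz), 0, hz)
      } else {
        rep(unname(cfg$hazards[bs]), nd)
      }
      hit <- runif(nd) < hazv
      if (any(hit)) {
        cand[[bs]] <- tibble(day = surv_days[hit], bs = bs, kind = "event",
                             code = NA_character_)
      }
    }
    noise_hit <- runif(nd) < cfg$noise_finding_rate
    if (any(noise_hit)) {
      ncodes <- sample(c("CLIN_SEPSIS_SIGN", "CLIN_RESP_SIGN", "CLIN_NEC_SIGN"),
                       sum(noise_hit), replace = TRUE)
      nbs <- vapply(ncodes, function(cd) defs$criteria[[cd]]$body_system,
                    character(1))
      cand$noise <- tibble(day = surv_days[noise_hit], bs = unname(nbs),
                           kind = "noise", code = ncodes)
    }
    queue <- bind_rows(cand)
    if (nrow(queue) > 0) {
      queue <- queue[order(queue$day, match(queue$kind, c("event", "noise")),
                           match(queue$bs, c("bloodstream", "respiratory",
                                             "gastrointestinal"))), ]
      for (q in seq_len(nrow(queue))) {
        d <- queue$day[q]
        bs <- queue$bs[q]
        if (d < next_allowed[[bs]]) next
        if (queue$kind[q] == "event") {
          type <- switch(bs,
            bloodstream = sample(names(cfg$bloodstream_mix), 1,
                                 prob = cfg$bloodstream_mix),
            respiratory = "pneumonia",
            gastrointestinal = if (runif(1) < cfg$nec_surgical_evidence_prob) {
              "nec_surgical"
            } else {
              "nec"
            }
          )
          plant(bs, type, d)
        } else {
          pf[[length(pf) + 1L]] <- tibble(
            patient_id = pid, date = d, category = "clinical",
            criterion_code = queue$code[q], body_system = bs
          )
        }
        next_allowed[[bs]] <- d + cfg$min_event_separation_days
      }
    }

    # surgeries and surgical site infections
    if (runif(1) < cfg$surgery_prob && nd >= 4) {
      n_surg <- 1L + (runif(1) < cfg$second_surgery_prob)
      for (s in seq_len(n_surg)) {
        surgery_counter <- surgery_counter + 1L
        sg_date <- sample1(surv_days[seq_len(max(1, nd - 3))])
        sg_id <- sprintf("S%04d", surgery_counter)
        implant <- runif(1) < cfg$implant_prob
        surgeries[[length(surgeries) + 1L]] <- tibble(
          surgery_id = sg_id, patient_id = pid,
          description = "abdominal procedure", date = sg_date,
          duration_minutes = sample1(30:180),
          main_procedure_code = sample1(c("KDQ10", "KDJ20", "JAB30")),
          side_procedure_codes = NA_character_,
          asa_score = sample1(2:4),
          wound_class = sample1(WOUND_CLASSES),
          endoscopic = runif(1) < 0.2, emergency = runif(1) < 0.4,
          revision = s > 1, primary_wound_closure = runif(1) < 0.9,
          implant = implant, infection_signs_at_surgery = FALSE
        )
        if (runif(1) < cfg$ssi_prob) {
          onset <- sg_date + sample1(1:40)
          if (onset %in% surv_days && onset >= next_allowed[["surgical_site"]]) {
            depth <- sample1(c("superficial", "deep", "organ_space"))
            plant("surgical_site", "ssi", onset, depth = depth,
                  surgery_id = sg_id)
            next_allowed[["surgical_site"]] <- onset +
              cfg$min_event_separation_days
          }
        }
      }
    }

    patients[[i]] <- tibble(
      patient_id = pid, gestational_weeks = ga_w, gestational_days = ga_d,
      birth_weight = bw, sex = sex, delivery_mode = dm, multiple_birth = mb,
      birth_date = birth, birth_time = NA_character_,
      admission_type = adm_type, admission_date = admission,
      end_date = end, end_reason = end_reason, live_born = TRUE
    )
    stays[[i]] <- st
    exposures[[i]] <- exg
    findings <- c(findings, pf)
    micro <- c(micro, pm)
    truth <- c(truth, ptruth)
  }

  tbl_or_null <- function(lst) {
    t <- bind_rows(lst)
    if (ncol(t) == 0) NULL else t
  }
  cohort <- neo_cohort(
    patients = tbl_or_null(patients), stays = tbl_or_null(stays),
    exposures = tbl_or_null(exposures), surgeries = tbl_or_null(surgeries),
    findings = tbl_or_null(findings), microbiology = tbl_or_null(micro)
  )
  truth_tbl <- bind_rows(truth)
  if (ncol(truth_tbl) == 0) {
    truth_tbl <- tibble(
      patient_id = character(0), body_system = character(0),
      planted_type = character(0), depth = character(0),
      onset_date = as.Date(character(0)),
      symptom_onset_date = as.Date(character(0)),
      primary_specimen_date = as.Date(character(0)),
      last_element_date = as.Date(character(0)),
      organisms = character(0), markers = character(0),
      device_planted = character(0), surgery_id = character(0)
    )
  }
  structure(list(cohort = cohort, truth = truth_tbl, config = cfg,
                 seed = as.integer(seed)),
            class = "neo_sim")
}

#' Planted ground truth of a simulated cohort
#'
#' Returns the planted event list of a [simulate_cohort()] result: one
#' row per planted infection with body system, intended type, onset,
#' symptom-onset and primary-specimen dates, organisms and markers, the
#' planted device run (if any) and the causal surgery (for SSIs). The
#' truth records what was planted, before surveillance rules: recovery
#' tests apply the eligibility, late-onset, attribution and repeat rules
#' to it independently.
#'
#' @param sim A `neo_sim` object.
#' @return The truth tibble.
#' @export
ground_truth <- function(sim) {
  stopifnot(inherits(sim, "neo_sim"))
  sim$truth
}

#' @export
print.neo_sim <- function(x, ...) {
  cat(sprintf("<neo_sim> seed %d: %d patients, %d planted events\n",
              x$seed, nrow(x$cohort$patients), nrow(x$truth)))
  invisible(x)
}
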