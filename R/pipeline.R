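# Full classification pipeline: cohort tables in, HAI line list out.

empty_linelist <- function() {
  tibble(
    patient_id = character(0), body_system = character(0),
    hai_type = character(0), infection_date = as.Date(character(0)),
    day_of_life = integer(0), episode_start = as.Date(character(0)),
    episode_end = as.Date(character(0)), device_association = character(0),
    linked_surgery_id = character(0), organisms = character(0),
    resistance_markers = character(0), is_mdro = logical(0),
    n_merged = integer(0), secondary = logical(0), secondary_to = character(0)
  )
}

#' Classify all healthcare-associated infections of a cohort
#'
#' Runs the complete rule set: surveillance windows are computed,
#' findings and microbiology results falling on surveillance days are
#' assembled into candidate episodes, each episode is classified, dated,
#' and kept only when late-onset (>= 72 h after birth); surgical-site
#' episodes are attributed to a qualifying surgery (30/90-day windows)
#' and dropped otherwise; device association is assessed for bloodstream
#' infections and pneumonia; repeat episodes within the 14-day window are
#' merged into the prior infection; multidrug-resistance is flagged; and,
#' optionally, bloodstream infections secondary to an active pneumonia,
#' NEC or SSI are marked and excluded from primary counts.
#'
#' @param cohort A validated [neo_cohort()].
#' @param definitions,catalog Active configuration.
#' @param windows Precomputed [surveillance_windows()] (computed when
#'   `NULL`).
#' @param enable_secondary_bsi Mark and separate secondary bloodstream
#'   infections (optional reporting; off by default).
#' @return The HAI line list: one row per counted infection with type,
#'   infection date, day of life, episode bounds, device association,
#'   linked surgery, organisms, resistance markers, MDRO flag, number of
#'   merged repeat episodes, and secondary-BSI linkage columns.
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 20), seed = 7)
#' classify_cohort(sim$cohort)
#' @export
classify_cohort <- function(cohort, definitions = default_definitions(),
                            catalog = default_organisms(), windows = NULL,
                            enable_secondary_bsi = FALSE) {
  stopifnot(inherits(cohort, "neo_cohort"))
  if (is.null(windows)) {
    windows <- surveillance_windows(cohort, definitions)
  }
  fd <- dplyr::semi_join(cohort$findings, windows$days,
                         by = c("patient_id", "date"))
  mb <- dplyr::semi_join(
    cohort$microbiology, windows$days,
    by = c("patient_id", "specimen_date" = "date")
  )
  el <- assemble_episodes(fd, mb, definitions)
  if (nrow(el) == 0) return(empty_linelist())
  pt <- cohort$patients
  birth <- setNames(pt$birth_date, pt$patient_id)
  rows <- lapply(split(el, el$episode_id), function(ep) {
    type <- classify_episode(ep, catalog, definitions)
    if (is.na(type)) return(NULL)
    pid <- ep$patient_id[1]
    inf_date <- determine_infection_date(ep)
    if (!is_late_onset(inf_date, birth[[pid]], definitions = definitions)) {
      return(NULL)
    }
    surgery_id <- NA_character_
    if (ep$body_system[1] == "surgical_site") {
      depth <- sub("^ssi_", "", type)
      att <- attribute_ssi(inf_date, depth,
                           cohort$surgeries[cohort$surgeries$patient_id == pid, ],
                           definitions)
      if (is.null(att)) return(NULL)
      surgery_id <- att$surgery_id
      type <- att$hai_type
    }
    dev <- assess_device_association(
      inf_date, cohort$exposures[cohort$exposures$patient_id == pid, ],
      type, definitions
    )
    primary <- PRIMARY_SPECIMEN[ep$body_system[1]]
    mic <- ep[ep$source == "micro" & ep$specimen_type %in% primary, ]
    tibble(
      patient_id = pid, body_system = ep$body_system[1], hai_type = type,
      infection_date = inf_date,
      day_of_life = day_of_life(inf_date, birth[[pid]]),
      episode_start = min(ep$date), episode_end = max(ep$date),
      device_association = dev, linked_surgery_id = surgery_id,
      organisms = join_set(mic$organism),
      resistance_markers = join_set(unlist(lapply(mic$resistance_markers, split_set)))
    )
  })
  hais <- bind_rows(rows)
  if (is.null(hais) || nrow(hais) == 0) return(empty_linelist())
  hais <- suppress_repeats(hais, definitions)
  if (enable_secondary_bsi) {
    hais <- link_secondary_bsi(hais, definitions)
  } else {
    hais$secondary <- FALSE
    hais$secondary_to <- NA_character_
  }
  hais$is_mdro <- flag_mdro(hais$resistance_markers)
  hais <- hais[order(hais$patient_id, hais$infection_date, hais$hai_type,
                     method = "radix"), ]
  hais[names(empty_linelist())]
}
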