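# Infection-episode assembly and rule-based HAI classification.
#
# Findings and microbiology results are "elements". Elements of one
# patient and body system are chained into candidate episodes under two
# temporal constraints (maximum gap between consecutive elements, maximum
# overall span); each episode is then matched against the configured
# criterion sets for a classification, dated, filtered to late onset,
# attributed to devices or surgeries, and de-duplicated under the repeat
# rule.

# Flatten findings + microbiology into one dated element table. The body
# system of a microbiology element follows its specimen type.
surveillance_elements <- function(findings, microbiology) {
  f <- tibble(
    patient_id = findings$patient_id,
    date = findings$date,
    source = if (nrow(findings)) "finding" else character(0),
    category = findings$category,
    criterion_code = findings$criterion_code,
    specimen_type = NA_character_,
    organism = NA_character_,
    resistance_markers = NA_character_,
    body_system = findings$body_system
  )
  m <- tibble(
    patient_id = microbiology$patient_id,
    date = microbiology$specimen_date,
    source = if (nrow(microbiology)) "micro" else character(0),
    category = NA_character_,
    criterion_code = NA_character_,
    specimen_type = microbiology$specimen_type,
    organism = microbiology$organism,
    resistance_markers = microbiology$resistance_markers,
    body_system = unname(SPECIMEN_BODY_SYSTEM[microbiology$specimen_type])
  )
  bind_rows(f, m)
}

#' Assemble findings and cultures into candidate infection episodes
#'
#' Within each patient and body system, dated elements (findings and
#' microbiology results) are chained left to right into maximal episodes:
#' an element joins the current episode while the gap to the previous
#' element is at most `episode_max_gap_days` and the overall span (last
#' minus first element date) stays within `episode_max_span_days`;
#' otherwise it starts a new episode. Every element belongs to exactly one
#' episode and the partition is independent of input row order.
#'
#' @param findings,microbiology The corresponding cohort tables.
#' @param definitions Definitions configuration (defaults: gap 3 days,
#'   span 10 days, the permissive end of the usual 2--3 day / 7--10 day
#'   guidance).
#' @return A tibble of elements with an integer `episode_id` column;
#'   split on it to obtain individual episodes.
#' @export
assemble_episodes <- function(findings, microbiology,
                              definitions = default_definitions()) {
  par <- definitions$parameters
  el <- surveillance_elements(findings, microbiology)
  el <- el[order(el$patient_id, el$body_system, el$date, el$source,
                 el$criterion_code, el$organism, method = "radix"), ]
  n <- nrow(el)
  if (n == 0) return(mutate(el, episode_id = integer(0)))
  new_group <- c(TRUE, el$patient_id[-1] != el$patient_id[-n] |
                   el$body_system[-1] != el$body_system[-n])
  episode_id <- integer(n)
  eid <- 0L
  ep_start <- as.Date(NA)
  prev_date <- as.Date(NA)
  for (i in seq_len(n)) {
    d <- el$date[i]
    if (new_group[i] ||
        as.integer(d - prev_date) > par$episode_max_gap_days ||
        as.integer(d - ep_start) > par$episode_max_span_days) {
      eid <- eid + 1L
      ep_start <- d
    }
    episode_id[i] <- eid
    prev_date <- d
  }
  el$episode_id <- episode_id
  el
}

#' Infection date of an episode
#'
#' The infection date is the first day on which symptoms appeared
#' (earliest clinical finding; any finding serves as fallback when no
#' clinical one exists), unless a positive culture from the primary site
#' of infection precedes symptom onset, in which case that earlier
#' specimen date is recorded.
#'
#' @param episode A single episode: the element rows sharing one
#'   `episode_id` from [assemble_episodes()].
#' @return A calendar date.
#' @export
determine_infection_date <- function(episode) {
  bs <- episode$body_system[1]
  fdates <- episode$date[episode$source == "finding"]
  clin <- episode$date[episode$source == "finding" & episode$category == "clinical"]
  onset <- if (length(clin)) min(clin) else if (length(fdates)) min(fdates) else as.Date(NA)
  primary <- PRIMARY_SPECIMEN[bs]
  mdates <- episode$date[episode$source == "micro" &
                           !is.na(episode$specimen_type) &
                           episode$specimen_type %in% primary]
  candidates <- c(onset, if (length(mdates)) min(mdates))
  candidates <- candidates[!is.na(candidates)]
  if (length(candidates) == 0) {
    abort("episode has neither findings nor a primary-site positive result")
  }
  min(candidates)
}

#' Late-onset test
#'
#' Healthcare-associated infections are restricted to late onset: at least
#' 72 hours after birth. When a birth time is available and the onset is
#' given as a date-time, exact hour arithmetic is used; with date-only
#' data the rule falls back to day-of-life granularity, where 72 h
#' corresponds to day of life 4 or later.
#'
#' @param onset Infection onset: a `Date`, or a `POSIXct` for hour-level
#'   testing.
#' @param birth_date Birth date.
#' @param birth_time Optional "HH:MM" birth time; only used when `onset`
#'   carries a time of day.
#' @param definitions Definitions configuration (`late_onset_hours`).
#' @return Logical.
#' @export
is_late_onset <- function(onset, birth_date, birth_time = NULL,
                          definitions = default_definitions()) {
  hours <- definitions$parameters$late_onset_hours
  if (inherits(onset, "POSIXct") && !is.null(birth_time) && !is.na(birth_time)) {
    birth <- as.POSIXct(paste(as.Date(birth_date), birth_time), tz = "UTC")
    return(as.numeric(difftime(onset, birth, units = "hours")) >= hours)
  }
  day_of_life(as.Date(onset), birth_date) >= (hours %/% 24) + 1L
}

# Does the episode satisfy one `requires` block: a list of slots, each a
# vector of alternative criterion codes, all slots needed?
meets_requirements <- function(codes, requires) {
  all(vapply(requires, function(slot) any(codes %in% slot), logical(1)))
}

#' Classify a candidate episode
#'
#' Matches an episode against the configured infection types of its body
#' system, in configuration order (which encodes precedence: for
#' bloodstream episodes, laboratory confirmation by a recognized pathogen
#' outranks a commensal-based classification, which outranks clinical
#' sepsis). Organism evidence is read from primary-site specimens:
#' `recognized_pathogen` requires at least one such pathogen,
#' `common_commensal` at least one commensal (and no pathogen, by
#' precedence), `none` requires the absence of any primary-site organism.
#' Surgical-site episodes resolve their depth (superficial, deep,
#' organ/space) from the deepest depth-tagged criterion present.
#'
#' @param episode Element rows of one episode.
#' @param catalog Organism catalog.
#' @param definitions Definitions configuration.
#' @return The infection type as a string (`"clinical_sepsis"`,
#'   `"lcbsi_pathogen"`, `"lcbsi_commensal"`, `"pneumonia"`, `"nec"`,
#'   `"ssi_superficial"`, `"ssi_deep"`, `"ssi_organ_space"`), or
#'   `NA_character_` when no criterion set is satisfied.
#' @export
classify_episode <- function(episode, catalog = default_organisms(),
                             definitions = default_definitions()) {
  bs <- episode$body_system[1]
  codes <- episode$criterion_code[episode$source == "finding"]
  primary <- PRIMARY_SPECIMEN[bs]
  orgs <- episode$organism[episode$source == "micro" &
                             episode$specimen_type %in% primary]
  classes <- if (length(orgs)) organism_class(orgs, catalog) else character(0)
  for (type_name in names(definitions$types)) {
    ty <- definitions$types[[type_name]]
    if (!identical(ty$body_system, bs)) next
    org_req <- ty$organism %||% "any"
    org_ok <- switch(org_req,
      recognized_pathogen = any(classes == "recognized_pathogen"),
      common_commensal = any(classes == "common_commensal"),
      none = length(classes) == 0,
      any = TRUE
    )
    if (!org_ok) next
    blocks <- if (!is.null(ty$any_of)) {
      lapply(ty$any_of, function(b) b$requires)
    } else {
      list(ty$requires %||% list())
    }
    matched <- any(vapply(blocks, function(req) meets_requirements(codes, req),
                          logical(1)))
    if (!matched) next
    if (identical(type_name, "ssi")) {
      return(paste0("ssi_", ssi_depth(codes, definitions)))
    }
    return(type_name)
  }
  NA_character_
}

# Deepest SSI depth among the depth-tagged criterion codes present.
ssi_depth <- function(codes, definitions) {
  depths <- vapply(codes, function(cd) {
    definitions$criteria[[cd]]$depth %||% NA_character_
  }, character(1))
  depths <- depths[!is.na(depths)]
  ord <- c("organ_space", "deep", "superficial")
  hit <- ord[ord %in% depths]
  if (length(hit) == 0) abort("surgical-site episode without a depth criterion")
  hit[1]
}

#' Device association of an infection
#'
#' An infection is device-associated when the relevant device had been in
#' use continuously for at least `device_assoc_min_days` qualifying
#' device-days (>= 12 h per day), in a run ending on the day of infection
#' onset or on the day immediately preceding it. Bloodstream infections
#' and clinical sepsis are assessed against central then peripheral
#' venous catheters (CVC before PVC when both qualify); pneumonia against
#' invasive then noninvasive ventilation.
#'
#' @param infection_date Onset date of the classified infection.
#' @param exposures The exposure rows of the infection's patient.
#' @param hai_type The classified infection type.
#' @param definitions Definitions configuration.
#' @return `"CVC"`, `"PVC"`, `"INV"`, `"NIV"`, or `"none"`.
#' @export
assess_device_association <- function(infection_date, exposures, hai_type,
                                      definitions = default_definitions()) {
  par <- definitions$parameters
  devices <- if (hai_type %in% c("clinical_sepsis", "lcbsi_pathogen", "lcbsi_commensal")) {
    c(CVC = "cvc_hours", PVC = "pvc_hours")
  } else if (identical(hai_type, "pneumonia")) {
    c(INV = "inv_hours", NIV = "niv_hours")
  } else {
    return("none")
  }
  for (dev in names(devices)) {
    dev_days <- exposures$date[exposures[[devices[[dev]]]] >= par$device_day_min_hours]
    for (offset in c(0L, 1L)) {
      last_day <- as.Date(infection_date) - offset
      run <- seq(last_day - par$device_assoc_min_days + 1L, last_day, by = "day")
      if (all(run %in% dev_days)) return(dev)
    }
  }
  "none"
}

#' Attribute a surgical site infection to a surgery
#'
#' An infection of the surgical site is attributed to the most recent
#' prior surgery within the post-operative window: 30 days for every
#' depth; extended to 90 days for deep incisional and organ/space SSIs
#' when an implant was placed. A superficial SSI never benefits from the
#' implant extension. Without a qualifying surgery the episode is not an
#' SSI case.
#'
#' @param infection_date Onset date.
#' @param depth `"superficial"`, `"deep"` or `"organ_space"`.
#' @param surgeries The surgery rows of the patient.
#' @param definitions Definitions configuration.
#' @return A list with `surgery_id` and `hai_type`, or `NULL` when no
#'   surgery qualifies.
#' @export
attribute_ssi <- function(infection_date, depth, surgeries,
                          definitions = default_definitions()) {
  par <- definitions$parameters
  if (nrow(surgeries) == 0) return(NULL)
  delta <- as.integer(infection_date - surgeries$date)
  window <- ifelse(surgeries$implant & depth %in% c("deep", "organ_space"),
                   par$ssi_implant_window_days, par$ssi_window_days)
  ok <- !is.na(delta) & delta >= 0 & delta <= window
  if (!any(ok)) return(NULL)
  pick <- which(ok)[which.max(surgeries$date[ok])]
  list(surgery_id = surgeries$surgery_id[pick], hai_type = paste0("ssi_", depth))
}

#' Suppress repeat infections
#'
#' Starting from an infection's date, at least `repeat_min_days` (14) days
#' must pass, including a symptom-free period, before an infection in the
#' same organ system can be registered again. A later episode inside that
#' window is merged into the prior infection: its organisms and
#' resistance markers are appended, it is not counted. The symptom-free
#' requirement compares the candidate's first element date with the last
#' element date of the kept infection (extended by merged episodes):
#' at least `symptom_free_min_days` empty calendar days must separate
#' them.
#'
#' @param hais Classified infection line list (one row per episode) with
#'   columns `patient_id`, `body_system`, `hai_type`, `infection_date`,
#'   `episode_start`, `episode_end`, `organisms`, `resistance_markers`.
#' @param definitions Definitions configuration.
#' @return The kept rows (a subset of the input, same columns plus
#'   `n_merged`), organisms merged from suppressed episodes.
#' @export
suppress_repeats <- function(hais, definitions = default_definitions()) {
  par <- definitions$parameters
  if (nrow(hais) == 0) return(mutate(hais, n_merged = integer(0)))
  hais <- hais[order(hais$patient_id, hais$body_system, hais$infection_date,
                     hais$hai_type, method = "radix"), ]
  keep <- logical(nrow(hais))
  n_merged <- integer(nrow(hais))
  groups <- split(seq_len(nrow(hais)),
                  paste(hais$patient_id, hais$body_system, sep = "\r"))
  for (idx in groups) {
    kept_i <- NA_integer_
    kept_date <- as.Date(NA)
    last_symptom <- as.Date(NA)
    for (i in idx) {
      new_inf <- is.na(kept_i) ||
        (as.integer(hais$infection_date[i] - kept_date) >= par$repeat_min_days &&
           as.integer(hais$episode_start[i] - last_symptom) - 1L >= par$symptom_free_min_days)
      if (new_inf) {
        kept_i <- i
        kept_date <- hais$infection_date[i]
        last_symptom <- hais$episode_end[i]
        keep[i] <- TRUE
      } else {
        hais$organisms[kept_i] <- merge_set_cells(hais$organisms[kept_i],
                                                  hais$organisms[i])
        hais$resistance_markers[kept_i] <- merge_set_cells(
          hais$resistance_markers[kept_i], hais$resistance_markers[i])
        n_merged[kept_i] <- n_merged[kept_i] + 1L
        last_symptom <- max(last_symptom, hais$episode_end[i])
      }
    }
  }
  out <- hais[keep, , drop = FALSE]
  out$n_merged <- n_merged[keep]
  out
}

#' Flag multidrug-resistant organisms
#'
#' An infection involves an MDRO when any of its organisms carries at
#' least one resistance marker (MRSA, VRE, 3GCR, carbapenem or colistin
#' resistance).
#'
#' @param resistance_markers Semicolon-delimited marker cell(s) as stored
#'   in the line list (NA or "" meaning none).
#' @return Logical vector.
#' @export
flag_mdro <- function(resistance_markers) {
  vapply(resistance_markers,
         function(m) length(split_set(if (is.null(m)) NA_character_ else m)) > 0,
         logical(1), USE.NAMES = FALSE)
}

#' Link secondary bloodstream infections
#'
#' A laboratory-confirmed or clinical bloodstream infection is flagged
#' secondary when a pneumonia, NEC or SSI of the same patient is active
#' at the bloodstream infection's onset (active for
#' `secondary_bsi_active_days` days from the primary's infection date)
#' and, when the primary has documented organisms, shares at least one
#' organism. Secondary bloodstream infections are excluded from primary
#' counts and reported separately; linkage is applied only when
#' secondary-BSI reporting is enabled.
#'
#' @param hais Classified line list after repeat suppression.
#' @param definitions Definitions configuration.
#' @return `hais` with logical `secondary` and character `secondary_to`
#'   columns.
#' @export
link_secondary_bsi <- function(hais, definitions = default_definitions()) {
  par <- definitions$parameters
  hais$secondary <- rep(FALSE, nrow(hais))
  hais$secondary_to <- rep(NA_character_, nrow(hais))
  if (nrow(hais) == 0) return(hais)
  bsi_types <- c("clinical_sepsis", "lcbsi_pathogen", "lcbsi_commensal")
  primary_types <- c("pneumonia", "nec", "ssi_superficial", "ssi_deep", "ssi_organ_space")
  for (i in which(hais$hai_type %in% bsi_types)) {
    cand <- which(hais$patient_id == hais$patient_id[i] &
                    hais$hai_type %in% primary_types &
                    hais$infection_date <= hais$infection_date[i] &
                    hais$infection_date + par$secondary_bsi_active_days >=
                      hais$infection_date[i])
    if (length(cand) == 0) next
    if (isTRUE(par$secondary_bsi_require_organism_match)) {
      cand <- cand[vapply(cand, function(j) {
        prim <- split_set(hais$organisms[j])
        length(prim) == 0 ||
          length(intersect(prim, split_set(hais$organisms[i]))) > 0
      }, logical(1))]
    }
    if (length(cand) == 0) next
    j <- cand[which.max(hais$infection_date[cand])]
    hais$secondary[i] <- TRUE
    hais$secondary_to[i] <- sprintf("%s@%s", hais$hai_type[j],
                                    format(hais$infection_date[j]))
  }
  hais
}
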