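# Eligibility and follow-up: who enters surveillance and on which days.

#' Assess inclusion in the surveillance population
#'
#' An infant is included when live-born, admitted to the unit within 120
#' days of birth, and either very low birth weight (< 1500 g) or very
#' preterm (< 32 completed weeks of gestation). Both thresholds are strict
#' inequalities; both limits and the admission window are configurable.
#'
#' @param patients The `patients` table of a cohort (or a compatible data
#'   frame).
#' @param definitions Definitions configuration supplying
#'   `eligibility_bw_grams`, `eligibility_ga_weeks` and
#'   `admission_window_days`.
#' @return A tibble with `patient_id`, `included` (logical) and
#'   `exclusion_reason` (`NA` when included; otherwise one of
#'   `not_live_born`, `admitted_outside_window`,
#'   `weight_and_gestation_above_threshold`). The function is total: every
#'   valid patient row yields a decision.
#' @examples
#' pts <- simulate_cohort(sim_config(n_patients = 5), seed = 1)$cohort$patients
#' assess_eligibility(pts)
#' @export
assess_eligibility <- function(patients, definitions = default_definitions()) {
  par <- definitions$parameters
  live <- if ("live_born" %in% names(patients)) {
    is.na(patients$live_born) | patients$live_born
  } else {
    rep(TRUE, nrow(patients))
  }
  within_window <- as.integer(patients$admission_date - patients$birth_date) <=
    par$admission_window_days
  size_criterion <- patients$birth_weight < par$eligibility_bw_grams |
    patients$gestational_weeks < par$eligibility_ga_weeks
  included <- live & within_window & size_criterion
  reason <- rep(NA_character_, nrow(patients))
  reason[!size_criterion] <- "weight_and_gestation_above_threshold"
  reason[!within_window] <- "admitted_outside_window"
  reason[!live] <- "not_live_born"
  reason[included] <- NA_character_
  tibble(patient_id = patients$patient_id, included = included,
         exclusion_reason = reason)
}

# Merge one patient's sorted stay intervals into the first follow-up
# episode: consecutive stays separated by <= absence_merge_hours are
# bridged; the window ends at the first longer gap. With date-granular
# data a gap of g full calendar days strictly between two stays counts as
# 24*g hours, so a 2-day absence (48 h) merges and a 3-day absence does
# not. Returns the row indices of stays belonging to the episode.
merge_stay_episode <- function(starts, ends, merge_hours) {
  keep <- 1L
  if (length(starts) > 1) {
    for (i in 2:length(starts)) {
      gap_days <- as.integer(starts[i] - ends[i - 1L]) - 1L
      if (gap_days < 0) abort("overlapping stay intervals")
      if (24 * gap_days > merge_hours) break
      keep <- c(keep, i)
    }
  }
  keep
}

#' Compute surveillance windows
#'
#' For each included patient, determines the set of calendar days under
#' surveillance: the union of the patient's stay intervals, where
#' consecutive stays separated by a short absence (up to 48 h, i.e. two
#' full calendar days at date granularity) are bridged into one follow-up
#' episode. Days fully absent during a bridged gap are not surveillance
#' days. Surveillance ends at death, discharge or transfer, or at the
#' first absence longer than the merge threshold; stays after such a gap
#' are outside the episode and are dropped with a warning. Patients
#' without stay rows are assumed present from admission to their end date.
#'
#' @param cohort A validated [neo_cohort()].
#' @param definitions Definitions configuration.
#' @param as_of Closing date for windows of patients with no end date
#'   (censoring open); defaults to the latest date appearing anywhere in
#'   the cohort.
#' @return A list of class `neo_windows` with `summary` (one row per
#'   patient: inclusion, window bounds, `end_reason`, `patient_days`) and
#'   `days` (one row per patient x surveillance day, with `day_of_life`).
#' @export
surveillance_windows <- function(cohort, definitions = default_definitions(),
                                 as_of = NULL) {
  stopifnot(inherits(cohort, "neo_cohort"))
  par <- definitions$parameters
  elig <- assess_eligibility(cohort$patients, definitions)
  pt <- cohort$patients
  if (is.null(as_of)) {
    candidates <- c(pt$end_date, cohort$stays$end_date, cohort$exposures$date,
                    pt$admission_date)
    as_of <- suppressWarnings(max(candidates, na.rm = TRUE))
  }
  dropped_msgs <- character(0)
  day_rows <- vector("list", nrow(pt))
  summary_rows <- vector("list", nrow(pt))
  for (i in seq_len(nrow(pt))) {
    pid <- pt$patient_id[i]
    inc <- elig$included[i]
    st <- cohort$stays[cohort$stays$patient_id == pid, , drop = FALSE]
    if (nrow(st) == 0) {
      st <- tibble(patient_id = pid, start_date = pt$admission_date[i],
                   end_date = pt$end_date[i])
    }
    st <- st[order(st$start_date), , drop = FALSE]
    ends <- st$end_date
    ends[is.na(ends)] <- min(pt$end_date[i], as_of, na.rm = TRUE)
    days <- as.Date(character(0))
    end_reason <- NA_character_
    win_start <- as.Date(NA)
    win_end <- as.Date(NA)
    if (inc) {
      keep <- merge_stay_episode(st$start_date, ends, par$absence_merge_hours)
      if (length(keep) < nrow(st)) {
        dropped_msgs <- c(dropped_msgs, sprintf(
          "patient %s: %d stay(s) after a > %g h absence are outside the surveillance episode",
          pid, nrow(st) - length(keep), par$absence_merge_hours))
      }
      days <- sort(unique(do.call(c, lapply(keep, function(k) {
        seq(st$start_date[k], ends[k], by = "day")
      }))))
      days <- days[days >= pt$admission_date[i]]
      if (!is.na(pt$end_date[i]) && length(keep) == nrow(st)) {
        days <- days[days <= pt$end_date[i]]
      }
      win_start <- days[1]
      win_end <- days[length(days)]
      end_reason <- if (!is.na(pt$end_date[i]) && win_end >= pt$end_date[i]) {
        pt$end_reason[i]
      } else {
        "discharge_or_transfer"
      }
    }
    summary_rows[[i]] <- tibble(
      patient_id = pid, included = inc,
      exclusion_reason = elig$exclusion_reason[i],
      window_start = win_start, window_end = win_end,
      end_reason = end_reason, patient_days = length(days)
    )
    if (length(days) > 0) {
      day_rows[[i]] <- tibble(
        patient_id = pid, date = days,
        day_of_life = day_of_life(days, pt$birth_date[i])
      )
    }
  }
  if (length(dropped_msgs) > 0) warn(dropped_msgs)
  days_tbl <- bind_rows(day_rows)
  if (ncol(days_tbl) == 0) {
    days_tbl <- tibble(patient_id = character(0), date = as.Date(character(0)),
                       day_of_life = integer(0))
  }
  summary_tbl <- bind_rows(summary_rows)
  if (ncol(summary_tbl) == 0) {
    summary_tbl <- tibble(
      patient_id = character(0), included = logical(0),
      exclusion_reason = character(0), window_start = as.Date(character(0)),
      window_end = as.Date(character(0)), end_reason = character(0),
      patient_days = integer(0)
    )
  }
  structure(list(summary = summary_tbl, days = days_tbl), class = "neo_windows")
}

#' @export
print.neo_windows <- function(x, ...) {
  cat(sprintf("<neo_windows> %d patients (%d included), %d patient-days\n",
              nrow(x$summary), sum(x$summary$included), nrow(x$days)))
  invisible(x)
}
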