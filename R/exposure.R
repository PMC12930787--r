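# Exposure accounting: patient-days, device-days, and risk/protective
# factor day counts, the denominators of every surveillance rate.

#' Day of life
#'
#' The day of birth is day of life 1; every subsequent calendar day
#' increments the count by one, regardless of time of day.
#'
#' @param date Calendar date(s) of interest.
#' @param birth_date The infant's birth date.
#' @return Integer day(s) of life, `>= 1`. Dates before birth are an error.
#' @examples
#' day_of_life(as.Date("2025-01-05"), as.Date("2025-01-01"))  # 5
#' @export
day_of_life <- function(date, birth_date) {
  dol <- as.integer(as.Date(date) - as.Date(birth_date)) + 1L
  if (any(dol < 1L, na.rm = TRUE)) abort("day_of_life: date precedes birth_date")
  dol
}

#' Per-patient exposure summary
#'
#' Counts, over each included patient's surveillance days: patient-days
#' (every day with any presence counts, no minimum duration), device-days
#' per device (a day with at least 12 cumulative hours of the device),
#' antibiotic days (at least one systemic substance), exclusive
#' breast-milk feeding days, probiotic days, and kangaroo-care days (at
#' least 2 h of skin-to-skin contact). Exposure rows dated outside a
#' patient's surveillance days (for example during a bridged absence) are
#' ignored with a warning. Thresholds come from the definitions
#' configuration and are `>=` comparisons on exact (possibly fractional)
#' hour values.
#'
#' @param cohort A validated [neo_cohort()].
#' @param windows Result of [surveillance_windows()]; computed when `NULL`.
#' @param definitions Definitions configuration.
#' @return A tibble, one row per included patient: `patient_id`,
#'   `patient_days`, `cvc_days`, `pvc_days`, `inv_days`, `niv_days`,
#'   `antibiotic_days`, `breast_milk_days`, `probiotic_days`,
#'   `kangaroo_days`.
#' @seealso [substance_days()] for per-substance antibiotic day counts.
#' @export
exposure_summary <- function(cohort, windows = NULL,
                             definitions = default_definitions()) {
  if (is.null(windows)) windows <- surveillance_windows(cohort, definitions)
  par <- definitions$parameters
  ex <- dplyr::semi_join(cohort$exposures, windows$days,
                         by = c("patient_id", "date"))
  n_out <- nrow(cohort$exposures) - nrow(ex)
  if (n_out > 0) {
    warn(sprintf("%d exposure row(s) outside surveillance windows ignored", n_out))
  }
  has_ab <- !is.na(ex$antibiotic_substances) & nzchar(ex$antibiotic_substances)
  per_patient <- ex |>
    mutate(has_ab = has_ab) |>
    group_by(.data$patient_id) |>
    summarise(
      cvc_days = sum(.data$cvc_hours >= par$device_day_min_hours),
      pvc_days = sum(.data$pvc_hours >= par$device_day_min_hours),
      inv_days = sum(.data$inv_hours >= par$device_day_min_hours),
      niv_days = sum(.data$niv_hours >= par$device_day_min_hours),
      antibiotic_days = sum(.data$has_ab),
      breast_milk_days = sum(.data$enteral_feeding == "exclusive_breast_milk"),
      probiotic_days = sum(.data$probiotic_given),
      kangaroo_days = sum(.data$kangaroo_hours >= par$kangaroo_min_hours),
      .groups = "drop"
    )
  base <- windows$summary[windows$summary$included,
                          c("patient_id", "patient_days")]
  out <- left_join(base, per_patient, by = "patient_id")
  count_cols <- setdiff(names(out), c("patient_id", "patient_days"))
  out[count_cols] <- lapply(out[count_cols], function(v) {
    as.integer(ifelse(is.na(v), 0L, v))
  })
  out
}

#' Antibiotic days per substance
#'
#' Antibiotic use is captured both cumulatively (any substance, see
#' [exposure_summary()]) and per substance: for each substance the number
#' of surveillance days on which the patient received it. A day with two
#' substances contributes one day to each substance but a single day to
#' the cumulative count.
#'
#' @inheritParams exposure_summary
#' @return A tibble `patient_id`, `substance`, `days`.
#' @export
substance_days <- function(cohort, windows = NULL,
                           definitions = default_definitions()) {
  if (is.null(windows)) windows <- surveillance_windows(cohort, definitions)
  ex <- dplyr::semi_join(cohort$exposures, windows$days,
                         by = c("patient_id", "date"))
  ex <- ex[!is.na(ex$antibiotic_substances) & nzchar(ex$antibiotic_substances), ]
  if (nrow(ex) == 0) {
    return(tibble(patient_id = character(0), substance = character(0),
                  days = integer(0)))
  }
  sets <- strsplit(ex$antibiotic_substances, ";", fixed = TRUE)
  long <- tibble(
    patient_id = rep(ex$patient_id, lengths(sets)),
    date = rep(ex$date, lengths(sets)),
    substance = trimws(unlist(sets))
  )
  long |>
    distinct() |>                      # guard: same substance listed twice in one cell
    select(-"date") |>
    count(.data$patient_id, .data$substance, name = "days") |>
    mutate(days = as.integer(.data$days)) |>
    arrange(.data$patient_id, .data$substance)
}
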