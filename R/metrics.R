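# Unit-level surveillance metrics, stratified by birth weight.

STRATA <- c("<500 g", "500-999 g", "1000-1499 g", ">=1500 g")
HAI_TYPES <- c("clinical_sepsis", "lcbsi_pathogen", "lcbsi_commensal",
               "pneumonia", "nec", "ssi_superficial", "ssi_deep",
               "ssi_organ_space")

#' Birth-weight stratum
#'
#' Assigns the four half-open analysis strata: `[0,500)`, `[500,1000)`,
#' `[1000,1500)` and `[1500,Inf)` grams. The last stratum holds the small
#' subset of very preterm infants above the very-low-birth-weight cut.
#'
#' @param birth_weight Birth weight(s) in grams.
#' @return A factor with levels `<500 g`, `500-999 g`, `1000-1499 g`,
#'   `>=1500 g`.
#' @examples
#' assign_stratum(c(499, 500, 1499, 1500))
#' @export
assign_stratum <- function(birth_weight) {
  cut(birth_weight, breaks = c(0, 500, 1000, 1500, Inf), labels = STRATA,
      right = FALSE)
}

#' Surveillance rate formulas
#'
#' The elementary rate computations of the unit report. All return `NA`
#' when the denominator is zero: "no exposure" must remain
#' distinguishable from "no events".
#'
#' * `use_rate()`: percentage of patient-days on which a risk or
#'   protective factor was in use, `100 * factor_days / patient_days`.
#' * `incidence_density()`: infections per 1000 patient-days,
#'   `1000 * n_infections / patient_days`.
#' * `device_associated_density()`: device-associated infections per 1000
#'   device-days.
#' * `agent_detection_rate()`: percentage of infections with a detected
#'   agent.
#' * `agent_per_infection_rate()`: detected agents per 100 infections
#'   with an agent (exceeds 100 with polymicrobial infections).
#'
#' @param factor_days,patient_days,n_infections,n_device_associated,device_days,n_with_agent,n_agents
#'   Nonnegative counts/denominators (vectorized).
#' @return Numeric rate(s); `NA` where the denominator is zero.
#' @examples
#' use_rate(50, 200)              # 25
#' incidence_density(3, 1500)     # 2
#' agent_per_infection_rate(12, 8) # 150
#' @name rates
NULL

#' @rdname rates
#' @export
use_rate <- function(factor_days, patient_days) {
  if (any(factor_days > patient_days, na.rm = TRUE)) {
    abort("use_rate: factor_days exceeds patient_days")
  }
  ifelse(patient_days == 0, NA_real_, 100 * factor_days / patient_days)
}

#' @rdname rates
#' @export
incidence_density <- function(n_infections, patient_days) {
  ifelse(patient_days == 0, NA_real_, 1000 * n_infections / patient_days)
}

#' @rdname rates
#' @export
device_associated_density <- function(n_device_associated, device_days) {
  ifelse(device_days == 0, NA_real_, 1000 * n_device_associated / device_days)
}

#' @rdname rates
#' @export
agent_detection_rate <- function(n_with_agent, n_infections) {
  if (any(n_with_agent > n_infections, na.rm = TRUE)) {
    abort("agent_detection_rate: infections with agent exceed total infections")
  }
  ifelse(n_infections == 0, NA_real_, 100 * n_with_agent / n_infections)
}

#' @rdname rates
#' @export
agent_per_infection_rate <- function(n_agents, n_with_agent) {
  if (any(n_agents < n_with_agent, na.rm = TRUE)) {
    abort("agent_per_infection_rate: fewer agents than infections with agent")
  }
  ifelse(n_with_agent == 0, NA_real_, 100 * n_agents / n_with_agent)
}

#' Surgical site infection rates
#'
#' Overall SSI rate: SSI cases per 100 surgical procedures. Specific
#' rates are computed per procedure group, by default the 3-character
#' prefix of the main procedure code (configurable via `group_fun`).
#' Groups without surgeries report `NA`.
#'
#' @param hais HAI line list; SSI rows must carry `linked_surgery_id`.
#' @param surgeries The cohort surgery table.
#' @param group_fun Function mapping main procedure codes to group labels.
#' @return A tibble `group`, `n_surgeries`, `n_ssi`, `ssi_rate`, with the
#'   overall rate in group `"(all)"`.
#' @export
ssi_rates <- function(hais, surgeries,
                      group_fun = function(code) substr(code, 1, 3)) {
  ssi <- hais[grepl("^ssi_", hais$hai_type) & !hais$secondary, , drop = FALSE]
  if (any(is.na(ssi$linked_surgery_id))) {
    abort("ssi_rates: SSI case without linked surgery")
  }
  surgeries$group <- group_fun(surgeries$main_procedure_code)
  ssi_group <- surgeries$group[match(ssi$linked_surgery_id, surgeries$surgery_id)]
  if (anyNA(ssi_group)) abort("ssi_rates: linked surgery not found")
  per_group <- surgeries |>
    count(.data$group, name = "n_surgeries") |>
    left_join(tibble(group = ssi_group) |> count(.data$group, name = "n_ssi"),
              by = "group") |>
    mutate(n_ssi = ifelse(is.na(.data$n_ssi), 0L, .data$n_ssi))
  overall <- tibble(
    group = "(all)", n_surgeries = nrow(surgeries), n_ssi = nrow(ssi)
  )
  bind_rows(overall, per_group) |>
    mutate(ssi_rate = ifelse(.data$n_surgeries == 0, NA_real_,
                             100 * .data$n_ssi / .data$n_surgeries))
}

#' Aggregate counts and denominators per birth-weight stratum
#'
#' Builds the stratum-level aggregate underlying the unit report: patient
#' counts, patient-days, device-days and factor-days, infection counts
#' per type, device-associated counts per device, surgery and SSI counts,
#' and agent-detection tallies. Sums over strata equal the pooled totals
#' by construction.
#'
#' @param cohort A validated cohort.
#' @param windows,expsum,hais Precomputed module outputs
#'   ([surveillance_windows()], [exposure_summary()],
#'   [classify_cohort()]); any may be `NULL` to compute here.
#' @param definitions,catalog Active configuration.
#' @return A tibble with one row per stratum (all four always present).
#' @export
aggregate_strata <- function(cohort, windows = NULL, expsum = NULL,
                             hais = NULL, definitions = default_definitions(),
                             catalog = default_organisms()) {
  if (is.null(windows)) windows <- surveillance_windows(cohort, definitions)
  if (is.null(expsum)) expsum <- exposure_summary(cohort, windows, definitions)
  if (is.null(hais)) hais <- classify_cohort(cohort, definitions, catalog, windows)
  pt <- cohort$patients
  pt$stratum <- assign_stratum(pt$birth_weight)
  strat <- setNames(as.character(pt$stratum), pt$patient_id)

  exp_full <- expsum
  exp_full$stratum <- strat[exp_full$patient_id]
  exp_agg <- exp_full |>
    group_by(.data$stratum) |>
    summarise(
      n_patients = n(),
      dplyr::across(c("patient_days", "cvc_days", "pvc_days", "inv_days",
                      "niv_days", "antibiotic_days", "breast_milk_days",
                      "probiotic_days", "kangaroo_days"), sum),
      .groups = "drop"
    )

  primary <- hais[!hais$secondary, , drop = FALSE]
  primary$stratum <- strat[primary$patient_id]
  hai_counts <- primary |>
    count(.data$stratum, .data$hai_type) |>
    tidyr::pivot_wider(names_from = "hai_type", values_from = "n",
                       values_fill = 0L)
  for (ty in HAI_TYPES) {
    if (!ty %in% names(hai_counts)) hai_counts[[ty]] <- 0L
  }
  dev_counts <- primary |>
    filter(.data$device_association != "none") |>
    count(.data$stratum, .data$device_association) |>
    tidyr::pivot_wider(names_from = "device_association", values_from = "n",
                       values_fill = 0L)
  for (d in DEVICES) if (!d %in% names(dev_counts)) dev_counts[[d]] <- 0L
  names(dev_counts)[-1] <- paste0(tolower(names(dev_counts)[-1]), "_associated")

  agent_tally <- primary |>
    mutate(n_agents = vapply(.data$organisms,
                             function(o) length(split_set(o)), integer(1))) |>
    group_by(.data$stratum) |>
    summarise(
      infections_with_agent = sum(.data$n_agents > 0),
      agents_detected = sum(.data$n_agents),
      mdro_infections = sum(.data$is_mdro),
      .groups = "drop"
    )

  sg <- cohort$surgeries
  sg$stratum <- strat[sg$patient_id]
  sg_agg <- sg |> count(.data$stratum, name = "n_surgeries")
  ssi_agg <- primary |>
    filter(grepl("^ssi_", .data$hai_type)) |>
    count(.data$stratum, name = "n_ssi")

  out <- tibble(stratum = STRATA) |>
    left_join(exp_agg, by = "stratum") |>
    left_join(hai_counts, by = "stratum") |>
    left_join(dev_counts, by = "stratum") |>
    left_join(agent_tally, by = "stratum") |>
    left_join(sg_agg, by = "stratum") |>
    left_join(ssi_agg, by = "stratum")
  num_cols <- setdiff(names(out), "stratum")
  out[num_cols] <- lapply(out[num_cols], function(v) {
    as.integer(ifelse(is.na(v), 0L, v))
  })
  out
}

#' Unit metric table
#'
#' Derives every reported rate from a stratum aggregate: use rates for
#' the four devices, antibiotics and the three protective factors;
#' incidence densities overall and per infection type; device-associated
#' densities per device; agent detection and agent-per-infection rates;
#' and the overall SSI rate. One row per metric and stratum, plus pooled
#' (`"(all)"`) rows obtained by summing numerators and denominators over
#' strata.
#'
#' @param strata A stratum aggregate from [aggregate_strata()].
#' @return A tidy tibble `metric`, `stratum`, `numerator`, `denominator`,
#'   `value` (`NA` value where the denominator is zero).
#' @export
unit_metrics <- function(strata) {
  pooled <- strata |>
    summarise(dplyr::across(-"stratum", sum)) |>
    mutate(stratum = "(all)")
  s <- bind_rows(strata, pooled)
  bsi <- s$clinical_sepsis + s$lcbsi_pathogen + s$lcbsi_commensal
  n_hai <- bsi + s$pneumonia + s$nec + s$ssi_superficial + s$ssi_deep +
    s$ssi_organ_space
  rate_row <- function(metric, num, den, f) {
    tibble(metric = metric, stratum = s$stratum, numerator = num,
           denominator = den, value = f(num, den))
  }
  bind_rows(
    rate_row("cvc_use_rate", s$cvc_days, s$patient_days, use_rate),
    rate_row("pvc_use_rate", s$pvc_days, s$patient_days, use_rate),
    rate_row("inv_use_rate", s$inv_days, s$patient_days, use_rate),
    rate_row("niv_use_rate", s$niv_days, s$patient_days, use_rate),
    rate_row("antibiotic_use_rate", s$antibiotic_days, s$patient_days, use_rate),
    rate_row("breast_milk_use_rate", s$breast_milk_days, s$patient_days, use_rate),
    rate_row("probiotic_use_rate", s$probiotic_days, s$patient_days, use_rate),
    rate_row("kangaroo_use_rate", s$kangaroo_days, s$patient_days, use_rate),
    rate_row("hai_incidence_density", n_hai, s$patient_days, incidence_density),
    rate_row("bsi_incidence_density", bsi, s$patient_days, incidence_density),
    rate_row("pneumonia_incidence_density", s$pneumonia, s$patient_days,
             incidence_density),
    rate_row("nec_incidence_density", s$nec, s$patient_days, incidence_density),
    rate_row("cvc_associated_density", s$cvc_associated, s$cvc_days,
             device_associated_density),
    rate_row("pvc_associated_density", s$pvc_associated, s$pvc_days,
             device_associated_density),
    rate_row("inv_associated_density", s$inv_associated, s$inv_days,
             device_associated_density),
    rate_row("niv_associated_density", s$niv_associated, s$niv_days,
             device_associated_density),
    rate_row("agent_detection_rate", s$infections_with_agent, n_hai,
             agent_detection_rate),
    rate_row("agent_per_infection_rate", s$agents_detected,
             s$infections_with_agent, agent_per_infection_rate),
    rate_row("mdro_incidence_density", s$mdro_infections, s$patient_days,
             incidence_density),
    rate_row("overall_ssi_rate", s$n_ssi, s$n_surgeries,
             function(n, d) ifelse(d == 0, NA_real_, 100 * n / d))
  )
}
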