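# Standardized infection ratio: expected counts from reference rates
# stratified by birth weight and day of life, and unit benchmarking.

#' Day-of-life bands
#'
#' Risk changes quickly over an infant's first weeks, so reference rates
#' are stratified by day of life in addition to birth weight. The default
#' bands are 1-3, 4-7, 8-14, 15-28 and 29+ days; any ordered set of lower
#' edges starting at 1 may be used, but benchmarks are only comparable
#' across identical bands, so reports echo the edges.
#'
#' @param edges Integer vector of band lower edges, starting at 1,
#'   strictly increasing.
#' @return For `default_bands()`, the default edges. For `band_label()`,
#'   the band label(s) (e.g. `"8-14"`, `"29+"`) for the given days of
#'   life.
#' @examples
#' band_label(c(1, 7, 29), default_bands())
#' @export
default_bands <- function() c(1L, 4L, 8L, 15L, 29L)

#' @rdname default_bands
#' @param day_of_life Day(s) of life, `>= 1`.
#' @export
band_label <- function(day_of_life, edges = default_bands()) {
  stopifnot(edges[1] == 1, !is.unsorted(edges, strictly = TRUE))
  labs <- band_labels(edges)
  labs[findInterval(day_of_life, edges)]
}

band_labels <- function(edges) {
  upper <- c(edges[-1] - 1L, NA)
  ifelse(is.na(upper), paste0(edges, "+"), paste0(edges, "-", upper))
}

#' Tabulate patient-days at risk per stratum and day-of-life band
#'
#' Assigns every surveillance day of every included patient to exactly
#' one cell of the birth-weight x day-of-life grid. Cell sums equal total
#' patient-days.
#'
#' @param windows [surveillance_windows()] result.
#' @param patients The cohort patient table (for birth weights).
#' @param edges Day-of-life band edges.
#' @return A complete-grid tibble `stratum`, `band`, `patient_days`.
#' @export
tabulate_risk_days <- function(windows, patients, edges = default_bands()) {
  d <- windows$days
  strat <- setNames(as.character(assign_stratum(patients$birth_weight)),
                    patients$patient_id)
  grid <- tidyr::expand_grid(stratum = STRATA, band = band_labels(edges))
  if (nrow(d) == 0) return(mutate(grid, patient_days = 0L))
  counts <- tibble(stratum = strat[d$patient_id],
                   band = band_label(d$day_of_life, edges)) |>
    count(.data$stratum, .data$band, name = "patient_days")
  grid |>
    left_join(counts, by = c("stratum", "band")) |>
    mutate(patient_days = as.integer(ifelse(is.na(.data$patient_days), 0L,
                                            .data$patient_days)))
}

# Observed infections per (stratum, band) cell, overall or per type.
observed_by_cell <- function(hais, patients, edges = default_bands()) {
  strat <- setNames(as.character(assign_stratum(patients$birth_weight)),
                    patients$patient_id)
  grid <- tidyr::expand_grid(stratum = STRATA, band = band_labels(edges))
  primary <- hais[!hais$secondary, , drop = FALSE]
  if (nrow(primary) == 0) return(mutate(grid, infections = 0L))
  counts <- tibble(stratum = strat[primary$patient_id],
                   band = band_label(primary$day_of_life, edges)) |>
    count(.data$stratum, .data$band, name = "infections")
  grid |>
    left_join(counts, by = c("stratum", "band")) |>
    mutate(infections = as.integer(ifelse(is.na(.data$infections), 0L,
                                          .data$infections)))
}

#' Unit aggregation cells for benchmarking
#'
#' The per-cell observed infections and patient-days of one unit: the
#' only data that leaves the unit for reference-building (aggregates
#' only, no patient-level rows).
#'
#' @param cohort,windows,hais Cohort and precomputed module outputs
#'   (computed when `NULL`).
#' @param edges Day-of-life band edges.
#' @param definitions,catalog Active configuration.
#' @return A tibble `stratum`, `band`, `infections`, `patient_days` with
#'   attribute `edges`.
#' @export
unit_cells <- function(cohort, windows = NULL, hais = NULL,
                       edges = default_bands(),
                       definitions = default_definitions(),
                       catalog = default_organisms()) {
  if (is.null(windows)) windows <- surveillance_windows(cohort, definitions)
  if (is.null(hais)) hais <- classify_cohort(cohort, definitions, catalog, windows)
  cells <- observed_by_cell(hais, cohort$patients, edges) |>
    left_join(tabulate_risk_days(windows, cohort$patients, edges),
              by = c("stratum", "band"))
  attr(cells, "edges") <- edges
  cells
}

#' Reference rates
#'
#' Infections per patient-day for every birth-weight x day-of-life cell,
#' the basis of expected counts. `reference_rates()` builds the object
#' from per-cell rates; `aggregate_reference()` pools unit aggregates
#' (sum of infections over sum of patient-days per cell). Cells with no
#' reference patient-days carry an `NA` rate and may not be occupied by a
#' benchmarked unit.
#'
#' @param cells A tibble `stratum`, `band`, `rate` (for
#'   `reference_rates()`), or with `infections` and `patient_days` (for
#'   `aggregate_reference()`).
#' @param edges Day-of-life band edges the cells were built with.
#' @return A tibble of class `neo_reference` with columns `stratum`,
#'   `band`, `rate` and attribute `edges`.
#' @export
reference_rates <- function(cells, edges = default_bands()) {
  stopifnot(all(c("stratum", "band", "rate") %in% names(cells)))
  if (any(cells$rate < 0, na.rm = TRUE)) abort("reference rates must be >= 0")
  out <- as_tibble(cells[c("stratum", "band", "rate")])
  attr(out, "edges") <- edges
  structure(out, class = c("neo_reference", class(out)))
}

#' @rdname reference_rates
#' @param units A list of unit cell tables from [unit_cells()] (or one
#'   such table).
#' @export
aggregate_reference <- function(units) {
  if (is.data.frame(units)) units <- list(units)
  edges_list <- lapply(units, attr, "edges")
  if (length(unique(lapply(edges_list, as.integer))) != 1) {
    abort("aggregate_reference: units use different day-of-life band edges")
  }
  edges <- edges_list[[1]]
  pooled <- bind_rows(units) |>
    group_by(.data$stratum, .data$band) |>
    summarise(infections = sum(.data$infections),
              patient_days = sum(.data$patient_days), .groups = "drop") |>
    mutate(rate = ifelse(.data$patient_days == 0, NA_real_,
                         .data$infections / .data$patient_days))
  # keep the canonical stratum x band ordering of the cell grids
  grid <- tidyr::expand_grid(stratum = STRATA, band = band_labels(edges))
  pooled <- left_join(grid, pooled, by = c("stratum", "band"))
  reference_rates(pooled, edges)
}

#' Expected infections under reference rates
#'
#' Sum over cells of reference rate times the unit's patient-days in that
#' cell. Every occupied cell (patient-days > 0) must be covered by a
#' non-missing reference rate.
#'
#' @param risk_days Output of [tabulate_risk_days()] (columns `stratum`,
#'   `band`, `patient_days`).
#' @param reference A [reference_rates()] object.
#' @return The expected infection count (double).
#' @export
expected_infections <- function(risk_days, reference) {
  joined <- left_join(risk_days, reference, by = c("stratum", "band"))
  uncovered <- joined$patient_days > 0 & is.na(joined$rate)
  if (any(uncovered)) {
    abort(sprintf("expected_infections: no reference rate for occupied cell(s): %s",
                  paste(sprintf("(%s, %s)", joined$stratum[uncovered],
                                joined$band[uncovered]), collapse = ", ")))
  }
  sum(joined$rate * joined$patient_days, na.rm = TRUE)
}

#' Standardized infection ratio
#'
#' The ratio of observed to expected infections. A value of 1.0 means
#' observed rates match the reference; above or below 1.0, higher or
#' lower than expected. When the expected count is zero the ratio is
#' incalculable and reported as `NA` with the observed count (never as
#' infinity).
#'
#' @param observed Observed infection count (integer >= 0).
#' @param expected Expected count under the reference (double >= 0).
#' @return A list of class `neo_sir` with `observed`, `expected`, `sir`.
#' @examples
#' standardized_infection_ratio(10, 10)  # sir = 1
#' @export
standardized_infection_ratio <- function(observed, expected) {
  if (observed < 0 || expected < 0) {
    abort("standardized_infection_ratio: negative input")
  }
  sir <- if (expected > 0) observed / expected else NA_real_
  if (is.na(sir) && observed > 0) {
    warn(sprintf("SIR incalculable: expected = 0 with observed = %d", observed))
  }
  structure(list(observed = as.integer(observed), expected = as.double(expected),
                 sir = sir), class = "neo_sir")
}

#' @export
print.neo_sir <- function(x, ...) {
  cat(sprintf("SIR = %s (observed %d, expected %.3f)\n",
              ifelse(is.na(x$sir), "incalculable", format(x$sir, digits = 4)),
              x$observed, x$expected))
  invisible(x)
}

#' Benchmark a unit against reference rates
#'
#' Computes the unit's overall SIR and, additionally, a per-type SIR for
#' each infection type observed (benchmarking a type requires a
#' type-specific reference; against an all-type reference only the
#' overall SIR is meaningful, so per-type rows are emitted only when
#' `reference` is a named list of per-type references).
#'
#' @param cohort A validated cohort.
#' @param reference A [reference_rates()] object, or a named list with
#'   element `overall` and optionally one reference per infection type.
#' @param windows,hais Precomputed module outputs (computed when `NULL`).
#' @param definitions,catalog Active configuration.
#' @return A tibble `scope`, `observed`, `expected`, `sir`.
#' @export
unit_sir <- function(cohort, reference, windows = NULL, hais = NULL,
                     definitions = default_definitions(),
                     catalog = default_organisms()) {
  if (is.null(windows)) windows <- surveillance_windows(cohort, definitions)
  if (is.null(hais)) hais <- classify_cohort(cohort, definitions, catalog, windows)
  refs <- if (inherits(reference, "neo_reference")) {
    list(overall = reference)
  } else {
    reference
  }
  primary <- hais[!hais$secondary, , drop = FALSE]
  rows <- lapply(names(refs), function(scope) {
    ref <- refs[[scope]]
    risk <- tabulate_risk_days(windows, cohort$patients, attr(ref, "edges"))
    obs <- if (identical(scope, "overall")) {
      nrow(primary)
    } else {
      sum(primary$hai_type == scope)
    }
    exp <- expected_infections(risk, ref)
    sir <- standardized_infection_ratio(obs, exp)
    tibble(scope = scope, observed = sir$observed, expected = sir$expected,
           sir = sir$sir)
  })
  bind_rows(rows)
}
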