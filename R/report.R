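# Unit report generation and multi-unit benchmarking. Mirrors the
# two-level dataflow of network surveillance: each unit analyzes its own
# data; only aggregated cell tables leave the unit and are pooled into
# reference rates for benchmarking.

#' Run the full unit analysis
#'
#' Executes the complete pipeline on one unit's cohort and writes the
#' unit report: per-patient exposure summary, antibiotic days per
#' substance, the HAI line list, the stratified metric table (CSV with
#' rates to two decimals, JSON at full precision), SSI rates, the unit's
#' aggregation cells for benchmarking, an optional SIR table when a
#' reference is supplied, and a JSON metadata block (engine version,
#' configuration hashes, band edges, row counts, warnings). Reports
#' contain no direct identifiers beyond the opaque pseudonym ids of the
#' input.
#'
#' @param input A [neo_cohort()] or a directory readable by
#'   [read_cohort()].
#' @param output_dir Directory for the report files (created if needed);
#'   `NULL` to skip writing.
#' @param definitions,catalog Active configuration.
#' @param reference Optional [reference_rates()] for SIR benchmarking.
#' @param edges Day-of-life band edges for the aggregation cells.
#' @param enable_secondary_bsi Enable optional secondary-BSI reporting.
#' @return A list of class `neo_unit_report` with all computed tables and
#'   metadata, invisibly when writing.
#' @export
run_unit_analysis <- function(input, output_dir = NULL,
                              definitions = default_definitions(),
                              catalog = default_organisms(),
                              reference = NULL, edges = default_bands(),
                              enable_secondary_bsi = FALSE) {
  warnings_seen <- character(0)
  cohort <- withCallingHandlers(
    {
      if (inherits(input, "neo_cohort")) {
        validate_cohort(input, definitions, catalog)
        input
      } else {
        read_cohort(input, definitions, catalog, quiet = TRUE)
      }
    },
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  windows <- collect(surveillance_windows(cohort, definitions))
  expsum <- collect(exposure_summary(cohort, windows, definitions))
  subst <- collect(substance_days(cohort, windows, definitions))
  hais <- collect(classify_cohort(cohort, definitions, catalog, windows,
                                  enable_secondary_bsi))
  strata <- aggregate_strata(cohort, windows, expsum, hais, definitions, catalog)
  metrics <- unit_metrics(strata)
  ssi <- ssi_rates(hais, cohort$surgeries)
  cells <- unit_cells(cohort, windows, hais, edges, definitions, catalog)
  sir <- if (!is.null(reference)) {
    collect(unit_sir(cohort, reference, windows, hais, definitions, catalog))
  }
  n_eligible <- sum(windows$summary$included)
  if (n_eligible == 0) {
    warnings_seen <- c(warnings_seen,
                       "no eligible patients: report tables are empty")
  }
  report <- structure(list(
    metadata = list(
      engine_version = as.character(packageVersion("neosurv")),
      generated = "deterministic",
      definitions_hash = config_hash(unclass(definitions)),
      catalog_hash = config_hash(as.data.frame(catalog)),
      band_edges = as.integer(edges),
      n_patients = nrow(cohort$patients),
      n_eligible = n_eligible,
      patient_days = sum(windows$summary$patient_days),
      n_hai = sum(!hais$secondary),
      warnings = warnings_seen
    ),
    windows = windows$summary, exposure_summary = expsum,
    substance_days = subst, hai_line_list = hais, strata = strata,
    metrics = metrics, ssi_rates = ssi, cells = cells, sir = sir
  ), class = "neo_unit_report")
  if (!is.null(output_dir)) {
    write_unit_report(report, output_dir)
    return(invisible(report))
  }
  report
}

write_unit_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(output_dir, f)
  readr::write_csv(report$exposure_summary, out("exposure_summary.csv"), na = "")
  readr::write_csv(report$substance_days, out("antibiotic_substance_days.csv"), na = "")
  readr::write_csv(report$hai_line_list, out("hai_line_list.csv"), na = "")
  metrics_csv <- report$metrics
  metrics_csv$value <- round(metrics_csv$value, 2)
  readr::write_csv(metrics_csv, out("metrics.csv"), na = "")
  jsonlite::write_json(report$metrics, out("metrics.json"), dataframe = "rows",
                       na = "null", digits = NA, pretty = TRUE)
  readr::write_csv(report$ssi_rates, out("ssi_rates.csv"), na = "")
  cells <- report$cells
  readr::write_csv(cells, out("cells.csv"), na = "")
  if (!is.null(report$sir)) {
    readr::write_csv(report$sir, out("sir.csv"), na = "")
  }
  jsonlite::write_json(report$metadata, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' @export
print.neo_unit_report <- function(x, ...) {
  cat("<neo_unit_report>\n")
  cat(sprintf("  patients: %d (%d eligible), patient-days: %d, HAIs: %d\n",
              x$metadata$n_patients, x$metadata$n_eligible,
              x$metadata$patient_days, x$metadata$n_hai))
  if (!is.null(x$sir)) {
    cat(sprintf("  overall SIR: %.3f\n", x$sir$sir[x$sir$scope == "overall"]))
  }
  invisible(x)
}

#' Read a unit's aggregation cells written by [run_unit_analysis()]
#'
#' @param path Path to a `cells.csv`.
#' @param edges Band edges the cells were computed with (checked against
#'   the band labels in the file).
#' @return The cell tibble with its `edges` attribute restored.
#' @export
read_unit_cells <- function(path, edges = default_bands()) {
  cells <- readr::read_csv(path, col_types = readr::cols(
    stratum = readr::col_character(), band = readr::col_character(),
    infections = readr::col_integer(), patient_days = readr::col_integer()
  ), progress = FALSE)
  if (!setequal(unique(cells$band), band_labels(edges))) {
    abort(sprintf("%s: band labels do not match edges %s", path,
                  paste(edges, collapse = ",")))
  }
  attr(cells, "edges") <- edges
  cells
}

#' Pool unit aggregates into reference rates and benchmark each unit
#'
#' Takes the aggregation cell tables of one or more units (from
#' [run_unit_analysis()]'s `cells` element or `cells.csv`), verifies they
#' share band edges, pools them into reference rates (sum of infections
#' over sum of patient-days per birth-weight x day-of-life cell), and
#' computes each unit's SIR against the pooled reference. Outputs contain
#' aggregates only, never patient-level rows.
#'
#' @param units A named list of unit cell tables (names become unit
#'   labels).
#' @param output_dir Optional directory to write `reference_rates.csv`
#'   and `unit_sir.csv`.
#' @return A list with `reference` (a [reference_rates()] object) and
#'   `sir` (tibble `unit`, `observed`, `expected`, `sir`).
#' @export
run_benchmark <- function(units, output_dir = NULL) {
  if (is.data.frame(units)) units <- list(unit1 = units)
  if (is.null(names(units)) || any(!nzchar(names(units)))) {
    names(units) <- sprintf("unit%d", seq_along(units))
  }
  reference <- aggregate_reference(units)
  sir_rows <- lapply(names(units), function(u) {
    cells <- units[[u]]
    risk <- cells[c("stratum", "band", "patient_days")]
    res <- standardized_infection_ratio(sum(cells$infections),
                                        expected_infections(risk, reference))
    tibble(unit = u, observed = res$observed, expected = res$expected,
           sir = res$sir)
  })
  sir <- bind_rows(sir_rows)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    ref_out <- as_tibble(reference)
    readr::write_csv(ref_out, file.path(output_dir, "reference_rates.csv"), na = "")
    readr::write_csv(sir, file.path(output_dir, "unit_sir.csv"), na = "")
    jsonlite::write_json(
      list(band_edges = attr(reference, "edges")),
      file.path(output_dir, "benchmark.json"), auto_unbox = FALSE, digits = NA
    )
  }
  list(reference = reference, sir = sir)
}
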