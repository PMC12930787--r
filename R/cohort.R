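# Cohort data model: the six patient-level input tables, their schemas,
# validation, and lossless CSV round-trip I/O.

SEXES <- c("male", "female", "undetermined")
DELIVERY_MODES <- c("vaginal", "elective_cesarean", "emergency_cesarean")
ADMISSION_TYPES <- c("delivery_room", "transfer_day_of_birth", "transfer_later")
END_REASONS <- c("discharge_or_transfer", "death")
FEEDING_LEVELS <- c("none", "exclusive_breast_milk", "mixed_or_formula")
FINDING_CATEGORIES <- c("clinical", "laboratory", "imaging", "surgical_evidence")
BODY_SYSTEMS <- c("bloodstream", "respiratory", "gastrointestinal", "surgical_site", "other")
SPECIMEN_TYPES <- c("blood", "respiratory", "wound", "other")
WOUND_CLASSES <- c("clean", "clean_contaminated", "contaminated", "dirty")
RESISTANCE_MARKERS <- c("MRSA", "VRE", "3GCR", "carbapenem_resistant", "colistin_resistant")
DEVICES <- c("CVC", "PVC", "INV", "NIV")

# Maps specimen types to the body system an episode belongs to, and body
# systems to their primary specimen site (used by the infection-date rule).
SPECIMEN_BODY_SYSTEM <- c(
  blood = "bloodstream", respiratory = "respiratory",
  wound = "surgical_site", other = "other"
)
PRIMARY_SPECIMEN <- c(
  bloodstream = "blood", respiratory = "respiratory", surgical_site = "wound"
)

cohort_schemas <- function() {
  list(
    patients = readr::cols(
      patient_id = readr::col_character(),
      gestational_weeks = readr::col_integer(),
      gestational_days = readr::col_integer(),
      birth_weight = readr::col_integer(),
      sex = readr::col_character(),
      delivery_mode = readr::col_character(),
      multiple_birth = readr::col_integer(),
      birth_date = readr::col_date(),
      birth_time = readr::col_character(),
      admission_type = readr::col_character(),
      admission_date = readr::col_date(),
      end_date = readr::col_date(),
      end_reason = readr::col_character(),
      live_born = readr::col_logical()
    ),
    stays = readr::cols(
      patient_id = readr::col_character(),
      start_date = readr::col_date(),
      end_date = readr::col_date()
    ),
    exposures = readr::cols(
      patient_id = readr::col_character(),
      date = readr::col_date(),
      cvc_hours = readr::col_double(),
      pvc_hours = readr::col_double(),
      inv_hours = readr::col_double(),
      niv_hours = readr::col_double(),
      antibiotic_substances = readr::col_character(),
      enteral_feeding = readr::col_character(),
      probiotic_given = readr::col_logical(),
      kangaroo_hours = readr::col_double()
    ),
    surgeries = readr::cols(
      surgery_id = readr::col_character(),
      patient_id = readr::col_character(),
      description = readr::col_character(),
      date = readr::col_date(),
      duration_minutes = readr::col_integer(),
      main_procedure_code = readr::col_character(),
      side_procedure_codes = readr::col_character(),
      asa_score = readr::col_integer(),
      wound_class = readr::col_character(),
      endoscopic = readr::col_logical(),
      emergency = readr::col_logical(),
      revision = readr::col_logical(),
      primary_wound_closure = readr::col_logical(),
      implant = readr::col_logical(),
      infection_signs_at_surgery = readr::col_logical()
    ),
    findings = readr::cols(
      patient_id = readr::col_character(),
      date = readr::col_date(),
      category = readr::col_character(),
      criterion_code = readr::col_character(),
      body_system = readr::col_character()
    ),
    microbiology = readr::cols(
      patient_id = readr::col_character(),
      specimen_date = readr::col_date(),
      specimen_type = readr::col_character(),
      organism = readr::col_character(),
      resistance_markers = readr::col_character()
    )
  )
}

empty_table <- function(name) {
  spec <- cohort_schemas()[[name]]$cols
  cols <- lapply(spec, function(ct) {
    switch(class(ct)[1],
      collector_character = character(0),
      collector_integer = integer(0),
      collector_double = double(0),
      collector_logical = logical(0),
      collector_date = as.Date(character(0))
    )
  })
  as_tibble(cols)
}

coerce_table <- function(df, name) {
  template <- empty_table(name)
  missing <- setdiff(names(template), names(df))
  if (length(missing) > 0) {
    abort(sprintf("table '%s': missing column(s) %s", name, paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df)[names(template)]
  for (col in names(template)) {
    target <- template[[col]]
    if (inherits(target, "Date")) {
      df[[col]] <- as_date_strict(df[[col]], sprintf("%s$%s", name, col))
    } else if (is.integer(target)) {
      df[[col]] <- as.integer(df[[col]])
    } else if (is.double(target)) {
      df[[col]] <- as.double(df[[col]])
    } else if (is.logical(target)) {
      df[[col]] <- as.logical(df[[col]])
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  df
}

#' Assemble a surveillance cohort from its component tables
#'
#' A cohort bundles the six patient-level input tables of the surveillance
#' engine: patient demographics/admissions, stay intervals, daily exposure
#' records, surgeries, dated findings, and microbiology results. Any table
#' may be omitted (an empty table is substituted); supplied tables are
#' coerced to the canonical column types.
#'
#' @param patients,stays,exposures,surgeries,findings,microbiology Data
#'   frames following the documented schemas (see the package vignette or
#'   [write_cohort()] for the file layout).
#' @return A list of class `neo_cohort` holding the six tibbles.
#' @seealso [validate_cohort()], [read_cohort()], [write_cohort()]
#' @export
neo_cohort <- function(patients = NULL, stays = NULL, exposures = NULL,
                       surgeries = NULL, findings = NULL, microbiology = NULL) {
  tables <- list(
    patients = patients, stays = stays, exposures = exposures,
    surgeries = surgeries, findings = findings, microbiology = microbiology
  )
  out <- lapply(names(tables), function(nm) {
    if (is.null(tables[[nm]])) empty_table(nm) else coerce_table(tables[[nm]], nm)
  })
  names(out) <- names(tables)
  structure(out, class = "neo_cohort")
}

#' @export
print.neo_cohort <- function(x, ...) {
  cat("<neo_cohort>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

# --- validation ------------------------------------------------------------

located <- function(table, rows, msg) {
  sprintf("%s row %s: %s", table, paste(rows, collapse = ","), msg)
}

#' Validate a cohort against the surveillance data contract
#'
#' Checks every type invariant (value ranges, enumerations, date ordering),
#' uniqueness of per-patient-day exposure rows, foreign-key resolution of
#' patient ids, and membership of criterion codes and organism keys in the
#' active configuration. Validation is total: all problems are collected
#' and reported together, each locating the offending table and row.
#'
#' @param cohort A [neo_cohort()].
#' @param definitions A definitions configuration; criterion codes in
#'   `findings` must belong to its vocabulary.
#' @param catalog An organism catalog; organisms in `microbiology` must be
#'   listed.
#' @return `cohort`, invisibly, if valid; otherwise an error listing every
#'   violation.
#' @export
validate_cohort <- function(cohort, definitions = default_definitions(),
                            catalog = default_organisms()) {
  problems <- cohort_problems(cohort, definitions, catalog)
  if (length(problems) > 0) {
    abort(c("invalid cohort:", setNames(problems, rep("x", length(problems)))))
  }
  invisible(cohort)
}

#' @rdname validate_cohort
#' @return For `cohort_problems()`, a character vector of located
#'   violations (empty when the cohort is valid).
#' @export
cohort_problems <- function(cohort, definitions = default_definitions(),
                            catalog = default_organisms()) {
  stopifnot(inherits(cohort, "neo_cohort"))
  p <- character(0)
  add <- function(cond, table, msg) {
    rows <- which(cond)
    if (length(rows) > 0) p <<- c(p, located(table, rows, msg))
  }
  pt <- cohort$patients
  add(duplicated(pt$patient_id), "patients", "duplicate patient_id")
  add(!is.na(pt$birth_weight) & pt$birth_weight <= 0, "patients", "birth_weight must be > 0")
  add(is.na(pt$birth_weight), "patients", "birth_weight missing")
  add(is.na(pt$gestational_weeks) | pt$gestational_weeks <= 0, "patients", "gestational_weeks must be > 0")
  add(is.na(pt$gestational_days) | pt$gestational_days < 0 | pt$gestational_days > 6,
      "patients", "gestational_days must be in 0..6")
  add(!pt$sex %in% SEXES, "patients", "unknown sex")
  add(!pt$delivery_mode %in% DELIVERY_MODES, "patients", "unknown delivery_mode")
  add(is.na(pt$multiple_birth) | pt$multiple_birth < 1, "patients", "multiple_birth must be >= 1")
  add(!pt$admission_type %in% ADMISSION_TYPES, "patients", "unknown admission_type")
  add(is.na(pt$birth_date) | is.na(pt$admission_date), "patients", "birth/admission date missing")
  add(!is.na(pt$admission_date) & !is.na(pt$birth_date) & pt$admission_date < pt$birth_date,
      "patients", "admission_date before birth_date")
  add(!is.na(pt$end_date) & pt$end_date < pt$admission_date, "patients", "end_date before admission_date")
  add(xor(is.na(pt$end_date), is.na(pt$end_reason)), "patients",
      "end_reason must be present iff end_date is present")
  add(!is.na(pt$end_reason) & !pt$end_reason %in% END_REASONS, "patients", "unknown end_reason")
  add(!is.na(pt$birth_time) & !grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", pt$birth_time),
      "patients", "birth_time must be HH:MM")

  known <- pt$patient_id
  st <- cohort$stays
  add(!st$patient_id %in% known, "stays", "unknown patient_id")
  add(is.na(st$start_date), "stays", "start_date missing")
  add(!is.na(st$end_date) & st$end_date < st$start_date, "stays", "end before start")
  if (nrow(st) > 1) {
    ord <- order(st$patient_id, st$start_date)
    so <- st[ord, ]
    same <- so$patient_id[-1] == so$patient_id[-nrow(so)]
    prev_end <- so$end_date[-nrow(so)]
    overlap <- same & !is.na(prev_end) & so$start_date[-1] <= prev_end
    add(c(FALSE, overlap)[order(ord)], "stays", "overlapping stay intervals for one patient")
  }

  ex <- cohort$exposures
  add(!ex$patient_id %in% known, "exposures", "unknown patient_id")
  add(duplicated(paste(ex$patient_id, ex$date)), "exposures",
      "more than one exposure row per patient-day")
  for (hc in c("cvc_hours", "pvc_hours", "inv_hours", "niv_hours", "kangaroo_hours")) {
    add(is.na(ex[[hc]]) | ex[[hc]] < 0 | ex[[hc]] > 24, "exposures",
        sprintf("%s must be in [0,24]", hc))
  }
  add(!ex$enteral_feeding %in% FEEDING_LEVELS, "exposures", "unknown enteral_feeding")
  add(is.na(ex$probiotic_given), "exposures", "probiotic_given missing")

  sg <- cohort$surgeries
  add(!sg$patient_id %in% known, "surgeries", "unknown patient_id")
  add(duplicated(sg$surgery_id), "surgeries", "duplicate surgery_id")
  add(is.na(sg$duration_minutes) | sg$duration_minutes <= 0, "surgeries", "duration_minutes must be > 0")
  add(is.na(sg$asa_score) | sg$asa_score < 1 | sg$asa_score > 5, "surgeries", "asa_score must be in 1..5")
  add(!sg$wound_class %in% WOUND_CLASSES, "surgeries", "unknown wound_class")

  fd <- cohort$findings
  add(!fd$patient_id %in% known, "findings", "unknown patient_id")
  add(!fd$category %in% FINDING_CATEGORIES, "findings", "unknown category")
  add(!fd$body_system %in% BODY_SYSTEMS, "findings", "unknown body_system")
  vocab <- names(definitions$criteria)
  bad_code <- !fd$criterion_code %in% vocab
  if (any(bad_code)) {
    p <- c(p, located("findings", which(bad_code),
                      sprintf("criterion code not in definitions: %s",
                              paste(unique(fd$criterion_code[bad_code]), collapse = ", "))))
  }

  mb <- cohort$microbiology
  add(!mb$patient_id %in% known, "microbiology", "unknown patient_id")
  add(!mb$specimen_type %in% SPECIMEN_TYPES, "microbiology", "unknown specimen_type")
  bad_org <- !mb$organism %in% catalog$organism
  if (any(bad_org)) {
    p <- c(p, located("microbiology", which(bad_org),
                      sprintf("organism not in catalog: %s",
                              paste(unique(mb$organism[bad_org]), collapse = ", "))))
  }
  if (nrow(mb) > 0) {
    markers_ok <- vapply(mb$resistance_markers, function(m) {
      all(split_set(m) %in% RESISTANCE_MARKERS)
    }, logical(1))
    add(!markers_ok, "microbiology", "unknown resistance marker")
  }
  p
}

# --- I/O -------------------------------------------------------------------

COHORT_FILES <- c(
  patients = "patients.csv", stays = "stays.csv", exposures = "exposures.csv",
  surgeries = "surgeries.csv", findings = "findings.csv",
  microbiology = "microbiology.csv"
)

#' Read a cohort from a directory of CSV files
#'
#' Expects the six files `patients.csv`, `stays.csv`, `exposures.csv`,
#' `surgeries.csv`, `findings.csv`, `microbiology.csv` (UTF-8, comma
#' delimited, header row, ISO-8601 dates). The result is validated; any
#' invariant violation is reported with its table and row.
#'
#' @param dir Directory containing the cohort files.
#' @param definitions,catalog Active configuration used for validation.
#' @param quiet Suppress the per-table row-count message.
#' @return A validated [neo_cohort()].
#' @export
read_cohort <- function(dir, definitions = default_definitions(),
                        catalog = default_organisms(), quiet = FALSE) {
  paths <- file.path(dir, COHORT_FILES)
  missing <- COHORT_FILES[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("missing cohort file(s) in %s: %s", dir, paste(missing, collapse = ", ")))
  }
  schemas <- cohort_schemas()
  tables <- lapply(names(COHORT_FILES), function(nm) {
    readr::read_csv(file.path(dir, COHORT_FILES[[nm]]), col_types = schemas[[nm]],
                    progress = FALSE)
  })
  names(tables) <- names(COHORT_FILES)
  cohort <- do.call(neo_cohort, tables)
  validate_cohort(cohort, definitions, catalog)
  if (!quiet) {
    counts <- vapply(cohort, nrow, integer(1))
    message(paste(sprintf("%s: %d rows", names(counts), counts), collapse = "; "))
  }
  cohort
}

#' Write a cohort to a directory of CSV files
#'
#' Emits the six cohort tables in the layout read by [read_cohort()];
#' the write/read round trip is lossless (field-by-field equality).
#'
#' @param cohort A [neo_cohort()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "neo_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory: %s", dir))
  for (nm in names(COHORT_FILES)) {
    readr::write_csv(cohort[[nm]], file.path(dir, COHORT_FILES[[nm]]), na = "")
  }
  invisible(dir)
}
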