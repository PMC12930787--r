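#' Surveillance definitions configuration
#'
#' The definitions configuration bundles every tunable rule parameter
#' (temporal thresholds in hours or days), the closed criterion-code
#' vocabulary for findings, and the per-infection-type criterion sets.
#' A default configuration implementing the neonatal core-module rule set
#' ships with the package; users may load an edited YAML/JSON copy.
#'
#' @param path Path to a YAML (or JSON) definitions file. For
#'   `default_definitions()` the packaged file is used.
#' @return A list of class `neo_definitions` with elements `parameters`
#'   (named numerics/logicals), `criteria` (criterion code -> category,
#'   body system, optional SSI depth), and `types` (classification rules,
#'   in precedence order).
#' @examples
#' defs <- default_definitions()
#' defs$parameters$late_onset_hours
#' @export
read_definitions <- function(path) {
  if (!file.exists(path)) abort(sprintf("definitions file not found: %s", path))
  raw <- yaml::read_yaml(path)
  validate_definitions(raw)
}

#' @rdname read_definitions
#' @export
default_definitions <- function() {
  read_definitions(system.file("extdata", "definitions.yaml", package = "neosurv"))
}

validate_definitions <- function(x) {
  required <- c(
    "eligibility_bw_grams", "eligibility_ga_weeks", "admission_window_days",
    "absence_merge_hours", "device_day_min_hours", "kangaroo_min_hours",
    "late_onset_hours", "episode_max_span_days", "episode_max_gap_days",
    "repeat_min_days", "symptom_free_min_days", "device_assoc_min_days",
    "ssi_window_days", "ssi_implant_window_days", "secondary_bsi_active_days"
  )
  missing <- setdiff(required, names(x$parameters))
  if (length(missing) > 0) {
    abort(sprintf("definitions: missing parameters: %s", paste(missing, collapse = ", ")))
  }
  num <- x$parameters[required]
  if (any(!vapply(num, is.numeric, logical(1))) || any(unlist(num) <= 0)) {
    abort("definitions: all temporal parameters must be positive numbers")
  }
  if (x$parameters$episode_max_span_days < x$parameters$episode_max_gap_days) {
    abort("definitions: episode_max_span_days must be >= episode_max_gap_days")
  }
  if (is.null(x$criteria) || length(x$criteria) == 0) abort("definitions: empty criteria vocabulary")
  for (code in names(x$criteria)) {
    cr <- x$criteria[[code]]
    if (!cr$category %in% c("clinical", "laboratory", "imaging", "surgical_evidence")) {
      abort(sprintf("definitions: criterion %s has unknown category '%s'", code, cr$category))
    }
    if (!cr$body_system %in% c("bloodstream", "respiratory", "gastrointestinal", "surgical_site", "other")) {
      abort(sprintf("definitions: criterion %s has unknown body system '%s'", code, cr$body_system))
    }
  }
  if (is.null(x$types) || length(x$types) == 0) abort("definitions: no infection types configured")
  structure(x, class = "neo_definitions")
}

#' Organism catalog
#'
#' Maps organism keys to display names and a binary class, recognized
#' pathogen vs common commensal, which determines how a positive blood
#' culture contributes to bloodstream-infection classification. The
#' bundled catalog is a compact default; units may extend it.
#'
#' @param path Path to a YAML catalog file.
#' @return A tibble of class `neo_catalog` with columns `organism`,
#'   `display`, `class`.
#' @examples
#' cat <- default_organisms()
#' subset(cat, class == "common_commensal")
#' @export
read_organisms <- function(path) {
  if (!file.exists(path)) abort(sprintf("organism catalog not found: %s", path))
  raw <- yaml::read_yaml(path)
  out <- tibble(
    organism = names(raw),
    display = vapply(raw, function(e) e$display %||% NA_character_, character(1)),
    class = vapply(raw, function(e) e$class %||% NA_character_, character(1))
  )
  bad <- out$organism[!out$class %in% c("recognized_pathogen", "common_commensal")]
  if (length(bad) > 0) {
    abort(sprintf(
      "organism catalog: class must be recognized_pathogen or common_commensal for: %s",
      paste(bad, collapse = ", ")
    ))
  }
  structure(out, class = c("neo_catalog", class(out)))
}

#' @rdname read_organisms
#' @export
default_organisms <- function() {
  read_organisms(system.file("extdata", "organisms.yaml", package = "neosurv"))
}

organism_class <- function(organisms, catalog) {
  idx <- match(organisms, catalog$organism)
  if (anyNA(idx)) {
    abort(sprintf(
      "unknown organism key(s): %s",
      paste(unique(organisms[is.na(idx)]), collapse = ", ")
    ))
  }
  catalog$class[idx]
}
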