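# Small internal helpers shared across modules.

# Split a semicolon-delimited cell into a character vector; NA or "" is the
# empty set. Used for antibiotic substances, side procedure codes and
# resistance markers, which are sets stored in single CSV cells.
split_set <- function(x) {
  if (length(x) != 1L) stop("split_set() is scalar")
  if (is.na(x) || !nzchar(x)) return(character(0))
  sort(unique(trimws(strsplit(x, ";", fixed = TRUE)[[1]])))
}

join_set <- function(x) {
  x <- sort(unique(x[!is.na(x) & nzchar(x)]))
  if (length(x) == 0L) NA_character_ else paste(x, collapse = ";")
}

# Union of two set-cells.
merge_set_cells <- function(a, b) {
  join_set(c(split_set(a), split_set(b)))
}

as_date_strict <- function(x, what = "date") {
  out <- tryCatch(as.Date(x), error = function(e) NULL)
  if (is.null(out)) abort(sprintf("cannot parse %s: %s", what, paste(x, collapse = ", ")))
  out
}

# Stable md5 of an R object, used to fingerprint configurations in reports
# so that benchmark comparability is machine-checkable.
config_hash <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f), add = TRUE)
  writeLines(deparse(x, control = c("exact", "niceNames")), f, useBytes = TRUE)
  unname(tools::md5sum(f))
}
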