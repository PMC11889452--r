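# Results document: assembly, JSON serialization, parsing, validation.
# Undetermined / absent values are NA internally and null in JSON; key order
# is fixed so identical runs serialize byte-identically.

#' Serialize a results document as JSON
#'
#' Renders the document with a fixed key order, `null` for every
#' undetermined or absent value, and full numeric precision, so two runs on
#' identical input produce byte-identical output.
#'
#' @param results A `results_document` from [run_all()].
#' @return A single JSON string (UTF-8, pretty-printed).
#' @export
serialize_results <- function(results) {
  txt <- jsonlite::toJSON(unclass_deep(results), auto_unbox = TRUE,
                          na = "null", digits = NA, pretty = TRUE)
  paste0(as.character(txt), "\n")
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}

#' Parse a serialized results document
#'
#' Inverse of [serialize_results()]: JSON `null` becomes `NA`, restoring a
#' document that compares equal to the one serialized.
#'
#' @param json A JSON string.
#' @return A `results_document`.
#' @export
parse_results <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  doc <- null_to_na(raw)
  structure(doc, class = "results_document")
}

null_to_na <- function(x) {
  if (is.list(x)) {
    lapply(x, null_to_na)
  } else if (is.null(x)) {
    NA
  } else {
    x
  }
}

#' Validate a results document's structure
#'
#' Checks the document against the contract shipped as
#' `inst/schema/results_schema.json`: required top-level blocks, per-file
#' sub-objects, enumerated states and value ranges. `file_2` sub-objects
#' must be present exactly when the run had two input files.
#'
#' @param results A `results_document` (or a parsed JSON equivalent).
#' @return `TRUE` invisibly; malformed documents raise a usage error
#'   describing the first violation.
#' @export
validate_results <- function(results) {
  need <- c("library_stats", "library_source", "library_type",
            "read_orientation", "read_layout")
  miss <- setdiff(need, names(results))
  if (length(miss)) abort_usage("results document lacks block '%s'", miss[1L])

  two_files <- "file_2" %in% names(results$library_stats)
  files <- if (two_files) c("file_1", "file_2") else "file_1"
  for (f in files) {
    rl <- results$library_stats[[f]]$read_length
    if (is.null(rl) || !all(c("min", "max", "mean", "median", "mode") %in% names(rl))) {
      abort_usage("library_stats.%s.read_length is incomplete", f)
    }
    if (!is_na_scalar(rl$min) && !(rl$min <= rl$mean && rl$mean <= rl$max)) {
      abort_usage("library_stats.%s: mean outside [min, max]", f)
    }
    src <- results$library_source[[f]]
    if (is.null(src) || !all(c("short_name", "taxon_id") %in% names(src))) {
      abort_usage("library_source.%s is incomplete", f)
    }
    if (is_na_scalar(src$short_name) != is_na_scalar(src$taxon_id)) {
      abort_usage("library_source.%s: short_name and taxon_id must be null together", f)
    }
    lay <- results$read_layout[[f]]
    if (is.null(lay) || !all(c("adapt_3", "polya_fraction") %in% names(lay))) {
      abort_usage("read_layout.%s is incomplete", f)
    }
    if (!is_na_scalar(lay$polya_fraction) &&
        (lay$polya_fraction < 0 || lay$polya_fraction > 1)) {
      abort_usage("read_layout.%s.polya_fraction outside [0,1]", f)
    }
  }
  for (blk in c("library_stats", "library_source", "read_layout")) {
    if (("file_2" %in% names(results[[blk]])) != two_files) {
      abort_usage("%s: file_2 presence inconsistent across blocks", blk)
    }
  }
  lt <- results$library_type
  ok_lab <- c("single", "first_mate", "second_mate", "mixed_mates", "undetermined")
  if (!is_na_scalar(lt$file_1) && !lt$file_1 %in% ok_lab) {
    abort_usage("library_type.file_1 has unknown state '%s'", lt$file_1)
  }
  if (!is_na_scalar(lt$relationship) &&
      !lt$relationship %in% c("split_mates", "not_mates", "undetermined")) {
    abort_usage("library_type.relationship has unknown state '%s'", lt$relationship)
  }
  ro <- results$read_orientation
  if (!is_na_scalar(ro$file_1) && !ro$file_1 %in% c("SF", "SR", "U", "undetermined")) {
    abort_usage("read_orientation.file_1 has unknown state '%s'", ro$file_1)
  }
  if (!is_na_scalar(ro$relationship) &&
      !ro$relationship %in% c("ISF", "ISR", "IU", "undetermined")) {
    abort_usage("read_orientation.relationship has unknown state '%s'", ro$relationship)
  }
  invisible(TRUE)
}

is_na_scalar <- function(x) length(x) == 1L && is.na(x)

#' @export
print.results_document <- function(x, ...) {
  cat(serialize_results(x))
  invisible(x)
}
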