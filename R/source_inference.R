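#' Call the library source from a per-organism abundance table
#'
#' The top-ranked organism is assigned as the library source only if its
#' signal clears two configurable cutoffs: a minimum RPM floor
#' (`source_min_rpm`), rejecting libraries in which RP transcripts were
#' essentially not detected, and a minimum ratio between the best and
#' second-best organism (`source_min_ratio`, default 2), rejecting ambiguous
#' calls such as closely related species or absent true sources. A
#' second-best RPM of zero counts as an infinite ratio (sole detection is
#' maximal evidence); tied top RPMs give ratio 1 and are therefore
#' ambiguous.
#'
#' @param abundances An `organism_abundance` table sorted by RPM descending
#'   (as returned by [quantify_reads()]).
#' @param config An [inference_config()].
#' @return A list of class `source_call`: `state` (one of `assigned`,
#'   `unassigned_low_signal`, `unassigned_ambiguous`), `organism`,
#'   `taxon_id` (both `NA` unless assigned), `top_rpm`, `ratio_to_second`.
#' @examples
#' ab <- data.frame(organism = c("hsapiens", "mmusculus"),
#'                  taxon_id = c(9606L, 10090L),
#'                  read_count = c(900, 100), rpm = c(900, 100))
#' infer_source(ab, inference_config())$state
#' @export
infer_source <- function(abundances, config = inference_config()) {
  if (is.null(nrow(abundances)) || nrow(abundances) == 0L) {
    abort_usage("cannot infer a source from an empty abundance table")
  }
  if (is.unsorted(rev(abundances$rpm))) {
    abort_usage("abundance table must be sorted by rpm descending")
  }
  top_rpm <- abundances$rpm[1L]
  second_rpm <- if (nrow(abundances) >= 2L) abundances$rpm[2L] else 0
  ratio <- if (second_rpm == 0) Inf else top_rpm / second_rpm
  if (top_rpm < config$source_min_rpm) {
    state <- "unassigned_low_signal"
  } else if (ratio < config$source_min_ratio) {
    state <- "unassigned_ambiguous"
  } else {
    state <- "assigned"
  }
  structure(
    list(state = state,
         organism = if (state == "assigned") abundances$organism[1L] else NA_character_,
         taxon_id = if (state == "assigned") abundances$taxon_id[1L] else NA_integer_,
         top_rpm = top_rpm,
         ratio_to_second = ratio),
    class = "source_call")
}

#' Resolve the library source, honouring a manual taxon-id override
#'
#' With an override taxon id (`--tax-id` on the command line) the call is
#' assigned directly from the reference annotation, bypassing quantification
#' and all cutoffs; `top_rpm`/`ratio_to_second` are `NA` because no signal
#' was measured. Without an override the decision is delegated to
#' [infer_source()].
#'
#' @param abundances Abundance table (may be `NULL` when an override is
#'   given).
#' @param override_taxon_id Positive integer taxon id present in the
#'   reference, or `NA` for no override.
#' @param reference The `rp_reference` in use.
#' @param config An [inference_config()].
#' @return A `source_call` (see [infer_source()]).
#' @export
resolve_source <- function(abundances, override_taxon_id, reference,
                           config = inference_config()) {
  if (!is.na(override_taxon_id)) {
    hit <- match(as.integer(override_taxon_id), reference$organisms$taxon_id)
    if (is.na(hit)) {
      abort_usage(
        "taxon id %d is not in the reference (%d organisms supported)",
        override_taxon_id, nrow(reference$organisms))
    }
    return(structure(
      list(state = "assigned",
           organism = reference$organisms$organism[hit],
           taxon_id = reference$organisms$taxon_id[hit],
           top_rpm = NA_real_,
           ratio_to_second = NA_real_),
      class = "source_call"))
  }
  infer_source(abundances, config)
}

#' @export
print.source_call <- function(x, ...) {
  if (x$state == "assigned") {
    cat(sprintf("<source_call> %s (taxon %d), rpm %.4g, ratio %.4g\n",
                x$organism, x$taxon_id, x$top_rpm, x$ratio_to_second))
  } else {
    cat(sprintf("<source_call> %s (top rpm %.4g, ratio %.4g)\n",
                x$state, x$top_rpm, x$ratio_to_second))
  }
  invisible(x)
}
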