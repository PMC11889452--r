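#' Load an organism-annotated ribosomal-protein transcript reference
#'
#' Reads a FASTA file whose headers follow the strict pipe-delimited dialect
#' `>transcript_id|organism_short_name|taxon_id` (e.g.
#' `>ENST0001|hsapiens|9606`). The reference is the substrate for library
#' source inference, the alignment fallback and orientation calling.
#' Sequence lines may be wrapped or unwrapped. Validation is strict and
#' loud: duplicate transcript ids, malformed headers, a short name bound to
#' two taxon ids, or ambiguity codes in a sequence are format errors —
#' ambiguous bases would silently poison the k-mer index downstream.
#'
#' @param path Path to the reference FASTA.
#' @return An object of class `rp_reference`: a list with `transcripts`
#'   (data frame: `transcript_id`, `organism`, `taxon_id`, `sequence`) and
#'   `organisms` (data frame: `organism`, `taxon_id`).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1|hsapiens|9606", strrep("ACGT", 15),
#'              ">t2|mmusculus|10090", strrep("GGCA", 15)), fa)
#' ref <- load_rp_reference(fa)
#' ref$organisms
#' @export
load_rp_reference <- function(path) {
  if (!file.exists(path)) abort_input("reference FASTA does not exist: %s", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) abort_format(
                    "could not parse reference FASTA %s: %s", path,
                    conditionMessage(e)))
  if (length(set) == 0L) abort_format("reference FASTA %s has no records", path)
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    abort_format(
      "reference record %d: header '%s' does not match 'transcript_id|short_name|taxon_id'",
      bad[1L], headers[bad[1L]])
  }
  tx <- data.frame(
    transcript_id = vapply(fields, `[[`, "", 1L),
    organism = vapply(fields, `[[`, "", 2L),
    taxon_id = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L))),
    sequence = as.character(set),
    stringsAsFactors = FALSE)
  rownames(tx) <- NULL
  bad <- which(is.na(tx$taxon_id) | tx$taxon_id < 1L)
  if (length(bad)) {
    abort_format("reference record %d ('%s'): taxon_id is not a positive integer",
                 bad[1L], headers[bad[1L]])
  }
  dup <- tx$transcript_id[duplicated(tx$transcript_id)]
  if (length(dup)) {
    abort_format("duplicate transcript_id in reference: %s", dup[1L])
  }
  bad <- which(!grepl("^[ACGT]+$", tx$sequence))
  if (length(bad)) {
    abort_format(
      "reference transcript '%s' contains bases outside ACGT (ambiguity codes are rejected)",
      tx$transcript_id[bad[1L]])
  }
  orgs <- unique(tx[, c("organism", "taxon_id")])
  rownames(orgs) <- NULL
  inconsistent <- orgs$organism[duplicated(orgs$organism)]
  if (length(inconsistent)) {
    abort_format("organism short name '%s' is bound to more than one taxon_id",
                 inconsistent[1L])
  }
  if (anyDuplicated(orgs$taxon_id)) {
    abort_format("taxon_id %d is bound to more than one organism short name",
                 orgs$taxon_id[duplicated(orgs$taxon_id)][1L])
  }
  structure(list(transcripts = tx, organisms = orgs), class = "rp_reference")
}

#' Write a reference in the package's FASTA dialect
#'
#' Inverse of [load_rp_reference()]; sequences are written unwrapped.
#'
#' @param reference An `rp_reference` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_rp_reference <- function(reference, path) {
  tx <- reference$transcripts
  lines <- as.vector(rbind(
    sprintf(">%s|%s|%d", tx$transcript_id, tx$organism, tx$taxon_id),
    tx$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.rp_reference <- function(x, ...) {
  cat(sprintf("<rp_reference> %d transcripts, %d organisms\n",
              nrow(x$transcripts), nrow(x$organisms)))
  invisible(x)
}
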