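#' Parse Illumina sequence identifiers
#'
#' Recognizes the two systematic Illumina header grammars and extracts the
#' mate index and the mate-invariant core identifier:
#' * `casava_1_8`: `instrument:run:flowcell:lane:tile:x:y mate:filtered:control:index`
#'   with mate 1 or 2; the core id is the seven-field coordinate part.
#' * `pre_casava_1_8`: a coordinate stem ending in `#index/mate` or `/mate`
#'   with mate 1 or 2; the core id is everything before `/mate`.
#'
#' Anything else is dialect `unknown` with no mate index — never an error,
#' since unrecognized headers simply trigger the alignment fallback.
#'
#' @param identifiers Character vector of FASTQ identifiers (no leading
#'   `@`).
#' @return A data frame with columns `dialect` (`casava_1_8`,
#'   `pre_casava_1_8`, `unknown`), `core_id`, `mate` (integer 1, 2 or `NA`).
#' @examples
#' parse_identifier("M01234:123:FC1:1:1101:15589:1331 1:N:0:ATCACG")
#' parse_identifier("HWUSI-EAS100R:6:73:941:1973#0/2")
#' @export
parse_identifier <- function(identifiers) {
  n <- length(identifiers)
  dialect <- rep("unknown", n)
  core <- identifiers
  mate <- rep(NA_integer_, n)

  casava <- "^([^:[:space:]]+:[^:[:space:]]*:[^:[:space:]]+:[0-9]+:[0-9]+:[0-9]+:[0-9]+) ([12]):[YN]:[0-9]+:[^[:space:]]+$"
  m <- regmatches(identifiers, regexec(casava, identifiers))
  hit <- lengths(m) == 3L
  dialect[hit] <- "casava_1_8"
  core[hit] <- vapply(m[hit], `[[`, "", 2L)
  mate[hit] <- as.integer(vapply(m[hit], `[[`, "", 3L))

  pre <- "^([^[:space:]]+?(?:#[^/[:space:]]+)?)/([12])$"
  left <- !hit
  m2 <- regmatches(identifiers[left], regexec(pre, identifiers[left]))
  hit2 <- lengths(m2) == 3L
  idx2 <- which(left)[hit2]
  dialect[idx2] <- "pre_casava_1_8"
  core[idx2] <- vapply(m2[hit2], `[[`, "", 2L)
  mate[idx2] <- as.integer(vapply(m2[hit2], `[[`, "", 3L))

  data.frame(dialect = dialect, core_id = core, mate = mate,
             stringsAsFactors = FALSE)
}

#' Infer the library type from sequence identifiers
#'
#' The fast path of library-type inference: if mate information is encoded
#' in a recognized Illumina grammar, single- vs paired-end structure and the
#' split-mates relationship of two files can be decided without touching the
#' reads. For two files the core identifiers must agree *position by
#' position* — mate files written by one sequencing run are ordered
#' identically, so a permutation means the files are not each other's mates.
#' If any identifier in play has an unknown dialect the result is
#' inconclusive (`conclusive = FALSE`) and the caller falls back to
#' alignment concordance.
#'
#' @param ids_1 Parsed identifiers of file 1 ([parse_identifier()] output).
#' @param ids_2 Parsed identifiers of file 2, or `NULL` for single-file
#'   input.
#' @return A list of class `library_type_call`: `file_1`, `file_2` (one of
#'   `single`, `first_mate`, `second_mate`, `mixed_mates`, `undetermined`;
#'   `file_2` is `NA` for one file), `relationship` (`split_mates`,
#'   `not_mates`, `undetermined`, or `NA` for one file), and `conclusive`
#'   (FALSE when the alignment fallback is needed).
#' @export
infer_type_from_ids <- function(ids_1, ids_2 = NULL) {
  if (is.null(nrow(ids_1)) || nrow(ids_1) == 0L) {
    abort_usage("cannot infer library type from an empty identifier list")
  }
  if (is.null(ids_2)) {
    return(structure(
      list(file_1 = file_label_from_mates(ids_1$mate),
           file_2 = NA_character_,
           relationship = NA_character_,
           conclusive = TRUE),
      class = "library_type_call"))
  }
  if (nrow(ids_2) == 0L) {
    abort_usage("cannot infer library type from an empty identifier list")
  }
  if (any(ids_1$dialect == "unknown") || any(ids_2$dialect == "unknown")) {
    return(structure(
      list(file_1 = "undetermined", file_2 = "undetermined",
           relationship = "undetermined", conclusive = FALSE),
      class = "library_type_call"))
  }
  lab_1 <- file_label_from_mates(ids_1$mate)
  lab_2 <- file_label_from_mates(ids_2$mate)
  opposite <- (lab_1 == "first_mate" && lab_2 == "second_mate") ||
    (lab_1 == "second_mate" && lab_2 == "first_mate")
  relationship <- if (opposite &&
                      nrow(ids_1) == nrow(ids_2) &&
                      all(ids_1$core_id == ids_2$core_id)) {
    "split_mates"
  } else {
    "not_mates"
  }
  structure(
    list(file_1 = lab_1, file_2 = lab_2, relationship = relationship,
         conclusive = TRUE),
    class = "library_type_call")
}

file_label_from_mates <- function(mates) {
  if (all(is.na(mates))) return("single")
  if (anyNA(mates)) return("undetermined")
  if (all(mates == 1L)) return("first_mate")
  if (all(mates == 2L)) return("second_mate")
  "mixed_mates"
}

#' Infer the mate relationship from alignment concordance
#'
#' The fallback path when identifiers carry no usable mate information.
#' Files sampled symmetrically make record i of each file a putative pair; a
#' pair is concordant when both reads align to the same transcript on
#' opposite strands facing inward (the `+`-strand hit starts at or before
#' the `-`-strand hit's end). With at least `min_mapped_reads` both-mapped
#' pairs, a concordant fraction at or above
#' `paired_min_concordant_fraction` calls `split_mates`, below it
#' `not_mates`; with fewer pairs the relationship stays `undetermined`.
#'
#' @param hits_1,hits_2 `alignment_hits` for the two files (best hit per
#'   read, keyed by `read_index`).
#' @param config An [inference_config()].
#' @return One of `"split_mates"`, `"not_mates"`, `"undetermined"`.
#' @export
infer_type_from_alignments <- function(hits_1, hits_2,
                                       config = inference_config()) {
  pairs <- concordant_pairs(hits_1, hits_2)
  if (pairs$n_pairs < config$min_mapped_reads) return("undetermined")
  frac <- pairs$n_concordant / pairs$n_pairs
  if (frac >= config$paired_min_concordant_fraction) "split_mates" else "not_mates"
}

# Join best hits of two mate files on read_index and classify each
# both-mapped pair as concordant (same transcript, opposite strands,
# inward-facing) or not. Returns per-pair detail for orientation calling.
concordant_pairs <- function(hits_1, hits_2) {
  m <- merge(as.data.frame(hits_1), as.data.frame(hits_2),
             by = "read_index", suffixes = c("_1", "_2"))
  if (nrow(m) == 0L) {
    return(list(n_pairs = 0L, n_concordant = 0L,
                concordant = m, mate1_plus = logical(0)))
  }
  same_tx <- m$transcript_id_1 == m$transcript_id_2
  opposite <- m$strand_1 != m$strand_2
  plus_start <- ifelse(m$strand_1 == "+", m$start_1, m$start_2)
  minus_end <- ifelse(m$strand_1 == "-", m$end_1, m$end_2)
  inward <- plus_start <= minus_end
  ok <- same_tx & opposite & inward
  list(n_pairs = nrow(m),
       n_concordant = sum(ok),
       concordant = m[ok, , drop = FALSE],
       mate1_plus = m$strand_1[ok] == "+")
}

#' @export
print.library_type_call <- function(x, ...) {
  cat(sprintf("<library_type_call> file_1 %s, file_2 %s, relationship %s%s\n",
              x$file_1, x$file_2, x$relationship,
              if (isTRUE(x$conclusive)) "" else " (inconclusive ids)"))
  invisible(x)
}
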