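#' Call single-file read orientation (SF / SR / U)
#'
#' The orientation of a library follows from how many reads had to be
#' reverse-complemented to align: the forward fraction is the share of
#' `+`-strand best hits among mapped reads. At or above `orient_high`
#' (default 0.85) the library is stranded-forward (SF); at or below
#' `orient_low` (default 0.15) stranded-reverse (SR); in between unstranded
#' (U). Fewer than `min_mapped_reads` mapped reads yield `undetermined` —
#' a 50/50 unstranded library with only a handful of mapped reads could
#' breach the bands by chance. Unmapped reads carry no strand information
#' and are excluded from the denominator.
#'
#' @param hits `alignment_hits` (best hit per read).
#' @param config An [inference_config()].
#' @return A list of class `orientation_call`: `state` (`SF`, `SR`, `U`,
#'   `undetermined`), `mapped_reads`, `forward_fraction` (`NA` when no read
#'   mapped).
#' @export
infer_orientation_single <- function(hits, config = inference_config()) {
  mapped <- nrow(hits)
  fwd_frac <- if (mapped >= 1L) mean(hits$strand == "+") else NA_real_
  state <- if (mapped < config$min_mapped_reads) {
    "undetermined"
  } else if (fwd_frac >= config$orient_high) {
    "SF"
  } else if (fwd_frac <= config$orient_low) {
    "SR"
  } else {
    "U"
  }
  structure(list(state = state, mapped_reads = mapped,
                 forward_fraction = fwd_frac),
            class = "orientation_call")
}

#' Call paired-end relative orientation (ISF / ISR / IU)
#'
#' For split-mate input the inward-facing concordant pairs (same transcript,
#' opposite strands — the only geometry Illumina paired-end RNA-seq
#' produces) are classified by the strand of the first mate: the fraction of
#' concordant pairs whose mate 1 aligned forward is compared against the
#' same bands as in the single-file case, giving inward-stranded-forward
#' (ISF), inward-stranded-reverse (ISR) or inward-unstranded (IU). The
#' evidence floor `min_mapped_reads` applies to the concordant-pair count.
#' Per-file SF/SR/U states are also computed for each mate file
#' independently.
#'
#' @param hits_1,hits_2 `alignment_hits` of the two mate files.
#' @param config An [inference_config()].
#' @return A list of class `paired_orientation_call`: `relationship`
#'   (`ISF`, `ISR`, `IU`, `undetermined`), `file_1`, `file_2`
#'   (single-file `orientation_call`s), `concordant_pairs`,
#'   `mate1_forward_fraction`.
#' @export
infer_orientation_paired <- function(hits_1, hits_2,
                                     config = inference_config()) {
  pairs <- concordant_pairs(hits_1, hits_2)
  n_conc <- pairs$n_concordant
  frac <- if (n_conc >= 1L) mean(pairs$mate1_plus) else NA_real_
  relationship <- if (n_conc < config$min_mapped_reads) {
    "undetermined"
  } else if (frac >= config$orient_high) {
    "ISF"
  } else if (frac <= config$orient_low) {
    "ISR"
  } else {
    "IU"
  }
  structure(
    list(relationship = relationship,
         file_1 = infer_orientation_single(hits_1, config),
         file_2 = infer_orientation_single(hits_2, config),
         concordant_pairs = n_conc,
         mate1_forward_fraction = frac),
    class = "paired_orientation_call")
}

#' @export
print.orientation_call <- function(x, ...) {
  cat(sprintf("<orientation_call> %s (%d mapped, forward fraction %s)\n",
              x$state, x$mapped_reads, format(x$forward_fraction)))
  invisible(x)
}
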