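#' Inference configuration
#'
#' Collects every tunable threshold of the inference pipeline with its
#' default. All cutoffs the method describes as configurable live here; the
#' defaults are the package's study conditions and are documented per field.
#'
#' @param records_limit Maximum number of FASTQ records to read per input
#'   file (the file prefix, applied to each file independently so mate files
#'   stay index-aligned). Default 1e6. `Inf` disables the limit.
#' @param tax_id Optional taxon identifier overriding library-source
#'   inference (e.g. 9606 for human). Must be present in the reference.
#'   `NA` (default) means infer from the data.
#' @param kmer_k k-mer size for the pseudo-alignment quantifier; odd,
#'   >= 11. Default 21.
#' @param seed_len Seed length (nt) for the seed-and-extend aligner.
#'   Default 20.
#' @param min_identity Minimum fraction of matching bases for an alignment
#'   to be reported. Default 0.9.
#' @param source_min_rpm Minimum RP signal (reads per million processed
#'   reads) required to assign a library source. Default 5.
#' @param source_min_ratio Minimum ratio between best and second-best
#'   organism RPM to assign a source. Default 2.
#' @param min_mapped_reads Minimum number of mapped reads (or concordant
#'   pairs) supporting an orientation or mate-concordance call. Default 20.
#' @param orient_low,orient_high Forward-strand-fraction thresholds:
#'   at or below `orient_low` calls stranded-reverse, at or above
#'   `orient_high` calls stranded-forward, in between unstranded.
#'   Defaults 0.15 / 0.85.
#' @param paired_min_concordant_fraction Minimum fraction of both-mapped
#'   read pairs that must align concordantly (same transcript, opposite
#'   strands, inward-facing) to call two files split mates. Default 0.75.
#' @param adapter_min_fraction Minimum per-read adapter prevalence for an
#'   adapter call. Default 0.02.
#' @param adapter_min_ratio Minimum best/second-best adapter prevalence
#'   ratio. Default 2.
#' @param polya_min_length Minimum length of a 3'-terminal adenosine run for
#'   a read to count as poly(A)-positive. Default 10.
#' @param polya_max_mismatches Number of non-A bases tolerated inside the
#'   terminal window of `polya_min_length` bases. Default 0 (strict run).
#'
#' @return An object of class `inference_config` (a named list).
#' @examples
#' cfg <- inference_config(records_limit = 1000)
#' cfg$source_min_ratio
#' @export
inference_config <- function(records_limit = 1e6,
                             tax_id = NA_integer_,
                             kmer_k = 21L,
                             seed_len = 20L,
                             min_identity = 0.9,
                             source_min_rpm = 5,
                             source_min_ratio = 2,
                             min_mapped_reads = 20L,
                             orient_low = 0.15,
                             orient_high = 0.85,
                             paired_min_concordant_fraction = 0.75,
                             adapter_min_fraction = 0.02,
                             adapter_min_ratio = 2,
                             polya_min_length = 10L,
                             polya_max_mismatches = 0L) {
  cfg <- list(
    records_limit = records_limit,
    tax_id = as.integer(tax_id),
    kmer_k = as.integer(kmer_k),
    seed_len = as.integer(seed_len),
    min_identity = min_identity,
    source_min_rpm = source_min_rpm,
    source_min_ratio = source_min_ratio,
    min_mapped_reads = as.integer(min_mapped_reads),
    orient_low = orient_low,
    orient_high = orient_high,
    paired_min_concordant_fraction = paired_min_concordant_fraction,
    adapter_min_fraction = adapter_min_fraction,
    adapter_min_ratio = adapter_min_ratio,
    polya_min_length = as.integer(polya_min_length),
    polya_max_mismatches = as.integer(polya_max_mismatches)
  )
  validate_config(cfg)
  structure(cfg, class = "inference_config")
}

validate_config <- function(cfg) {
  stopifnot_usage(is.numeric(cfg$records_limit) && length(cfg$records_limit) == 1L &&
                    (is.infinite(cfg$records_limit) || cfg$records_limit >= 1),
                  "records_limit must be a positive count or Inf")
  stopifnot_usage(is.na(cfg$tax_id) || cfg$tax_id >= 1L,
                  "tax_id must be a positive integer")
  stopifnot_usage(cfg$kmer_k >= 11L && cfg$kmer_k %% 2L == 1L,
                  "kmer_k must be odd and >= 11")
  stopifnot_usage(cfg$seed_len >= 1L, "seed_len must be >= 1")
  stopifnot_usage(cfg$min_identity > 0 && cfg$min_identity <= 1,
                  "min_identity must be in (0, 1]")
  stopifnot_usage(cfg$source_min_rpm >= 0, "source_min_rpm must be >= 0")
  stopifnot_usage(cfg$source_min_ratio >= 1, "source_min_ratio must be >= 1")
  stopifnot_usage(cfg$min_mapped_reads >= 1L, "min_mapped_reads must be >= 1")
  stopifnot_usage(cfg$orient_low >= 0 && cfg$orient_low < cfg$orient_high &&
                    cfg$orient_high <= 1,
                  "need 0 <= orient_low < orient_high <= 1")
  stopifnot_usage(cfg$paired_min_concordant_fraction >= 0 &&
                    cfg$paired_min_concordant_fraction <= 1,
                  "paired_min_concordant_fraction must be in [0, 1]")
  stopifnot_usage(cfg$adapter_min_fraction >= 0 && cfg$adapter_min_fraction <= 1,
                  "adapter_min_fraction must be in [0, 1]")
  stopifnot_usage(cfg$adapter_min_ratio >= 1, "adapter_min_ratio must be >= 1")
  stopifnot_usage(cfg$polya_min_length >= 1L, "polya_min_length must be >= 1")
  stopifnot_usage(cfg$polya_max_mismatches >= 0L,
                  "polya_max_mismatches must be >= 0")
  invisible(cfg)
}

stopifnot_usage <- function(ok, msg) {
  if (!isTRUE(ok)) abort_usage("%s", msg)
}

#' @export
print.inference_config <- function(x, ...) {
  cat("<inference_config>\n")
  for (nm in names(x)) cat(sprintf("  %-32s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
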