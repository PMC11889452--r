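# Classed error conditions. Three families, mirroring the exit-code contract
# of the command-line tool: input (missing/unreadable files), format (malformed
# FASTQ/FASTA/adapter files), usage (invalid arguments or empty inputs).

abort_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fastqmeta_input_error", "fastqmeta_error")))
}

abort_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fastqmeta_format_error", "fastqmeta_error")))
}

abort_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fastqmeta_usage_error", "fastqmeta_error")))
}
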