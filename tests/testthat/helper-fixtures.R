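# Shared fixture builders. Everything is generated in code at test time.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

# fastq_records data frame from bare sequences.
make_records <- function(seqs, ids = sprintf("read_%04d", seq_along(seqs))) {
  structure(
    data.frame(identifier = ids, sequence = seqs,
               quality = strrep("I", nchar(seqs)),
               stringsAsFactors = FALSE),
    class = c("fastq_records", "data.frame"))
}

# rp_reference straight from vectors (bypasses FASTA round trip).
make_reference <- function(ids, organisms, taxa, seqs) {
  tx <- data.frame(transcript_id = ids, organism = organisms,
                   taxon_id = as.integer(taxa), sequence = seqs,
                   stringsAsFactors = FALSE)
  orgs <- unique(tx[, c("organism", "taxon_id")])
  rownames(orgs) <- NULL
  structure(list(transcripts = tx, organisms = orgs), class = "rp_reference")
}

# Write a 4-line-per-record FASTQ fixture and return its path.
write_fastq_lines <- function(lines, gzip = FALSE) {
  path <- tempfile(fileext = if (gzip) ".fastq.gz" else ".fastq")
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con)
  close(con)
  path
}

# Abundance table in the sorted form infer_source() expects.
make_abundance <- function(organisms, taxa, rpm, processed = 1e6) {
  df <- data.frame(organism = organisms, taxon_id = as.integer(taxa),
                   read_count = rpm * processed / 1e6, rpm = rpm,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$rpm, df$taxon_id), ]
  rownames(df) <- NULL
  structure(df, class = c("organism_abundance", "data.frame"),
            processed_reads = processed, mapped_reads = sum(df$read_count))
}

# Alignment-hit table from parallel vectors.
make_hits <- function(read_index, transcript_id, strand, start, end,
                      matches = end - start) {
  structure(
    data.frame(read_index = read_index, transcript_id = transcript_id,
               strand = strand, start = start, end = end, matches = matches,
               stringsAsFactors = FALSE),
    class = c("alignment_hits", "data.frame"))
}
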