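#' Read a FASTQ file, plain or gzip-compressed
#'
#' Streams 4-line FASTQ records from `path`, stopping after `max_records`
#' records. Compression is detected from the file content (gzip magic bytes),
#' never from the extension. Bases are uppercased; records are validated
#' (equal sequence/quality length, non-empty sequence, alphabet `ACGTN`).
#' Multi-line-wrapped FASTQ is rejected: Illumina writers emit strict 4-line
#' records, and silent re-wrapping would desynchronize mate files.
#'
#' @param path Path to a FASTQ file (plain or gzipped).
#' @param max_records Maximum number of records to return (the file prefix);
#'   `Inf` reads the whole file.
#' @return A data frame of class `fastq_records` with character columns
#'   `identifier` (header without the leading `@`), `sequence`, `quality`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "acgt", "+", "IIII"), fq)
#' read_fastq(fq)$sequence
#' @export
read_fastq <- function(path, max_records = Inf) {
  if (!file.exists(path)) abort_input("input file does not exist: %s", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  chunk_records <- 65536L
  lines <- character(0)
  n_read <- 0
  repeat {
    want <- if (is.finite(max_records)) {
      min(chunk_records, max_records - n_read) * 4L
    } else 4L * chunk_records
    if (want <= 0) break
    got <- readLines(con, n = want, warn = FALSE)
    lines <- c(lines, got)
    n_read <- length(lines) %/% 4L
    if (length(got) < want) break
  }
  if (length(lines) %% 4L != 0L) {
    abort_format(
      "truncated FASTQ record at end of %s: %d trailing line(s) after record %d",
      path, length(lines) %% 4L, length(lines) %/% 4L)
  }
  fastq_from_lines(lines, path)
}

# Vectorized 4-line record validation shared by read_fastq and parse_record.
fastq_from_lines <- function(lines, origin = "<lines>") {
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  headers <- lines[4L * idx - 3L]
  seqs <- lines[4L * idx - 2L]
  seps <- lines[4L * idx - 1L]
  quals <- lines[4L * idx]

  bad <- which(!startsWith(headers, "@"))
  if (length(bad)) {
    abort_format("record %d in %s: header does not start with '@' (%s)",
                 bad[1L], origin, headers[bad[1L]])
  }
  bad <- which(!startsWith(seps, "+"))
  if (length(bad)) {
    abort_format("record %d in %s: missing '+' separator line", bad[1L], origin)
  }
  seqs <- toupper(seqs)
  bad <- which(nchar(seqs) == 0L)
  if (length(bad)) {
    abort_format("record %d in %s: empty sequence", bad[1L], origin)
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    abort_format("record %d in %s: sequence length %d != quality length %d",
                 bad[1L], origin, nchar(seqs[bad[1L]]), nchar(quals[bad[1L]]))
  }
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad)) {
    abort_format("record %d in %s: sequence contains characters outside ACGTN",
                 bad[1L], origin)
  }
  structure(
    data.frame(identifier = substring(headers, 2L),
               sequence = seqs,
               quality = quals,
               stringsAsFactors = FALSE),
    class = c("fastq_records", "data.frame"))
}

#' Parse one 4-line FASTQ record
#'
#' @param lines Character vector of exactly four lines: header (starting
#'   `@`), sequence, separator (starting `+`), quality.
#' @return A one-row `fastq_records` data frame.
#' @examples
#' parse_fastq_record(c("@r1 1:N:0:ACGT", "ACGT", "+", "IIII"))
#' @export
parse_fastq_record <- function(lines) {
  if (length(lines) != 4L) {
    abort_format("a FASTQ record has 4 lines, got %d", length(lines))
  }
  fastq_from_lines(lines, "<record>")
}

#' Write FASTQ records
#'
#' Inverse of [read_fastq()]: writes strict 4-line records, optionally
#' gzip-compressed.
#'
#' @param records A `fastq_records` data frame.
#' @param path Output path.
#' @param gzip Compress the output with gzip.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path, gzip = FALSE) {
  lines <- as.vector(rbind(paste0("@", records$identifier),
                           records$sequence,
                           "+",
                           records$quality))
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
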