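#' Build a canonical k-mer index over an RP reference
#'
#' Indexes every k-mer of every reference transcript under its canonical
#' form (the lexicographic minimum of the k-mer and its reverse complement),
#' so that lookups are strand-agnostic: the library source must be callable
#' before read orientation is known. k-mers containing non-ACGT characters
#' are skipped (reference sequences never contain them; read k-mers with N
#' simply never match).
#'
#' @param reference An `rp_reference` from [load_rp_reference()].
#' @param k Odd k-mer size >= 11; default 21. Odd k prevents palindromic
#'   k-mers that are their own reverse complement.
#' @return An object of class `kmer_index`: environment-backed hash from
#'   canonical k-mer to integer vector of transcript indices, plus the
#'   organism annotation needed by [quantify_reads()].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1|orga|9001", strrep("ACGTG", 10)), fa)
#' idx <- build_kmer_index(load_rp_reference(fa), k = 11)
#' idx$k
#' @export
build_kmer_index <- function(reference, k = 21L) {
  k <- as.integer(k)
  if (k < 11L || k %% 2L == 0L) abort_usage("k must be odd and >= 11, got %d", k)
  tx <- reference$transcripts
  if (all(nchar(tx$sequence) < k)) {
    abort_usage("all %d reference transcripts are shorter than k = %d",
                nrow(tx), k)
  }
  kmer_list <- lapply(tx$sequence, kmers_of, k = k)
  tx_idx <- rep.int(seq_len(nrow(tx)), lengths(kmer_list))
  kmers <- unlist(kmer_list, use.names = FALSE)
  keep <- !grepl("[^ACGT]", kmers)
  kmers <- canonical_kmer(kmers[keep])
  tx_idx <- tx_idx[keep]
  pairs <- unique(data.frame(kmer = kmers, tx = tx_idx,
                             stringsAsFactors = FALSE))
  map <- list2env(split(pairs$tx, pairs$kmer), hash = TRUE,
                  size = max(16L, nrow(pairs)))
  structure(
    list(k = k,
         map = map,
         n_kmers = length(map),
         transcript_id = tx$transcript_id,
         organism = tx$organism,
         taxon_id = tx$taxon_id,
         organisms = reference$organisms),
    class = "kmer_index")
}

#' Quantify per-organism RP abundance by pseudo-alignment
#'
#' Assigns each read to the set of reference transcripts compatible with its
#' canonical k-mers: the intersection of the transcript sets of all k-mers
#' that occur in the index (k-mers absent from the index are ignored; a read
#' none of whose k-mers occur, or whose intersection is empty, is unmapped).
#' A mapped read contributes total weight 1, split equally among the
#' distinct organisms represented in its compatibility set, so read mass is
#' conserved exactly.
#'
#' @param reads A `fastq_records` data frame.
#' @param index A `kmer_index` built from the reference whose organisms the
#'   output reports.
#' @return A data frame of class `organism_abundance` with one row per
#'   reference organism (zeros included): `organism`, `taxon_id`,
#'   `read_count`, `rpm` (read_count per million processed reads), sorted by
#'   `rpm` descending, ties broken by `taxon_id` ascending. Attributes
#'   `processed_reads` and `mapped_reads` carry the denominators.
#' @export
quantify_reads <- function(reads, index) {
  n_reads <- nrow(reads)
  if (is.null(n_reads) || n_reads == 0L) {
    abort_usage("cannot quantify an empty read stream")
  }
  k <- index$k
  kmer_list <- lapply(reads$sequence, kmers_of, k = k)
  read_idx <- rep.int(seq_len(n_reads), lengths(kmer_list))
  kmers <- unlist(kmer_list, use.names = FALSE)
  if (length(kmers)) {
    keep <- !grepl("[^ACGT]", kmers)
    read_idx <- read_idx[keep]
    kmers <- canonical_kmer(kmers[keep])
  }
  hits <- if (length(kmers)) {
    mget(kmers, envir = index$map, ifnotfound = list(NULL))
  } else list()
  counts <- setNames(numeric(nrow(index$organisms)), index$organisms$organism)
  mapped <- 0L
  if (length(hits)) {
    matched <- !vapply(hits, is.null, logical(1))
    by_read <- split(hits[matched], read_idx[matched])
    for (sets in by_read) {
      compat <- Reduce(intersect, sets)
      if (length(compat) == 0L) next
      orgs <- unique(index$organism[compat])
      counts[orgs] <- counts[orgs] + 1 / length(orgs)
      mapped <- mapped + 1L
    }
  }
  out <- data.frame(
    organism = index$organisms$organism,
    taxon_id = index$organisms$taxon_id,
    read_count = as.numeric(counts[index$organisms$organism]),
    stringsAsFactors = FALSE)
  out$rpm <- out$read_count * 1e6 / n_reads
  out <- out[order(-out$rpm, out$taxon_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("organism_abundance", "data.frame"),
            processed_reads = n_reads,
            mapped_reads = mapped)
}

#' Write an abundance table as TSV
#'
#' Debug output mirroring the per-organism table the source call is made
#' from.
#'
#' @param abundances An `organism_abundance` data frame.
#' @param path Output TSV path (or `""` for stdout).
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(abundances, path = "") {
  df <- as.data.frame(abundances)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
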