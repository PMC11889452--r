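#' Align reads to one organism's RP transcripts (ungapped seed-and-extend)
#'
#' A deliberately small, exactly specified aligner feeding the library-type
#' fallback and orientation calls: it answers "which transcript, where, and
#' did the read need reverse complementing", nothing more. For each read
#' (and its reverse complement) the first `seed_len`-mer and every further
#' `seed_len`-mer at stride `seed_len` are looked up in an exact index of
#' the transcript set; every seed occurrence implies one ungapped full-read
#' placement, which is scored by its number of matching bases. The best
#' placement is reported if it reaches `ceiling(min_identity * read
#' length)` matches; ties break to the `+` strand, then the lowest
#' transcript id, then the lowest start. Reads shorter than `seed_len`, or
#' without any seeded placement, are unmapped (no error).
#'
#' @param reads A `fastq_records` data frame.
#' @param transcripts Rows of `rp_reference$transcripts` restricted to one
#'   organism.
#' @param config An [inference_config()] (`seed_len`, `min_identity`).
#' @return A data frame of class `alignment_hits` with one row per mapped
#'   read: `read_index`, `transcript_id`, `strand` (`+` read as-is, `-`
#'   reverse complement), `start` (0-based inclusive), `end` (exclusive),
#'   `matches`.
#' @export
align_reads <- function(reads, transcripts, config = inference_config()) {
  if (is.null(nrow(transcripts)) || nrow(transcripts) == 0L) {
    abort_usage("cannot align against an empty transcript set")
  }
  if (length(unique(transcripts$organism)) > 1L) {
    abort_usage("alignment target must be restricted to a single organism")
  }
  sl <- config$seed_len
  seed_map <- build_seed_index(transcripts$sequence, sl)
  tx_len <- nchar(transcripts$sequence)
  n <- nrow(reads)
  fwd <- reads$sequence
  rev <- revcomp(fwd)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    hit <- align_one(fwd[i], rev[i], seed_map, transcripts, tx_len, sl,
                     config$min_identity)
    if (!is.null(hit)) {
      hit$read_index <- i
      out[[i]] <- hit
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) {
    do.call(rbind, lapply(out, function(h) {
      data.frame(read_index = h$read_index, transcript_id = h$transcript_id,
                 strand = h$strand, start = h$start, end = h$end,
                 matches = h$matches, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(read_index = integer(0), transcript_id = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               matches = integer(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  structure(res, class = c("alignment_hits", "data.frame"))
}

# Exact index of all seed_len-mers of the transcript set:
# seed string -> integer matrix with columns (tx, pos), pos 1-based.
build_seed_index <- function(sequences, seed_len) {
  seed_list <- lapply(sequences, kmers_of, k = seed_len)
  tx <- rep.int(seq_along(sequences), lengths(seed_list))
  pos <- unlist(lapply(lengths(seed_list), seq_len), use.names = FALSE)
  seeds <- unlist(seed_list, use.names = FALSE)
  if (is.null(seeds)) seeds <- character(0)
  occ <- split(seq_along(seeds), seeds)
  map <- new.env(hash = TRUE, size = max(16L, length(occ)))
  for (s in names(occ)) {
    idx <- occ[[s]]
    assign(s, cbind(tx = tx[idx], pos = pos[idx]), envir = map)
  }
  map
}

align_one <- function(fwd, rev, seed_map, transcripts, tx_len, seed_len,
                      min_identity) {
  L <- nchar(fwd)
  if (L < seed_len) return(NULL)
  offsets <- seq.int(1L, L - seed_len + 1L, by = seed_len)
  cand <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") fwd else rev
    for (o in offsets) {
      occ <- get0(substr(s, o, o + seed_len - 1L), envir = seed_map,
                  ifnotfound = NULL)
      if (is.null(occ)) next
      starts <- occ[, "pos"] - o               # 0-based placement start
      ok <- starts >= 0L & starts + L <= tx_len[occ[, "tx"]]
      if (any(ok)) {
        cand[[length(cand) + 1L]] <-
          cbind(tx = occ[ok, "tx"], start = starts[ok],
                strand = if (strand == "+") 0L else 1L)
      }
    }
  }
  if (length(cand) == 0L) return(NULL)
  cand <- unique(do.call(rbind, cand))
  scores <- integer(nrow(cand))
  for (j in seq_len(nrow(cand))) {
    s <- if (cand[j, "strand"] == 0L) fwd else rev
    window <- substr(transcripts$sequence[cand[j, "tx"]],
                     cand[j, "start"] + 1L, cand[j, "start"] + L)
    scores[j] <- count_matches(s, window)
  }
  ord <- order(-scores, cand[, "strand"],
               transcripts$transcript_id[cand[, "tx"]], cand[, "start"])
  best <- ord[1L]
  if (scores[best] < ceiling(min_identity * L)) return(NULL)
  list(transcript_id = transcripts$transcript_id[cand[best, "tx"]],
       strand = if (cand[best, "strand"] == 0L) "+" else "-",
       start = as.integer(cand[best, "start"]),
       end = as.integer(cand[best, "start"] + L),
       matches = as.integer(scores[best]))
}

#' Dump alignment hits as a minimal SAM file
#'
#' Debug output only (not consumed internally): QNAME, FLAG (0x10 for `-`
#' strand), RNAME, 1-based POS, MAPQ 255, CIGAR `<len>M`.
#'
#' @param hits An `alignment_hits` data frame.
#' @param reads The `fastq_records` the hits refer to.
#' @param transcripts The transcript table aligned against (for `@SQ`
#'   headers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam_hits <- function(hits, reads, transcripts, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", transcripts$transcript_id,
                      nchar(transcripts$sequence)))
  qname <- sub(" .*$", "", reads$identifier[hits$read_index])
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                  qname,
                  ifelse(hits$strand == "-", 16L, 0L),
                  hits$transcript_id,
                  hits$start + 1L,
                  hits$end - hits$start,
                  reads$sequence[hits$read_index],
                  reads$quality[hits$read_index])
  writeLines(c(header, body), path)
  invisible(path)
}
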