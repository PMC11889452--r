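# Independent brute-force oracles. These deliberately share no code with the
# implementations they check: direct substring scans and exhaustive
# enumeration only.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    paste(rev(unname(comp[ch])), collapse = "")
  }, "", USE.NAMES = FALSE)
}

canonical_kmer_for_test <- function(km) {
  rc <- oracle_revcomp(km)
  if (km <= rc) km else rc
}

# All (pattern index, 0-based exclusive end) occurrences by sliding-window
# comparison, one pattern at a time.
oracle_multi_match <- function(patterns, text) {
  n <- nchar(text)
  pat <- integer(0)
  ends <- integer(0)
  for (pi in seq_along(patterns)) {
    m <- nchar(patterns[pi])
    if (m > n) next
    starts <- seq_len(n - m + 1L)
    hit <- substring(text, starts, starts + m - 1L) == patterns[pi]
    if (any(hit)) {
      pat <- c(pat, rep.int(pi, sum(hit)))
      ends <- c(ends, starts[hit] + m - 1L)
    }
  }
  ord <- order(ends, pat)
  data.frame(pattern = pat[ord], end = ends[ord])
}

# Per-organism abundance by direct substring search: a read k-mer matches a
# transcript iff the transcript contains the k-mer or its reverse
# complement; the read's compatibility set is the intersection over its
# matching k-mers; weight 1 splits equally over the organisms in the set.
oracle_quantify <- function(reads, reference, k) {
  tx <- reference$transcripts
  counts <- setNames(numeric(nrow(reference$organisms)),
                     reference$organisms$organism)
  mapped <- 0L
  for (s in reads$sequence) {
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    kmers <- kmers[!grepl("[^ACGT]", kmers)]
    compat <- NULL
    any_match <- FALSE
    for (km in kmers) {
      in_tx <- which(vapply(tx$sequence, function(t) {
        grepl(km, t, fixed = TRUE) || grepl(oracle_revcomp(km), t, fixed = TRUE)
      }, logical(1), USE.NAMES = FALSE))
      if (length(in_tx) == 0L) next
      compat <- if (any_match) intersect(compat, in_tx) else in_tx
      any_match <- TRUE
    }
    if (!any_match || length(compat) == 0L) next
    orgs <- unique(tx$organism[compat])
    counts[orgs] <- counts[orgs] + 1 / length(orgs)
    mapped <- mapped + 1L
  }
  out <- data.frame(organism = reference$organisms$organism,
                    taxon_id = reference$organisms$taxon_id,
                    read_count = as.numeric(counts),
                    stringsAsFactors = FALSE)
  out$rpm <- out$read_count * 1e6 / nrow(reads)
  out <- out[order(-out$rpm, out$taxon_id), ]
  rownames(out) <- NULL
  list(table = out, mapped = mapped)
}

# Best ungapped placement of a read by exhaustive enumeration over every
# (strand, transcript, offset), with the same scoring threshold and
# tie-break order as the aligner's contract. Returns NULL for no hit.
oracle_align <- function(read, transcripts, min_identity = 0.9) {
  L <- nchar(read)
  need <- ceiling(min_identity * L)
  read_int <- list(`+` = utf8ToInt(read), `-` = utf8ToInt(oracle_revcomp(read)))
  best <- NULL
  for (ti in seq_len(nrow(transcripts))) {
    t_int <- utf8ToInt(transcripts$sequence[ti])
    T_len <- length(t_int)
    if (T_len < L) next
    for (strand in c("+", "-")) {
      r <- read_int[[strand]]
      for (start0 in 0:(T_len - L)) {
        matches <- sum(r == t_int[(start0 + 1L):(start0 + L)])
        cand <- list(transcript_id = transcripts$transcript_id[ti],
                     strand = strand, start = start0, end = start0 + L,
                     matches = matches)
        if (is.null(best) || oracle_align_better(cand, best)) best <- cand
      }
    }
  }
  if (!is.null(best) && best$matches >= need) best else NULL
}

oracle_align_better <- function(a, b) {
  if (a$matches != b$matches) return(a$matches > b$matches)
  if (a$strand != b$strand) return(a$strand == "+")
  if (a$transcript_id != b$transcript_id) return(a$transcript_id < b$transcript_id)
  a$start < b$start
}

# Naive length statistics by sort-and-count.
oracle_length_stats <- function(lengths) {
  s <- sort(lengths)
  n <- length(s)
  freq <- table(s)
  list(min = s[1], max = s[n], mean = sum(s) / n,
       median = s[ceiling(n / 2)],
       mode = as.integer(names(freq)[freq == max(freq)])[1])
}
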