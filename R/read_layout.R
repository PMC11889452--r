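#' Load a 3' adapter fragment library
#'
#' Reads a plain-text adapter library: one sequence per line, `#` comments
#' and blank lines ignored. The packaged default (used when `path` is
#' `NULL`) holds eighteen 12-mers curated from the adapter and primer
#' sequences of common Illumina RNA-seq kits. Every entry must be exactly
#' 12 nt over `ACGT` and unique.
#'
#' @param path Path to an adapter library file, or `NULL` for the packaged
#'   default.
#' @return A character vector of class `adapter_library`.
#' @examples
#' lib <- load_adapter_library()
#' length(lib)   # 18
#' @export
load_adapter_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "adapter_fragments.txt",
                        package = "fastqmeta", mustWork = TRUE)
  }
  if (!file.exists(path)) abort_input("adapter library does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- toupper(trimws(lines))
  adapters <- lines[nzchar(lines)]
  if (length(adapters) == 0L) {
    abort_format("adapter library %s contains no sequences", path)
  }
  bad <- which(nchar(adapters) != 12L | grepl("[^ACGT]", adapters))
  if (length(bad)) {
    abort_format("adapter library entry '%s' is not a 12-mer over ACGT",
                 adapters[bad[1L]])
  }
  if (anyDuplicated(adapters)) {
    abort_format("adapter library contains duplicate entry '%s'",
                 adapters[duplicated(adapters)][1L])
  }
  structure(adapters, class = "adapter_library")
}

#' Build an Aho-Corasick automaton over an adapter library
#'
#' Constructs the classic multi-pattern matching automaton — a trie over
#' the patterns with breadth-first failure links, here collapsed into a
#' deterministic goto table over the `ACGT` alphabet — so one left-to-right
#' pass over a read finds every occurrence of every adapter, including
#' overlapping and co-terminal ones. Characters outside `ACGT` (e.g. `N`)
#' have no transitions and reset the automaton to its root.
#'
#' @param adapters An `adapter_library` (any non-empty set of `ACGT`
#'   patterns works; the 12-mer constraint is the library's, not the
#'   automaton's).
#' @return An object of class `adapter_automaton`.
#' @export
build_adapter_automaton <- function(adapters) {
  if (length(adapters) == 0L) abort_usage("adapter library is empty")
  if (any(grepl("[^ACGT]", adapters))) {
    abort_usage("automaton patterns must be over ACGT")
  }
  pat_codes <- lapply(adapters, function(p) char_codes(p))
  n_max <- sum(nchar(adapters)) + 1L
  goto <- matrix(0L, nrow = n_max, ncol = 4L)
  out <- vector("list", n_max)
  n_nodes <- 1L                                  # node 1 = root
  for (pi in seq_along(pat_codes)) {
    node <- 1L
    for (c in pat_codes[[pi]]) {
      nxt <- goto[node, c]
      if (nxt == 0L) {
        n_nodes <- n_nodes + 1L
        goto[node, c] <- n_nodes
        nxt <- n_nodes
      }
      node <- nxt
    }
    out[[node]] <- c(out[[node]], pi)
  }
  goto <- goto[seq_len(n_nodes), , drop = FALSE]
  out <- out[seq_len(n_nodes)]
  # Breadth-first failure links, folded into the goto table (DFA form).
  fail <- integer(n_nodes)
  fail[1L] <- 1L
  queue <- integer(0)
  for (c in 1:4) {
    v <- goto[1L, c]
    if (v == 0L) goto[1L, c] <- 1L
    else {
      fail[v] <- 1L
      queue <- c(queue, v)
    }
  }
  qi <- 1L
  while (qi <= length(queue)) {
    u <- queue[qi]; qi <- qi + 1L
    for (c in 1:4) {
      v <- goto[u, c]
      if (v == 0L) {
        goto[u, c] <- goto[fail[u], c]
      } else {
        fail[v] <- goto[fail[u], c]
        inherited <- out[[fail[v]]]
        # [[<- with NULL would delete the element; append only when non-empty
        if (!is.null(inherited)) out[[v]] <- c(out[[v]], inherited)
        queue <- c(queue, v)
      }
    }
  }
  structure(list(goto = goto, out = out, patterns = as.character(adapters)),
            class = "adapter_automaton")
}

# ACGT -> 1:4, anything else NA. Indexed by raw character code.
char_codes <- function(text) {
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt(text)]
}

#' Search a text with an adapter automaton
#'
#' One pass over `text`; reports every (pattern, end position) occurrence.
#'
#' @param automaton An `adapter_automaton`.
#' @param text A single string.
#' @return A data frame with `pattern` (index into the automaton's pattern
#'   set), `adapter` (the pattern string) and `end` (0-based exclusive end
#'   offset of the occurrence in `text`).
#' @export
ac_search <- function(automaton, text) {
  codes <- if (nchar(text)) char_codes(text) else integer(0)
  goto <- automaton$goto
  out <- automaton$out
  state <- 1L
  pat <- integer(0)
  ends <- integer(0)
  for (i in seq_along(codes)) {
    c <- codes[i]
    if (is.na(c)) {
      state <- 1L
      next
    }
    state <- goto[state, c]
    hits <- out[[state]]
    if (!is.null(hits)) {
      pat <- c(pat, hits)
      ends <- c(ends, rep.int(i, length(hits)))
    }
  }
  data.frame(pattern = pat, adapter = automaton$patterns[pat], end = ends,
             stringsAsFactors = FALSE)
}

#' Per-adapter read prevalence
#'
#' For every adapter in the automaton, the fraction of reads containing at
#' least one occurrence (a read counts once per adapter regardless of how
#' often the adapter occurs in it, and may count toward several adapters).
#'
#' @param reads A `fastq_records` data frame.
#' @param automaton An `adapter_automaton`.
#' @return A named numeric vector: adapter -> fraction of reads in `[0,1]`.
#' @export
count_adapters <- function(reads, automaton) {
  n <- nrow(reads)
  if (is.null(n) || n == 0L) abort_usage("cannot count adapters in an empty read stream")
  counts <- integer(length(automaton$patterns))
  for (s in reads$sequence) {
    found <- unique(ac_search(automaton, s)$pattern)
    counts[found] <- counts[found] + 1L
  }
  setNames(counts / n, automaton$patterns)
}

#' Call the 3' adapter from per-adapter prevalences
#'
#' The most prevalent adapter is assigned only if it clears the minimal
#' frequency cutoff (`adapter_min_fraction`) and the best/second-best ratio
#' cutoff (`adapter_min_ratio`); a second-best prevalence of zero counts as
#' infinite ratio. Ties at the top give ratio 1 and are reported ambiguous
#' (with the lexicographically smallest adapter as the nominal best).
#'
#' @param adapter_fractions Named fractions from [count_adapters()].
#' @param config An [inference_config()].
#' @return A list of class `adapter_call`: `state` (`assigned`,
#'   `unassigned_low_frequency`, `unassigned_ambiguous`), `adapt_3` (the
#'   adapter, `NA` unless assigned), `best_fraction`, `ratio_to_second`,
#'   `adapter_fractions`.
#' @export
call_adapter <- function(adapter_fractions, config = inference_config()) {
  stopifnot_usage(length(adapter_fractions) >= 1L,
                  "adapter fraction table is empty")
  nm <- names(adapter_fractions)
  ord <- order(-adapter_fractions, nm)
  best_name <- nm[ord[1L]]
  best <- adapter_fractions[[ord[1L]]]
  second <- if (length(ord) >= 2L) adapter_fractions[[ord[2L]]] else 0
  ratio <- if (second == 0) Inf else best / second
  state <- if (best < config$adapter_min_fraction) {
    "unassigned_low_frequency"
  } else if (ratio < config$adapter_min_ratio) {
    "unassigned_ambiguous"
  } else {
    "assigned"
  }
  structure(
    list(state = state,
         adapt_3 = if (state == "assigned") best_name else NA_character_,
         best_fraction = best,
         ratio_to_second = ratio,
         adapter_fractions = adapter_fractions),
    class = "adapter_call")
}

#' Fraction of poly(A)-containing reads
#'
#' A read is poly(A)-positive when its 3' terminus is a run of at least
#' `polya_min_length` adenosines (internal A-runs do not count: a tail that
#' was read through into the adapter is an adapter signal, not a terminal
#' poly(A) signal). `polya_max_mismatches` non-A bases are tolerated inside
#' the terminal window (default 0, i.e. a strict run).
#'
#' @param reads A `fastq_records` data frame.
#' @param config An [inference_config()].
#' @return The fraction of poly(A)-positive reads, in `[0,1]`.
#' @export
polya_fraction <- function(reads, config = inference_config()) {
  n <- nrow(reads)
  if (is.null(n) || n == 0L) abort_usage("cannot assess poly(A) in an empty read stream")
  len <- config$polya_min_length
  sl <- nchar(reads$sequence)
  long_enough <- sl >= len
  tails <- substring(reads$sequence[long_enough], sl[long_enough] - len + 1L,
                     sl[long_enough])
  non_a <- nchar(gsub("A", "", tails, fixed = TRUE))
  sum(non_a <= config$polya_max_mismatches) / n
}
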