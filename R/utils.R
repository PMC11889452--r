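# Small shared helpers.

# Vectorized reverse complement on plain character vectors.
# Biostrings carries the complement table; this wrapper keeps call sites terse.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Canonical k-mer: lexicographic minimum of a k-mer and its reverse complement.
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# All k-length windows of one sequence, in order. Returns character(0) when
# the sequence is shorter than k.
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards
# so fixture generation never perturbs user code.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Hamming-style match count between two equal-length strings.
count_matches <- function(a, b) {
  sum(utf8ToInt(a) == utf8ToInt(b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
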