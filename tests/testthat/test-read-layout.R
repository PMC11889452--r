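test_that("the default adapter library is 18 unique 12-mers", {
  lib <- load_adapter_library()
  expect_length(lib, 18L)
  expect_true(all(nchar(lib) == 12L))
  expect_false(any(duplicated(lib)))
  expect_false(any(grepl("[^ACGT]", lib)))
})

test_that("custom adapter files are validated", {
  good <- tempfile()
  writeLines(c("# comment", "AGATCGGAAGAG", "", "ctgtctcttata  # nextera"), good)
  lib <- load_adapter_library(good)
  expect_identical(as.character(lib), c("AGATCGGAAGAG", "CTGTCTCTTATA"))
  bad <- tempfile()
  writeLines("ACGT", bad)
  expect_error(load_adapter_library(bad), class = "fastqmeta_format_error")
  dup <- tempfile()
  writeLines(c("AGATCGGAAGAG", "AGATCGGAAGAG"), dup)
  expect_error(load_adapter_library(dup), class = "fastqmeta_format_error")
})

test_that("automaton finds containment, overlapping and co-terminal matches", {
  a <- build_adapter_automaton("AAAACCCCGGGG")
  m <- ac_search(a, "TTAAAACCCCGGGGTT")
  expect_equal(nrow(m), 1L)
  expect_equal(m$end, 14L)

  a2 <- build_adapter_automaton("AAAAAAAAAAAA")
  m2 <- ac_search(a2, strrep("A", 14))
  expect_equal(m2$end, c(12L, 13L, 14L))       # overlapping occurrences

  expect_equal(nrow(ac_search(a, "")), 0L)
  expect_error(build_adapter_automaton(character(0)),
               class = "fastqmeta_usage_error")
})

test_that("automaton equals the naive multi-pattern oracle on random instances", {
  set.seed(29)
  lib18 <- as.character(load_adapter_library())
  for (i in 1:200) {
    n_pat <- sample(1:18, 1)
    patterns <- if (runif(1) < 0.5) {
      sample(lib18, n_pat)
    } else {
      unique(vapply(seq_len(n_pat), function(j) rand_dna(12), ""))
    }
    # texts biased to contain patterns, sometimes with N
    text <- paste0(rand_dna(sample(0:80, 1)),
                   if (runif(1) < 0.7) sample(patterns, 1) else "",
                   if (runif(1) < 0.2) "N" else "",
                   rand_dna(sample(0:80, 1)))
    a <- build_adapter_automaton(patterns)
    got <- ac_search(a, text)
    got <- got[order(got$end, got$pattern), c("pattern", "end")]
    rownames(got) <- NULL
    want <- oracle_multi_match(patterns, text)
    expect_equal(got, want)
  }
})

test_that("adapter prevalence counts reads, not occurrences", {
  lib <- load_adapter_library()
  x <- "AGATCGGAAGAG"
  a <- build_adapter_automaton(lib)
  set.seed(31)
  seqs <- c(
    vapply(1:6, function(i) paste0(rand_dna(30), x, rand_dna(5)), ""),
    paste0(x, rand_dna(10), x),                # two occurrences, counts once
    vapply(1:3, function(i) rand_dna(47), ""))
  frac <- count_adapters(make_records(seqs), a)
  expect_equal(unname(frac[x]), 0.7)
  expect_true(all(frac >= 0 & frac <= 1))
  # invariant under read reordering
  frac2 <- count_adapters(make_records(rev(seqs)), a)
  expect_equal(frac, frac2)
})

test_that("adapter calls apply the frequency and ratio cutoffs", {
  cfg <- inference_config()
  base <- setNames(numeric(3), c("AAAACCCCGGGG", "CCCCGGGGTTTT", "GGGGTTTTAAAA"))
  f <- base; f[1] <- 0.60; f[2] <- 0.05
  call <- call_adapter(f, cfg)
  expect_identical(call$state, "assigned")
  expect_identical(call$adapt_3, "AAAACCCCGGGG")

  f <- base; f[1] <- 0.03; f[2] <- 0.02       # ratio 1.5 < 2
  expect_identical(call_adapter(f, cfg)$state, "unassigned_ambiguous")

  f <- base + 0.001                            # everything below the floor
  expect_identical(call_adapter(f, cfg)$state, "unassigned_low_frequency")

  f <- base; f[1] <- f[2] <- 0.4               # exact tie -> ambiguous
  tie <- call_adapter(f, cfg)
  expect_identical(tie$state, "unassigned_ambiguous")
  expect_equal(tie$ratio_to_second, 1)

  f <- base; f[2] <- 0.3                       # sole signal -> infinite ratio
  solo <- call_adapter(f, cfg)
  expect_identical(solo$state, "assigned")
  expect_identical(solo$adapt_3, "CCCCGGGGTTTT")
})

test_that("poly(A) detection requires a terminal run", {
  cfg <- inference_config()
  reads <- make_records(c(
    paste0("ACGT", strrep("A", 12)),                 # terminal run of 12
    paste0(strrep("A", 12), "CGT"),                  # internal only
    paste0(strrep("CG", 10), strrep("A", 10)),       # exactly the minimum
    paste0(strrep("CG", 10), strrep("A", 9))))       # one short
  expect_equal(polya_fraction(reads, cfg), 0.5)

  # planted fraction is recovered exactly
  set.seed(34)
  seqs <- c(vapply(1:50, function(i) paste0(rand_dna(40), strrep("A", 12)), ""),
            vapply(1:150, function(i) paste0(rand_dna(49), "C", "GT"), ""))
  expect_equal(polya_fraction(make_records(seqs), cfg), 0.25)

  # mismatch allowance admits a one-error tail
  lax <- inference_config(polya_max_mismatches = 1L)
  one_err <- make_records(paste0("ACGT", strrep("A", 6), "G", strrep("A", 3)))
  expect_equal(polya_fraction(one_err, cfg), 0)
  expect_equal(polya_fraction(one_err, lax), 1)
})

test_that("fixture libraries with one planted adapter are always assigned", {
  ref <- generate_rp_reference(1, 2, 200, seed = 111)
  lib <- load_adapter_library()
  a <- build_adapter_automaton(lib)
  cfg <- inference_config()
  for (adapter in as.character(lib)[c(1, 7, 13)]) {
    sim <- simulate_library(ref, library_spec(
      "orga", n_reads = 200, adapter = adapter,
      adapter_inclusion_rate = 0.3, seed = 35))
    frac <- count_adapters(read_fastq(sim$files), a)
    call <- call_adapter(frac, cfg)
    expect_identical(call$state, "assigned")
    expect_identical(call$adapt_3, adapter)
  }
})
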