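test_that("index windows and sharing behave as specified", {
  # single 21 nt transcript at k = 21: exactly one key
  ref1 <- make_reference("t1", "orga", 9001, "ACGTACGTACGTACGTACGTA")
  idx1 <- build_kmer_index(ref1, k = 21)
  expect_equal(idx1$n_kmers, 1L)

  # transcript of length 30 -> 10 windows, <= 10 distinct keys
  set.seed(3)
  ref2 <- make_reference("t1", "orga", 9001, rand_dna(30))
  idx2 <- build_kmer_index(ref2, k = 21)
  expect_lte(idx2$n_kmers, 10L)
  expect_gte(idx2$n_kmers, 1L)

  # a 21-mer shared between two transcripts maps to both
  set.seed(4)
  shared <- rand_dna(21)
  ref3 <- make_reference(c("t1", "t2"), c("orga", "orgb"), c(9001, 9002),
                         c(paste0(rand_dna(10), shared),
                           paste0(shared, rand_dna(10))))
  idx3 <- build_kmer_index(ref3, k = 21)
  key <- canonical_kmer_for_test(shared)
  expect_setequal(get(key, envir = idx3$map), c(1L, 2L))
})

test_that("index construction rejects unusable inputs", {
  ref <- make_reference("t1", "orga", 9001, "ACGTACGT")
  expect_error(build_kmer_index(ref, k = 21), class = "fastqmeta_usage_error")
  expect_error(build_kmer_index(ref, k = 12), class = "fastqmeta_usage_error")
  expect_error(build_kmer_index(ref, k = 9), class = "fastqmeta_usage_error")
})

test_that("perfect separation, equal splitting, and unmapped reads", {
  ref <- generate_rp_reference(2, 3, 120, seed = 21)
  idx <- build_kmer_index(ref, k = 21)
  tx_a <- ref$transcripts$sequence[ref$transcripts$organism == "orga"]
  set.seed(5)
  reads_a <- make_records(vapply(1:100, function(i) {
    t <- sample(tx_a, 1)
    s <- sample.int(nchar(t) - 50 + 1, 1)
    substr(t, s, s + 49)
  }, ""))
  ab <- quantify_reads(reads_a, idx)
  expect_equal(ab$read_count[ab$organism == "orga"], 100)
  expect_equal(ab$read_count[ab$organism == "orgb"], 0)
  expect_equal(ab$rpm[1], 1e6)

  # a read matching both organisms splits its weight equally
  shared <- with(list(), {set.seed(6); rand_dna(40)})
  ref_sh <- make_reference(c("t1", "t2"), c("orga", "orgb"), c(9001, 9002),
                           c(paste0(shared, rand_dna(60)),
                             paste0(rand_dna(60), shared)))
  idx_sh <- build_kmer_index(ref_sh, k = 21)
  ab_sh <- quantify_reads(make_records(shared), idx_sh)
  expect_equal(sort(ab_sh$read_count), c(0.5, 0.5))

  # a read sharing no k-mer is unmapped
  set.seed(7)
  junk <- make_records("TTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTT")
  ab_junk <- quantify_reads(junk, idx_sh)
  expect_true(all(ab_junk$read_count == 0))
  expect_true(all(ab_junk$rpm == 0))
  expect_equal(attr(ab_junk, "mapped_reads"), 0L)
})

test_that("read mass is conserved and counts are monotone in added reads", {
  ref <- generate_rp_reference(3, 2, 150, seed = 31)
  idx <- build_kmer_index(ref, k = 21)
  sim1 <- simulate_library(ref, library_spec("orga", n_reads = 60,
                                             read_length = 50, seed = 8))
  sim2 <- simulate_library(ref, library_spec("orgb", n_reads = 40,
                                             read_length = 50, seed = 9))
  r1 <- read_fastq(sim1$files)
  r2 <- read_fastq(sim2$files)
  ab1 <- quantify_reads(r1, idx)
  expect_equal(sum(ab1$read_count), attr(ab1, "mapped_reads"))
  both <- rbind(r1, r2)
  ab_both <- quantify_reads(both, idx)
  expect_equal(sum(ab_both$read_count), attr(ab_both, "mapped_reads"))
  expect_gte(ab_both$read_count[ab_both$organism == "orga"],
             ab1$read_count[ab1$organism == "orga"] - 1e-9)
})

test_that("quantifier matches the brute-force oracle on random instances", {
  set.seed(97)
  for (case in 1:40) {
    n_org <- sample(1:3, 1)
    n_tx <- sample(1:3, 1)
    tx_len <- sample(40:120, n_org * n_tx, replace = TRUE)
    ref <- make_reference(sprintf("t%d", seq_along(tx_len)),
                          rep(paste0("org", letters[1:n_org]), each = n_tx),
                          rep(9000 + 1:n_org, each = n_tx),
                          vapply(tx_len, rand_dna, ""))
    idx <- build_kmer_index(ref, k = 21)
    reads <- make_records(vapply(1:15, function(i) {
      if (runif(1) < 0.5) {
        rand_dna(sample(25:60, 1))             # mostly unmappable
      } else {
        t <- sample(ref$transcripts$sequence, 1)
        L <- sample(25:min(60, nchar(t)), 1)
        s <- sample.int(nchar(t) - L + 1, 1)
        frag <- substr(t, s, s + L - 1)
        if (runif(1) < 0.5) oracle_revcomp(frag) else frag
      }
    }, ""))
    got <- quantify_reads(reads, idx)
    want <- oracle_quantify(reads, ref, k = 21)
    expect_equal(as.data.frame(got), want$table, ignore_attr = TRUE)
    expect_equal(attr(got, "mapped_reads"), want$mapped)
  }
})

test_that("the simulated organism always ranks first", {
  ref <- generate_rp_reference(3, 3, 200, seed = 51)
  idx <- build_kmer_index(ref, k = 21)
  for (org in ref$organisms$organism) {
    for (s in 1:4) {
      sim <- simulate_library(ref, library_spec(org, n_reads = 50,
                                                read_length = 60,
                                                orientation = "U",
                                                seed = 100 * s))
      ab <- quantify_reads(read_fastq(sim$files), idx)
      expect_identical(ab$organism[1], org)
    }
  }
})
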