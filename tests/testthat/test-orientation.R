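test_that("pure and mixed strand fractions call SF, SR, U", {
  cfg <- inference_config()
  h_plus <- make_hits(1:100, "t1", "+", 0L, 50L)
  h_minus <- make_hits(1:100, "t1", "-", 0L, 50L)
  h_half <- make_hits(1:100, "t1", rep(c("+", "-"), 50), 0L, 50L)
  expect_identical(infer_orientation_single(h_plus, cfg)$state, "SF")
  expect_equal(infer_orientation_single(h_plus, cfg)$forward_fraction, 1)
  expect_identical(infer_orientation_single(h_minus, cfg)$state, "SR")
  expect_identical(infer_orientation_single(h_half, cfg)$state, "U")
  expect_equal(infer_orientation_single(h_half, cfg)$forward_fraction, 0.5)
})

test_that("too few mapped reads leave orientation undetermined", {
  cfg <- inference_config(min_mapped_reads = 20L)
  h <- make_hits(1:15, "t1", "+", 0L, 50L)
  out <- infer_orientation_single(h, cfg)
  expect_identical(out$state, "undetermined")
  expect_equal(out$mapped_reads, 15L)
  # forward fraction still reported when any read mapped
  expect_equal(out$forward_fraction, 1)
  empty <- h[0, ]
  expect_true(is.na(infer_orientation_single(empty, cfg)$forward_fraction))
})

test_that("paired orientation follows the first mate's strand over concordant pairs", {
  cfg <- inference_config()
  m1_plus <- make_hits(1:100, "t1", "+", 10L, 60L)
  m2_minus <- make_hits(1:100, "t1", "-", 90L, 140L)
  isf <- infer_orientation_paired(m1_plus, m2_minus, cfg)
  expect_identical(isf$relationship, "ISF")
  expect_identical(isf$file_1$state, "SF")
  expect_identical(isf$file_2$state, "SR")

  isr <- infer_orientation_paired(m2_minus, m1_plus, cfg)
  expect_identical(isr$relationship, "ISR")

  # 15 concordant pairs with a floor of 20: undetermined
  few <- infer_orientation_paired(m1_plus[1:15, ], m2_minus[1:15, ], cfg)
  expect_identical(few$relationship, "undetermined")

  # 50/50 first-mate strands: IU (the '+' mate is always upstream, inward)
  s1 <- rep(c("+", "-"), 50)
  st1 <- ifelse(s1 == "+", 10L, 90L)
  s2 <- rep(c("-", "+"), 50)
  st2 <- ifelse(s2 == "+", 10L, 90L)
  mix1 <- make_hits(1:100, "t1", s1, st1, st1 + 50L)
  mix2 <- make_hits(1:100, "t1", s2, st2, st2 + 50L)
  expect_identical(infer_orientation_paired(mix1, mix2, cfg)$relationship, "IU")
})

test_that("reverse-complementing a library flips SF<->SR and ISF<->ISR, fixes U", {
  ref <- generate_rp_reference(1, 3, 300, seed = 91)
  cfg <- inference_config()
  flip <- function(files) {
    lapply(files, function(f) {
      r <- read_fastq(f)
      r$sequence <- oracle_revcomp(r$sequence)
      r
    })
  }
  for (spec_orient in c("SF", "U")) {
    sim <- simulate_library(ref, library_spec("orga", n_reads = 120,
                                              orientation = spec_orient,
                                              seed = 17))
    reads <- read_fastq(sim$files)
    h <- align_reads(reads, ref$transcripts, cfg)
    h_rc <- align_reads(flip(sim$files)[[1]], ref$transcripts, cfg)
    got <- infer_orientation_single(h, cfg)$state
    got_rc <- infer_orientation_single(h_rc, cfg)$state
    if (spec_orient == "SF") {
      expect_identical(got, "SF")
      expect_identical(got_rc, "SR")
    } else {
      expect_identical(got, "U")
      expect_identical(got_rc, "U")
    }
  }
  sim <- simulate_library(ref, library_spec("orga", n_reads = 120,
                                            layout = "paired",
                                            orientation = "ISF", seed = 19))
  reads <- lapply(sim$files, read_fastq)
  h1 <- align_reads(reads[[1]], ref$transcripts, cfg)
  h2 <- align_reads(reads[[2]], ref$transcripts, cfg)
  expect_identical(infer_orientation_paired(h1, h2, cfg)$relationship, "ISF")
  rc <- flip(sim$files)
  h1r <- align_reads(rc[[1]], ref$transcripts, cfg)
  h2r <- align_reads(rc[[2]], ref$transcripts, cfg)
  expect_identical(infer_orientation_paired(h1r, h2r, cfg)$relationship, "ISR")
})

test_that("simulated SF/SR/U libraries are recovered across seeded trials", {
  ref <- generate_rp_reference(1, 3, 300, seed = 101)
  cfg <- inference_config()
  truth <- c("SF", "SR", "U")
  n_trials <- 100
  correct <- 0
  for (i in seq_len(n_trials)) {
    want <- truth[(i %% 3) + 1]
    sim <- simulate_library(ref, library_spec("orga", n_reads = 500,
                                              orientation = want,
                                              error_rate = 0.005,
                                              seed = 1000 + i))
    h <- align_reads(read_fastq(sim$files), ref$transcripts, cfg)
    if (identical(infer_orientation_single(h, cfg)$state, want)) {
      correct <- correct + 1
    }
  }
  expect_gte(correct / n_trials, 0.99)
})
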