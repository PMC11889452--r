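# Synthetic fixtures: toy RP references and ground-truthed read libraries.
# Everything is generated in code, deterministically for a fixed seed, so all
# inference stages are testable offline against known truth.

#' Generate a toy organism-annotated RP reference
#'
#' Draws `transcripts_per_organism` random transcripts (i.i.d. uniform over
#' `ACGT`) for each of `n_organisms` synthetic organisms (short names
#' `orga`, `orgb`, ..., taxon ids 9001, 9002, ...). Uniqueness across
#' organisms is enforced, not assumed: any organism sharing a canonical
#' k-mer with an earlier one is redrawn, and the final reference is checked
#' to share none. Deterministic for a fixed seed.
#'
#' @param n_organisms Number of organisms (1-26).
#' @param transcripts_per_organism Transcripts drawn per organism.
#' @param transcript_length Length of each transcript (nt); must be at
#'   least `2 * k`.
#' @param seed Integer seed.
#' @param k k-mer size used for the cross-organism uniqueness check
#'   (default 21, matching the quantifier default).
#' @return An `rp_reference`.
#' @examples
#' ref <- generate_rp_reference(3, 4, 300, seed = 7)
#' ref$organisms
#' @export
generate_rp_reference <- function(n_organisms, transcripts_per_organism,
                                  transcript_length, seed, k = 21L) {
  if (n_organisms < 1L || n_organisms > 26L) {
    abort_usage("n_organisms must be between 1 and 26")
  }
  if (transcripts_per_organism < 1L) {
    abort_usage("transcripts_per_organism must be >= 1")
  }
  if (transcript_length < 2L * k) {
    abort_usage("transcript_length must be >= 2 * k = %d", 2L * k)
  }
  max_retries <- 25L
  seen <- character(0)
  tx_rows <- vector("list", n_organisms)
  for (i in seq_len(n_organisms)) {
    org <- paste0("org", letters[i])
    ok <- FALSE
    for (attempt in 0:max_retries) {
      seqs <- with_seed(seed + 7919L * i + attempt, {
        vapply(seq_len(transcripts_per_organism), function(j) {
          paste(sample(c("A", "C", "G", "T"), transcript_length,
                       replace = TRUE), collapse = "")
        }, "")
      })
      kset <- unique(canonical_kmer(unlist(lapply(seqs, kmers_of, k = k))))
      if (!any(kset %in% seen)) {
        seen <- c(seen, kset)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort_usage(
        "could not draw organism %d without shared %d-mers after %d retries; increase transcript_length or reduce organisms",
        i, k, max_retries)
    }
    tx_rows[[i]] <- data.frame(
      transcript_id = sprintf("%s_t%d", org, seq_len(transcripts_per_organism)),
      organism = org,
      taxon_id = 9000L + i,
      sequence = seqs,
      stringsAsFactors = FALSE)
  }
  tx <- do.call(rbind, tx_rows)
  rownames(tx) <- NULL
  orgs <- unique(tx[, c("organism", "taxon_id")])
  rownames(orgs) <- NULL
  structure(list(transcripts = tx, organisms = orgs), class = "rp_reference")
}

#' Specify a synthetic read library
#'
#' Collects the ground-truth parameters of one simulated library. Defaults
#' describe a clean 500-read, 75-nt library, the grain used throughout the
#' package's own evaluation.
#'
#' @param organism Organism short name; must exist in the reference passed
#'   to [simulate_library()].
#' @param n_reads Number of reads (read pairs for paired layout).
#' @param read_length Read length (nt).
#' @param layout `"single"` or `"paired"`.
#' @param orientation Truth orientation: `SF`/`SR`/`U` for single,
#'   `ISF`/`ISR`/`IU` for paired.
#' @param fragment_length Fragment length (paired only); must be at least
#'   `read_length`.
#' @param adapter 3' adapter 12-mer to plant, or `NA` for none.
#' @param adapter_inclusion_rate Per-read probability of carrying the
#'   adapter at its 3' end.
#' @param polya_rate Per-read probability of carrying a terminal poly(A)
#'   run (12 nt).
#' @param error_rate Per-base substitution probability.
#' @param identifier_dialect `"casava_1_8"`, `"pre_casava_1_8"` or
#'   `"unknown"`.
#' @param seed Integer seed; the simulation is byte-deterministic in it.
#' @return A list of class `library_spec`.
#' @export
library_spec <- function(organism,
                         n_reads = 500L,
                         read_length = 75L,
                         layout = c("single", "paired"),
                         orientation = NULL,
                         fragment_length = 150L,
                         adapter = NA_character_,
                         adapter_inclusion_rate = 0,
                         polya_rate = 0,
                         error_rate = 0,
                         identifier_dialect = c("casava_1_8",
                                                "pre_casava_1_8", "unknown"),
                         seed = 1L) {
  layout <- match.arg(layout)
  identifier_dialect <- match.arg(identifier_dialect)
  if (is.null(orientation)) {
    orientation <- if (layout == "single") "SF" else "ISF"
  }
  ok_orient <- if (layout == "single") c("SF", "SR", "U") else c("ISF", "ISR", "IU")
  if (!orientation %in% ok_orient) {
    abort_usage("orientation '%s' is invalid for %s layout", orientation, layout)
  }
  rates <- c(adapter_inclusion_rate, polya_rate, error_rate)
  if (any(rates < 0 | rates > 1)) abort_usage("all rates must lie in [0, 1]")
  if (layout == "paired" && fragment_length < read_length) {
    abort_usage("paired layout needs fragment_length >= read_length")
  }
  if (!is.na(adapter) && grepl("[^ACGT]", adapter)) {
    abort_usage("adapter to plant must be over ACGT")
  }
  structure(list(organism = organism, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length), layout = layout,
                 orientation = orientation,
                 fragment_length = as.integer(fragment_length),
                 adapter = adapter,
                 adapter_inclusion_rate = adapter_inclusion_rate,
                 polya_rate = polya_rate, error_rate = error_rate,
                 identifier_dialect = identifier_dialect,
                 seed = as.integer(seed)),
            class = "library_spec")
}

#' Simulate a ground-truthed FASTQ library
#'
#' Samples fragments uniformly from the chosen organism's transcripts,
#' draws each read's strand according to the truth orientation (paired
#' mates face inward; the first mate's strand encodes ISF/ISR/IU), applies
#' per-base substitution errors, then plants 3'-terminal features on
#' Bernoulli-selected reads: a 12-nt poly(A) run and/or the adapter (when
#' both, the adapter is terminal — insert, poly(A), adapter — so such reads
#' are intentionally *not* terminal-poly(A) positive). Identifiers follow
#' the requested Illumina dialect with correct mate indices; single-end
#' pre-CASAVA identifiers are emitted without a `/mate` suffix (as real
#' single-end runs of that era were) and therefore parse as dialect
#' `unknown`.
#'
#' Every planted value is recorded in a JSON truth sidecar next to the
#' FASTQ file(s), including the library-type labels and relationship an
#' identifier-grammar reading of the files implies.
#'
#' @param reference An `rp_reference` containing `spec$organism`.
#' @param spec A [library_spec()].
#' @param dir Output directory (created if needed).
#' @param gzip Write gzip-compressed FASTQ.
#' @return A list: `files` (1 or 2 FASTQ paths), `truth` (list), and
#'   `truth_file` (path of the JSON sidecar).
#' @export
simulate_library <- function(reference, spec, dir = tempfile("simlib"),
                             gzip = FALSE) {
  org_tx <- reference$transcripts[reference$transcripts$organism == spec$organism, ,
                                  drop = FALSE]
  if (nrow(org_tx) == 0L) {
    abort_usage("organism '%s' is not in the reference", spec$organism)
  }
  rl <- spec$read_length
  fl <- if (spec$layout == "paired") spec$fragment_length else rl
  eligible <- which(nchar(org_tx$sequence) >= fl)
  if (length(eligible) == 0L) {
    abort_usage("no transcript of '%s' is at least fragment_length = %d nt",
                spec$organism, fl)
  }
  polya_run <- 12L
  sim <- with_seed(spec$seed, {
    n <- spec$n_reads
    tx_pick <- eligible[sample.int(length(eligible), n, replace = TRUE)]
    tx_seq <- org_tx$sequence[tx_pick]
    tx_len <- nchar(tx_seq)
    start <- vapply(tx_len - fl + 1L, function(m) sample.int(m, 1L), 1L)
    frag <- substr(tx_seq, start, start + fl - 1L)

    if (spec$layout == "single") {
      sense <- switch(spec$orientation,
                      SF = rep(TRUE, n),
                      SR = rep(FALSE, n),
                      U = runif(n) < 0.5)
      mate_seqs <- list(ifelse(sense, frag, revcomp(frag)))
      mate1_sense <- sense
    } else {
      mate1_sense <- switch(spec$orientation,
                            ISF = rep(TRUE, n),
                            ISR = rep(FALSE, n),
                            IU = runif(n) < 0.5)
      left <- substr(frag, 1L, rl)
      right_rc <- revcomp(substr(frag, fl - rl + 1L, fl))
      mate_seqs <- list(ifelse(mate1_sense, left, right_rc),
                        ifelse(mate1_sense, right_rc, left))
    }

    n_mates <- length(mate_seqs)
    planted_adapter <- vector("list", n_mates)
    planted_polya <- vector("list", n_mates)
    for (m in seq_len(n_mates)) {
      s <- mutate_bases(mate_seqs[[m]], spec$error_rate)
      has_ad <- if (!is.na(spec$adapter)) {
        runif(n) < spec$adapter_inclusion_rate
      } else rep(FALSE, n)
      has_pa <- runif(n) < spec$polya_rate
      tail <- paste0(ifelse(has_pa, strrep("A", polya_run), ""),
                     ifelse(has_ad, spec$adapter, ""))
      s <- ifelse(nzchar(tail),
                  paste0(substr(s, 1L, rl - nchar(tail)), tail),
                  s)
      mate_seqs[[m]] <- s
      planted_adapter[[m]] <- has_ad
      planted_polya[[m]] <- has_pa & !has_ad   # terminal poly(A) only
    }
    list(mate_seqs = mate_seqs, planted_adapter = planted_adapter,
         planted_polya = planted_polya)
  })

  n <- spec$n_reads
  n_mates <- length(sim$mate_seqs)
  ids <- simulate_identifiers(spec, n, n_mates)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- file.path(dir, paste0("lib_", seq_len(n_mates), ext))
  for (m in seq_len(n_mates)) {
    recs <- structure(
      data.frame(identifier = ids$ids[[m]],
                 sequence = sim$mate_seqs[[m]],
                 quality = strrep("I", nchar(sim$mate_seqs[[m]])),
                 stringsAsFactors = FALSE),
      class = c("fastq_records", "data.frame"))
    write_fastq(recs, paths[m], gzip = gzip)
  }

  taxon <- org_tx$taxon_id[1L]
  truth <- list(
    organism = spec$organism,
    taxon_id = taxon,
    layout = spec$layout,
    orientation = spec$orientation,
    identifier_dialect = spec$identifier_dialect,
    expected_file_labels = ids$expected_labels,
    expected_relationship = if (n_mates == 2L) "split_mates" else NA_character_,
    n_reads = n,
    read_length = spec$read_length,
    adapter = spec$adapter,
    adapter_reads = lapply(sim$planted_adapter, sum),
    polya_terminal_reads = lapply(sim$planted_polya, sum),
    polya_run_length = polya_run,
    error_rate = spec$error_rate,
    seed = spec$seed)
  truth_file <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  list(files = paths, truth = truth, truth_file = truth_file)
}

# Per-base substitutions at a fixed rate; each error draws one of the three
# other bases.
mutate_bases <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- which(runif(length(chars)) < rate)
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
    paste(chars, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Identifiers in the requested dialect, with the library-type labels and
# relationship they imply under the identifier grammar.
simulate_identifiers <- function(spec, n, n_mates) {
  i <- seq_len(n)
  dialect <- spec$identifier_dialect
  if (dialect == "casava_1_8") {
    make <- function(mate) sprintf("SIM01:1:FCX:1:1101:%d:%d %d:N:0:ACGTACGT",
                                   i, i + 1L, mate)
    labels <- if (n_mates == 2L) c("first_mate", "second_mate") else "first_mate"
  } else if (dialect == "pre_casava_1_8") {
    if (n_mates == 2L) {
      make <- function(mate) sprintf("SIMPRE:1:27:%d:%d#0/%d", i, i + 1L, mate)
      labels <- c("first_mate", "second_mate")
    } else {
      make <- function(mate) sprintf("SIMPRE:1:27:%d:%d#0", i, i + 1L)
      labels <- "single"
    }
  } else {
    make <- function(mate) sprintf("read_%06d", i)
    labels <- if (n_mates == 2L) c("first_mate", "second_mate") else "single"
  }
  list(ids = lapply(seq_len(n_mates), make),
       expected_labels = labels)
}
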