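#' Run the full metadata inference pipeline
#'
#' Orchestrates the five inference stages in dependency order over one
#' (single-end) or two (suspected paired-end) FASTQ files:
#'
#' 1. sample up to `config$records_limit` records per file;
#' 2. read-length statistics per file;
#' 3. library source per file by k-mer pseudo-alignment against the RP
#'    reference (skipped entirely under a `tax_id` override);
#' 4. library type, from Illumina identifier grammars first, falling back to
#'    mate-alignment concordance only when the identifiers are inconclusive
#'    and a source organism is available;
#' 5. read orientation, reusing the fallback alignments when they exist
#'    (the aligner runs at most once per file);
#' 6. read layout: 3' adapter and poly(A) fraction per file.
#'
#' Stages that depend on an unassigned source degrade to
#' undetermined/`NA` rather than failing: an unassignable field is a
#' result, not an error.
#'
#' @param paths Character vector of 1 or 2 FASTQ paths (plain or gzipped).
#' @param reference An `rp_reference` from [load_rp_reference()].
#' @param config An [inference_config()].
#' @param adapters An `adapter_library`; default the packaged 18-fragment
#'   library.
#' @param verbose Emit progress messages on stderr.
#' @return A `results_document` (nested list; see [serialize_results()]).
#'   The attribute `diagnostics` carries per-file abundance tables, stage
#'   calls and aligner invocation counts.
#' @export
run_all <- function(paths, reference, config = inference_config(),
                    adapters = load_adapter_library(), verbose = FALSE) {
  if (length(paths) < 1L || length(paths) > 2L) {
    abort_usage("expected 1 or 2 FASTQ paths, got %d", length(paths))
  }
  say <- function(...) if (verbose) message(sprintf(...))
  n_files <- length(paths)
  files <- paste0("file_", seq_len(n_files))

  say("reading up to %s records per file", format(config$records_limit))
  reads <- lapply(paths, read_fastq, max_records = config$records_limit)
  for (i in seq_len(n_files)) {
    if (nrow(reads[[i]]) == 0L) {
      abort_format("input file contains no records: %s", paths[i])
    }
  }

  stats <- lapply(reads, function(r) compute_length_stats(nchar(r$sequence)))

  # --- library source, per mate file independently -------------------------
  abundances <- vector("list", n_files)
  if (!is.na(config$tax_id)) {
    say("library source overridden (taxon %d); quantifier skipped", config$tax_id)
    sources <- rep(list(resolve_source(NULL, config$tax_id, reference, config)),
                   n_files)
  } else {
    say("quantifying RP abundance (k = %d)", config$kmer_k)
    index <- build_kmer_index(reference, config$kmer_k)
    abundances <- lapply(reads, quantify_reads, index = index)
    sources <- lapply(abundances, infer_source, config = config)
  }

  # One alignment organism serves every alignment-based stage of the run:
  # the first assigned per-file source (mate files of one sample share an
  # organism whenever inference succeeds).
  assigned <- vapply(sources, function(s) s$state == "assigned", logical(1))
  align_org <- if (any(assigned)) sources[[which(assigned)[1L]]]$organism else NA_character_
  align_tx <- if (!is.na(align_org)) {
    reference$transcripts[reference$transcripts$organism == align_org, ,
                          drop = FALSE]
  } else NULL

  hits <- vector("list", n_files)
  align_invocations <- integer(n_files)
  align_file <- function(i) {
    if (is.null(hits[[i]]) && !is.null(align_tx)) {
      say("aligning %s to %s RP transcripts", files[i], align_org)
      hits[[i]] <<- align_reads(reads[[i]], align_tx, config)
      align_invocations[i] <<- align_invocations[i] + 1L
    }
    hits[[i]]
  }

  # --- library type --------------------------------------------------------
  ids <- lapply(reads, function(r) parse_identifier(r$identifier))
  type_call <- infer_type_from_ids(ids[[1L]], if (n_files == 2L) ids[[2L]])
  if (!type_call$conclusive && n_files == 2L && !is.null(align_tx)) {
    say("identifiers inconclusive; falling back to alignment concordance")
    rel <- infer_type_from_alignments(align_file(1L), align_file(2L), config)
    type_call$relationship <- rel
    if (rel == "split_mates") {
      # alignments cannot identify which file holds mate 1; input order is
      # the reporting convention
      type_call$file_1 <- "first_mate"
      type_call$file_2 <- "second_mate"
    }
  }

  # --- read orientation ----------------------------------------------------
  orient <- list(file_1 = NA_character_, file_2 = NA_character_,
                 relationship = NA_character_)
  orient_calls <- NULL
  if (!is.null(align_tx)) {
    if (n_files == 2L && identical(type_call$relationship, "split_mates")) {
      paired <- infer_orientation_paired(align_file(1L), align_file(2L), config)
      orient_calls <- paired
      orient$file_1 <- undet_na(paired$file_1$state)
      orient$file_2 <- undet_na(paired$file_2$state)
      orient$relationship <- undet_na(paired$relationship)
    } else {
      singles <- lapply(seq_len(n_files), function(i) {
        infer_orientation_single(align_file(i), config)
      })
      orient_calls <- singles
      orient$file_1 <- undet_na(singles[[1L]]$state)
      if (n_files == 2L) orient$file_2 <- undet_na(singles[[2L]]$state)
    }
  } else {
    say("no source organism available; orientation left undetermined")
  }

  # --- read layout ---------------------------------------------------------
  say("scanning for 3' adapters (%d patterns) and poly(A)", length(adapters))
  automaton <- build_adapter_automaton(adapters)
  layout_calls <- lapply(reads, function(r) {
    list(adapter = call_adapter(count_adapters(r, automaton), config),
         polya = polya_fraction(r, config))
  })

  # --- assemble ------------------------------------------------------------
  doc <- list(
    library_stats = setNames(lapply(stats, function(s) {
      list(read_length = list(min = s$min, max = s$max, mean = s$mean,
                              median = s$median, mode = s$mode))
    }), files),
    library_source = setNames(lapply(sources, function(s) {
      list(short_name = s$organism, taxon_id = s$taxon_id)
    }), files),
    library_type = list(
      file_1 = undet_na(type_call$file_1),
      file_2 = if (n_files == 2L) undet_na(type_call$file_2) else NA_character_,
      relationship = if (n_files == 2L) undet_na(type_call$relationship) else NA_character_),
    read_orientation = orient,
    read_layout = setNames(lapply(layout_calls, function(l) {
      list(adapt_3 = l$adapter$adapt_3, polya_fraction = l$polya)
    }), files))
  structure(doc,
            class = "results_document",
            diagnostics = list(
              abundances = abundances,
              sources = sources,
              type_call = type_call,
              orientation = orient_calls,
              layout = layout_calls,
              align_organism = align_org,
              align_invocations = align_invocations))
}

undet_na <- function(x) {
  if (is.null(x) || is.na(x) || identical(x, "undetermined")) NA_character_ else x
}
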