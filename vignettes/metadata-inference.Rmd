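---
title: "Inferring library metadata from bulk RNA-seq FASTQ files"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring library metadata from bulk RNA-seq FASTQ files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastqmeta)
```

## The problem

Public sequencing archives hold millions of bulk RNA-seq libraries whose
metadata — source organism, single- vs paired-end structure, strandedness,
adapter content — were entered by hand, and are often missing or wrong.
Downstream tools need exactly these facts: an aligner needs read lengths and
library type, a quantifier needs the orientation code, a trimmer needs the
3' adapter. `fastqmeta` infers all of them directly from the reads of one
or two Illumina FASTQ files and reports a single JSON document, leaving a
field `null` whenever the evidence does not support a call: *unassigned is a
result, not an error*.

## The inference model, stage by stage

### Read-length statistics

Minimum, maximum, mean, median and mode of the sampled read lengths are
reported per file. Two deliberate conventions keep the output deterministic
and directly usable as aligner parameters: for an even number of reads the
median is the lower-middle *observed* length (never an interpolated
half-integer), and mode ties resolve to the smallest length. Statistics are
computed on the sampled records (after the `records_limit` prefix), like
every other inference, so one streaming pass suffices and all stages see
the same data.

### Library source

Ribosomal-protein (RP) mRNAs are highly expressed in essentially every
transcriptome and conserved across the tree of life, which makes a small
organism-annotated RP transcript collection a sufficient diagnostic
reference for species identification — there is no need to align against
whole genomes. Reads are assigned to organisms by canonical k-mer
pseudo-alignment:

* every reference k-mer (default $k = 21$) is indexed under its canonical
  form, the lexicographic minimum of the k-mer and its reverse complement,
  so the source call cannot depend on the (still unknown) read orientation;
* a read's compatibility set is the *intersection* of the transcript sets
  of its k-mers that occur in the index; k-mers absent from the index are
  ignored, mirroring pseudo-alignment equivalence classes and suppressing
  spurious cross-organism assignment;
* a mapped read contributes weight 1, split equally among the distinct
  organisms of its compatibility set, so read mass is conserved exactly.

Abundance is normalized as RPM — mapped-read count per million *processed*
reads. The top organism is assigned as the source only if it clears a
minimum signal (`source_min_rpm`, default 5 RPM) and a best/second-best
ratio (`source_min_ratio`, default 2; a second-best of zero counts as an
infinite ratio, and a tie at the top gives ratio 1, hence ambiguity).
Because downstream stages depend on this call, and because the organism is
usually known anyway, `tax_id` overrides the whole stage.

$k = 21$ is small enough that 75-nt reads carry dozens of k-mers and large
enough to be near-unique in mRNA; odd $k$ avoids self-reverse-complement
palindromes. For paired input the source is inferred per mate file
independently and both calls are reported.

### Library type

Illumina instruments encode the mate index in the read identifiers, so the
cheap path never touches the read sequences. Two grammars are recognized:
the CASAVA ≥1.8 form
(`instrument:run:flowcell:lane:tile:x:y mate:filtered:control:index`) and
the older `…#index/mate` form. Two files are *split mates* when one is all
mate 1, the other all mate 2, and the mate-invariant core identifiers agree
**position by position** — mate files written by one run are ordered
identically, so a permutation proves the files were processed
independently. A file mixing mate 1 and mate 2 identifiers is reported
honestly as `mixed_mates`. Note that a complete single-end Illumina library
also carries mate index 1 in its headers; under the identifier grammar it
is therefore labelled `first_mate`, and `single` is reserved for files
whose identifiers carry no mate information at all.

When any identifier fails both grammars the call falls back to alignment:
reads of both files are aligned to the inferred source organism's RP
transcripts, and record *i* of each file is treated as a putative pair
(both files are sampled as prefixes, so indices stay aligned). A pair is
concordant when both mates hit the same transcript on opposite strands
facing inward — the only geometry Illumina paired-end RNA-seq produces.
With at least `min_mapped_reads` (default 20) both-mapped pairs, a
concordant fraction of at least `paired_min_concordant_fraction` (default
0.75 — tolerant of multi-gene families and sequencing errors) calls
`split_mates`. In this fallback the alignments cannot reveal which file
holds mate 1, so mate labels follow input order by convention.

### Read orientation

The aligner records whether each read matched a transcript as-is (`+`) or
had to be reverse-complemented (`-`). The forward fraction among mapped
reads is compared against two bands: at or above `orient_high` (0.85) the
library is stranded-forward (SF), at or below `orient_low` (0.15)
stranded-reverse (SR), in between unstranded (U). Unmapped reads carry no
strand information and are excluded from the denominator. For split-mate
input the same bands are applied to the fraction of concordant pairs whose
first mate aligned forward, yielding ISF/ISR/IU in the Salmon fragment
library notation; per-file SF/SR/U states are reported alongside.

The symmetric (0.15, 0.85) bands leave a wide unstranded middle, the
conventional reading of stranded-protocol specifications. The evidence
floor of 20 mapped reads (or concordant pairs) makes it very unlikely
(binomial, $p < 10^{-3}$) that a 50/50 unstranded library breaches a band
by chance, while remaining permissive for shallow samples.

### The internal aligner

Library-type fallback and orientation need only "which transcript, where,
which strand", so the package uses a small, exactly specified ungapped
seed-and-extend aligner instead of a general spliced aligner: RP mRNA reads
against their own transcripts require no splicing or indel model, and an
ungapped contract admits an *exact* brute-force oracle in the test suite.
Seeds are the read's `seed_len`-mers (default 20) at stride `seed_len`,
looked up exactly in a transcript index for the read and its reverse
complement; each occurrence implies one full-read placement, scored by
matching bases. Only the best placement is reported (orientation counts
reads, not placements), and only if it reaches `ceiling(min_identity *
read_length)` matches (`min_identity` 0.9 — tolerant of sequencing errors,
rejecting cross-gene noise). Ties break deterministically: `+` strand
first, then lowest transcript id, then lowest start.

### Read layout

The 3' adapter is found by exact multi-pattern search with an Aho–Corasick
automaton built over a curated library of eighteen 12-nt adapter fragments
from common Illumina kits (trie with breadth-first failure links, collapsed
to a deterministic transition table over `ACGT`; `N` resets the automaton).
The reported frequency is per-read prevalence — the fraction of reads
containing the adapter at least once — not an occurrence count, which is
the natural reading of "frequency in the library" and easier to interpret.
The same two-cutoff logic as the source call is applied: minimal prevalence
(`adapter_min_fraction`, 0.02) and best/second-best ratio
(`adapter_min_ratio`, 2). A poly-A 12-mer is deliberately absent from the
default library: it is not an adapter, and genuine poly(A) tails would
register as a competing signal.

Poly(A) content is the fraction of reads whose 3' terminus is a run of at
least `polya_min_length` (10) adenosines, with `polya_max_mismatches` (0)
non-A bases tolerated in the terminal window. The rule is strict and
terminal by design — an internal A-run followed by adapter sequence is an
adapter signal, not a tail — and exactly testable.

## Configuration reference

| parameter | default | unit / meaning |
|---|---|---|
| `records_limit` | 1e6 | records read per file (file prefix) |
| `tax_id` | `NA` | manual source override (taxon id) |
| `kmer_k` | 21 | quantifier k-mer size (odd, ≥ 11) |
| `seed_len` | 20 | aligner seed length (nt) |
| `min_identity` | 0.9 | min fraction of matching bases per hit |
| `source_min_rpm` | 5 | min RP signal, reads per million processed |
| `source_min_ratio` | 2 | min best/second organism RPM ratio |
| `min_mapped_reads` | 20 | evidence floor, mapped reads / concordant pairs |
| `orient_low`, `orient_high` | 0.15, 0.85 | forward-fraction bands |
| `paired_min_concordant_fraction` | 0.75 | concordant share to call split mates |
| `adapter_min_fraction` | 0.02 | min per-read adapter prevalence |
| `adapter_min_ratio` | 2 | min best/second adapter ratio |
| `polya_min_length` | 10 | min terminal A-run (nt) |
| `polya_max_mismatches` | 0 | non-A bases tolerated in the window |

The record limit applies per file so that mate files are sampled
symmetrically, and it takes the file *prefix* rather than a random sample:
output is then deterministic without a seed, and record *i* of file 1 still
pairs with record *i* of file 2. Whether a "record" is a read or a pair is
genuinely ambiguous for paired input; here it counts reads per file.

## The synthetic-data generator

`generate_rp_reference()` draws random transcripts per synthetic organism
and *enforces* (rather than assumes) that organisms share no canonical
21-mer, redrawing on violation. `simulate_library()` samples fragments
uniformly from one organism's transcripts, draws each read's strand from
the truth orientation (SF/SR/U with sense probability 1/0/0.5; paired
mates face inward with the first mate's strand encoding ISF/ISR/IU),
applies i.i.d. per-base substitution errors, and plants 3'-terminal
features on Bernoulli-selected reads: a 12-nt poly(A) run and/or a known
adapter 12-mer. When both land on one read the adapter is terminal
(insert–poly(A)–adapter, the biological order), so such reads are recorded
as adapter-positive but not terminal-poly(A)-positive. Identifiers are
emitted in a chosen dialect; single-end pre-CASAVA headers are written
without a `/mate` suffix, as real single-end runs of that era were. Every
planted value is stored in a JSON truth sidecar, and output is
byte-deterministic in the seed.

The generator emulates what the inference stages consume: uniform-length
reads, substitution errors, mate geometry, identifier grammars, planted
adapters and tails. It does *not* emulate quality-dependent error profiles,
indels, expression heterogeneity across transcripts, RNA degradation,
intronic/intergenic reads, or contamination. Passing the recovery suite
therefore demonstrates that the decision rules and algorithms are
implemented correctly under their stated assumptions — not that the default
cutoffs are optimal for every real archive sample.

## Evaluation built into the package

The test suite and `scripts/acceptance.R` recompute, from scratch:

* exact agreement of the Aho–Corasick automaton, the k-mer quantifier and
  the seed-and-extend aligner with independent brute-force oracles on
  randomized small instances (direct substring scans and exhaustive
  placement enumeration);
* full recovery of source organism, library type and relationship,
  orientation, and planted adapter over an 18-cell grid:
  {single, paired} × {SF, SR, U / ISF, ISR, IU} × three identifier
  dialects, at 500 reads per cell, substitution rate 0.005, adapter
  inclusion 0.3, poly(A) rate 0.1;
* the packaged constants (18 adapter fragments of 12 nt; record limit
  10^6; source ratio cutoff 2) and the decision-rule edge cases (ratio
  1.5 → ambiguous, zero signal → low signal, 15 < 20 reads →
  undetermined, tied adapters → ambiguous).

These problem sizes — hundreds of reads, transcripts of a few hundred
nucleotides, tens of grid cells — were chosen as the smallest instances at
which every decision rule is exercised with comfortable statistical margin
(e.g. ≈315 mapped reads per cell put a 50/50 binomial far from the 0.15 /
0.85 bands). They are the package's evaluation conditions, not limits of
the implementation.

## Numerical and degenerate-input choices

* Empty read streams, empty abundance tables and empty identifier lists
  raise classed usage errors; silent zeros are never reported.
* Reads shorter than `seed_len` are unmapped, not errors; reads shorter
  than `kmer_k` simply contribute no k-mers.
* `N` bases are retained on input; k-mers and automaton paths containing
  them never match, and an `N` resets the automaton to its root.
* Reference sequences with ambiguity codes are rejected outright rather
  than sanitized — they would silently poison the k-mer index.
* All ratio rules treat a zero denominator as infinite (sole detection is
  maximal evidence) and exact ties as ratio 1 (hence ambiguity).
* JSON output uses a fixed key order, `null` for undetermined values and
  full numeric precision, so identical runs are byte-identical.

## Known limitations

Only Illumina bulk RNA-seq is in scope: identifier grammars, the inward
mate geometry and the adapter library are all Illumina-specific, and
single-cell chemistries violate the RP-abundance assumption. Library type,
orientation and the alignment fallback depend on a correct (or overridden)
source call and degrade to `undetermined` without one. The quantifier does
no mismatch-tolerant k-mer matching and no transcript-level EM; the aligner
is ungapped and reports no multi-mappers; fragment-length distributions and
probabilistic confidence estimates are not inferred. The shipped synthetic
reference stands in for a production RP database; assembling one (hundreds
of organisms, at least a handful of RP genes each) is a database-build
task outside the runtime scope of this package.
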