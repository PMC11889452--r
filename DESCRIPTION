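Package: fastqmeta
Title: Infer Library Metadata from Bulk Illumina RNA-Seq FASTQ Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers key sample metadata directly from one or two bulk RNA-seq
    FASTQ files produced on Illumina platforms: the source organism (via
    canonical k-mer pseudo-alignment of reads against an organism-annotated
    ribosomal-protein transcript reference), the library type (single-end,
    paired-end, and whether two files are split mates, decided from Illumina
    sequence-identifier grammars with an alignment-concordance fallback), the
    read orientation and strandedness (SF/SR/U and ISF/ISR/IU in Salmon
    notation), the most likely 3' adapter (exact multi-pattern Aho-Corasick
    search over a curated fragment library), the fraction of poly(A)-containing
    reads, and read-length summary statistics. Results are reported as a single
    JSON document. A synthetic-fixture module generates ground-truthed toy
    references and read libraries so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Config/testthat/edition: 3
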