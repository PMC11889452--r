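# Default 3' adapter fragment library: eighteen 12-mers taken from the
# adapter, sequencing-primer and grafting-primer sequences documented for
# common Illumina RNA-seq kits (TruSeq, Nextera, TruSeq Small RNA, legacy
# small-RNA kits, P5/P7). One sequence per line; '#' starts a comment.
AGATCGGAAGAG  # TruSeq universal adapter, read-through signature
CACACGTCTGAA  # TruSeq indexed adapter, downstream fragment
GAACTCCAGTCA  # TruSeq indexed adapter, index-proximal fragment
CGTCGTGTAGGG  # TruSeq read-2 adapter fragment
AAAGAGTGTAGA  # TruSeq read-2 adapter, downstream fragment
CTGTCTCTTATA  # Nextera / TruSight transposase adapter
CACATCTCCGAG  # Nextera adapter, downstream fragment
TGGAATTCTCGG  # TruSeq Small RNA 3' adapter
TCGGGTGCCAAG  # TruSeq Small RNA 3' adapter, downstream fragment
GATCGTCGGACT  # TruSeq Small RNA 5' adapter / RT primer fragment
TCGTATGCCGTC  # Legacy small RNA 3' adapter (v1.0/1.5)
ATCTCGTATGCC  # Legacy genomic/index adapter fragment
ACACTCTTTCCC  # Read-1 sequencing primer, 5' fragment
TACACGACGCTC  # Read-1 sequencing primer, downstream fragment
CTCTTCCGATCT  # Shared 3' end of read-1/read-2 sequencing primers
GTGACTGGAGTT  # Read-2 / PCR primer fragment
CAGACGTGTGCT  # Read-2 / PCR primer, downstream fragment
AATGATACGGCG  # P5 grafting primer fragment
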