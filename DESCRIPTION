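Package: polyAcall
Title: Poly(A) Site Identification and Polyadenylation Signal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies polyadenylation (pA) sites from poly(A)/poly(T)
    tail-bearing sequencing reads: quality filtering and tail trimming,
    strand orientation, exact-match placement of cleavage sites on a
    genome, removal of internal-priming artifacts caused by genomic
    adenine runs, single-linkage clustering of micro-heterogeneous
    cleavage sites, positional mono- and dinucleotide profiling around
    cleavage sites, exhaustive hexamer scanning with peak detection,
    hierarchical assignment of 14 polyadenylation-signal (PAS) motifs,
    and annotation of alternative polyadenylation (APA) against GFF3
    gene models with a 2 kb 3' extension. Includes a synthetic-data
    generator that plants pA clusters, PAS motifs, cleavage
    heterogeneity and internal-priming decoys with full ground truth,
    so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
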