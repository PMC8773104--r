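---
title: "Calling poly(A) sites and polyadenylation signals with polyAcall"
author: "polyAcall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling poly(A) sites and polyadenylation signals with polyAcall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyAcall)
```

## The problem

Cleavage and polyadenylation define the 3' end of almost every eukaryotic
mRNA. The cleavage site (CS) is specified by *cis*-acting elements: a
polyadenylation signal (PAS) hexamer — canonically AAUAAA — located roughly
10–30 nt upstream of the CS and recognized by CPSF, a CA dinucleotide at
the cleavage position itself, and a U/GU-rich downstream element (DSE)
15–30 nt 3' of the CS bound by CstF. Many genes carry more than one poly(A)
site (alternative polyadenylation, APA), producing transcript isoforms with
different 3' UTRs.

Poly(A) sites can be mapped without dedicated 3'-end protocols: ordinary
RNA-seq reads and ESTs that begin or end with a run of untemplated As (or
Ts, for reverse-complemented reads) witness the poly(A) tail directly.
`polyAcall` implements this strategy as a tested pipeline:

1. **Read processing** — whole-read quality filtering, optional adapter
   clipping, detection of terminal A/T runs of at least 10 nt, trimming,
   and orientation of every read to the sense strand.
2. **Site calling** — exact placement of trimmed reads on the genome
   (unique matches only), inference of the cleavage position from the
   oriented 3' end, removal of internal-priming artifacts (sites whose
   downstream genomic sequence contains a run of at least 8 consecutive
   As), and single-linkage merging of cleavage sites separated by at most
   20 nt into pA clusters.
3. **Signal analysis** — extraction of ±100 nt sense-strand contexts around
   each cluster, positional mono- and dinucleotide profiles, an exhaustive
   scan of all 4096 hexamers for positional peaks, and hierarchical
   assignment of one of 14 PAS motifs (or none) per cluster from the 40 nt
   upstream of the CS.
4. **APA annotation** — assignment of clusters to genes using a 2 kb
   strand-aware 3' extension, feature classification (3'UTR, 5'UTR,
   exon(CDS), intron), per-gene site counts, and per-chromosome summaries.

Because real corpora of ESTs and poly(A)-tailed RNA-seq reads are large and
external, the package ships a first-class synthetic-data generator that
plants every structure the analysis looks for, with complete ground truth,
so all stages are testable end to end at desk scale.

## Coordinate conventions

All internal coordinates are 0-based. A cleavage site is a *between-base*
coordinate: the index of the first genomic base not included in the
transcript. Context windows are indexed $-100..+100$ with the CS at 0;
index 0 holds the first base downstream of cleavage. For minus-strand
sites, context index $i$ maps to genomic base $p - 1 - i$, complemented, so
all analyses operate on the sense strand regardless of genomic strand. GFF3
and SAM coordinates are converted at the boundary (both are 1-based).

## The synthetic-data generator

`simulate_dataset()` produces a genome (FASTA), annotation (GFF3), reads
(FASTQ, Phred+33) and truth tables (TSV). Its defaults define the
package's reference fixture; each was chosen once, as a realistic desk-scale
emulation of the data the analysis targets, and is configurable:

* **Genome**: 2 chromosomes × 250 kb of uniform random sequence. Uniform
  composition keeps exact-match alignment unambiguous at read lengths
  ≥ 20 nt and makes chance motif occurrences analytically predictable.
* **Genes**: 200 multi-exon genes (2–4 exons) with 5'UTR, CDS, introns and
  3'UTR, alternating strands, non-overlapping; exon/intron/UTR lengths are
  drawn from ranges typical of compact annotations (exons 120–400 nt,
  introns 150–400 nt, 3'UTRs 150–400 nt).
* **pA clusters**: every gene receives one cluster at its annotated 3' end;
  80% of genes receive 1–4 additional clusters inside the 3'UTR or up to
  800 nt downstream (APA); 30 clusters are planted in intergenic space,
  emulating sites in unannotated regions. This yields ~600 planted
  clusters.
* **PAS motifs**: drawn per cluster from the package's reference frequency
  table (`default_motif_table()`: AAUAAA ≈ 51%, AUUAAA ≈ 12.4%, twelve
  rarer variants, none ≈ 10.6%) and written on the sense strand starting
  `offset ~ Normal(16, 2)` nt upstream of the representative CS, clamped to
  the 6–40 nt search range. The offset distribution is a modeling choice:
  the canonical placement window is 10–30 nt upstream, and no species-level
  offset distribution is assumed.
* **Cleavage heterogeneity**: the number of cleavage sites per cluster is
  drawn from (1: 0.3376, 2: 0.1941, 3: 0.2342, 4: 0.2341); members are
  placed within ±10 nt of the representative with pairwise spacing ≥ 2 nt,
  so a cluster spans at most 20 nt. The representative receives 60% of the
  cluster's reads, reflecting the major/minor usage structure of real
  micro-heterogeneity (and making "representative recovery" well defined).
* **Cleavage signature**: the CA dinucleotide is written at −1..0 of every
  member site (not only the representative) — biologically, CA marks each
  cleavage event — and a 21 nt T/GT-rich element (60% T, 40% G) at +5..+25
  of the representative. Writing CA at each member also guarantees that
  tail trimming stops at a non-A base, so cleavage positions are inferable
  exactly in the error-free limit.
* **Internal-priming decoys**: 40 genomic A-runs of 8–12 nt (half per
  strand, as T-runs on the plus strand for minus-strand decoys) planted in
  introns and intergenic space, at least 300 nt from any cluster. Artifact
  reads end immediately upstream of a decoy run, exactly mimicking
  oligo(dT) priming on genomic adenine.
* **Reads**: 100,000 single-end reads of 100 nt: 85% from clusters
  (fragment ending at a member CS plus a pure-A tail of
  `10 + Poisson(5)` nt), 5% internal-priming artifacts, 10% tailless
  background fragments (exercising the no-tail discard path). Half of all
  reads are emitted reverse-complemented. Substitution errors at 0.002 per
  base; 2% of reads receive uniformly low qualities to exercise the quality
  filter.

Planted elements never overwrite each other: a conflict re-draws the
element's position up to a bounded retry count and then skips it with a
warning. All stages are deterministic functions of the configuration seed.

What the generator does **not** emulate: realistic transcript-abundance
distributions, spliced reads (reads are genome-contiguous, adequate because
tail-trimmed reads are mapped genomically), paired ends, indels, mixed-base
tails, repeat sequence, and GC heterogeneity. Passing tests therefore
demonstrate correctness of the pipeline's logic under the stated model, not
robustness to every artifact of real libraries.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_run` | 10 nt | minimum terminal A/T run to call a tail |
| `q_threshold`, `min_fraction` | Q20, 0.8 | keep a read iff ≥ 80% of bases ≥ Q20 |
| `min_mappable` | 20 nt | minimum post-trim read length |
| `ip_window`, `ip_min_run` | 20 nt, 8 | internal-priming filter: flag sites with ≥ 8 consecutive As within 20 nt downstream |
| `cluster_gap` | 20 nt | maximum gap chained into one cluster |
| `flank` | 100 nt | context half-width |
| `pas_window` | 40 nt | upstream window searched for PAS motifs |
| `extension` | 2000 nt | 3' extension for site-to-gene assignment |
| `peak_threshold`, `peak_min_total_frac` | 3.0, 0.5% | signal call for hexamer peaks |

Notes on the less obvious choices:

* The internal-priming window length is not fixed by the filtering rule
  itself ("at least eight consecutive As downstream"); 20 nt is used
  because it must at least contain an 8-run and covers the region an
  oligo(dT) primer would anneal. The filter checks consecutive **A** on the
  sense strand only: after orientation, genomic A-runs are what mimic
  tails; T-runs on the opposite strand are the mirrored case and are
  handled by the strand-aware window.
* Tail runs are strict: no mismatches inside the run, and N breaks a run.
  When a read qualifies at both ends, the longer run wins; exact ties
  prefer the 3'-A call (the canonical library orientation).
* Clustering is single-linkage on consecutive gaps ≤ 20 nt, so a chain may
  span more than 20 nt overall while every adjacent pair is within the
  gap; the cluster's span is reported alongside. The representative is the
  member with the highest read support, ties resolved to the smallest
  position.
* The PAS search window keeps the whole hexamer within the upstream 40 nt
  (start positions −40..−6). When several motifs co-occur, the
  highest-ranked motif in the descending-frequency hierarchy wins
  (canonical AAUAAA first — the standard disambiguation convention for PAS
  tables), and among occurrences of the winner the most 3' is recorded.
* The hexamer peak score is this package's quantitative replacement for a
  judgment usually made by eye: mean counts per position in a signal
  window (starts −30..−11, i.e. motif bodies within about −25..−10)
  divided by the mean in a downstream background window (+20..+95), with
  the background mean floored at a pseudo-count of 0.5; a hexamer is a
  signal if the ratio reaches 3.0 and it occurs in at least 0.5% of
  contexts. All four numbers are parameters, reported with the output.
* Positions in the 2 kb extension are classified as 3'UTR in summaries
  (kept distinct internally as `extended_3UTR`): a poly(A) site there
  defines a 3' terminus that the annotation simply does not extend far
  enough to contain. Where annotated intervals overlap, precedence is
  3'UTR > 5'UTR > exon(CDS) > intron, resolving collisions toward the
  biologically expected class.

## Numerical and degenerate-input behavior

* Profile denominators count only unambiguous A/C/G/U symbols; padded
  (chromosome-truncated) positions are excluded, so frequencies sum to 1
  at every covered position.
* An empty cluster set yields all-zero heterogeneity counts with fractions
  reported as `NA`, never silent `0/0`.
* Windows that extend past a chromosome end are truncated (internal-priming
  filter) or padded (contexts) and flagged.
* Site-to-gene ties (a position inside one gene and inside another gene's
  extension) resolve to the gene with the nearest annotated 3' end;
  remaining ties resolve lexicographically by gene id, deterministically.
* All outputs are sorted and all randomness flows from a single integer
  seed, so identical configurations give byte-identical artifacts.

## What the test suite establishes

On the reference fixture, the suite verifies end to end that ≥ 95% of
planted clusters are recovered with a representative within ±5 nt, that
≥ 99% of planted internal-priming decoys are removed (and that no retained
site has a qualifying downstream A-run), that AAUAAA and AUUAAA are flagged
as positional signals peaking in the −25..−10 body range while never-planted
hexamers are not, and that APA gene fractions and the heterogeneity
distribution are recovered within three binomial standard deviations of the
planted truth. Motif-frequency recovery is checked on 10,000 directly
generated contexts against a background-corrected expectation: chance
occurrences of PAS hexamers in random flanks are measured by a Monte-Carlo
oracle on motif-free contexts from the same generator, and the expected
assigned frequency of each motif combines the planted rate with the chance
rate of higher- and lower-ranked motifs. Implementation-level checks
compare tail detection, the internal-priming decision, hexamer counting and
clustering against independent brute-force oracles.

Problem sizes were chosen to exercise every stage at meaningful depth while
keeping a full run of the suite on a single CPU comfortable: the reference
fixture uses a 500 kb genome, 200 genes and 100,000 reads; oracle
comparisons use 10,000 random instances; motif recovery uses 10,000
contexts.

## Known limitations

* The built-in aligner is exact-match and unique-only, intended for
  synthetic genomes; real data should be aligned externally and imported
  via SAM (`import_sam()` honours flags, MAPQ and CIGAR).
* Reads with a substitution error in the templated fragment are dropped by
  exact matching rather than rescued; at the default 0.002 error rate this
  costs coverage, not accuracy. An error adjacent to the cleavage junction
  can create a low-support phantom member 1 nt from a true site; this
  inflates small heterogeneity classes slightly and is visible in the
  recovery tests' tolerances.
* EST-style FASTA input bypasses the quality filter (no qualities exist);
  both streams are otherwise processed identically and merged at the site
  level before clustering.
* No isoform-level quantification, no differential APA between conditions,
  and no GO/KEGG-style enrichment: the package ends at annotated site
  tables and summaries.
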