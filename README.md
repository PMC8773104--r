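# polyAcall

Identification of polyadenylation (pA) sites and polyadenylation-signal
(PAS) usage from poly(A)/poly(T) tail-bearing sequencing reads, with
alternative-polyadenylation (APA) annotation — plus a synthetic-data
generator with full planted ground truth so the whole pipeline is testable
end to end without external data.

## Who this is for

Transcriptomics analysts who want to map mRNA 3' ends from ordinary
RNA-seq or EST data rather than dedicated 3'-end protocols: reads that
begin or end with an untemplated run of ≥ 10 As (or Ts, for
reverse-complemented reads) witness the poly(A) tail directly, and their
trimmed 3' ends pin the cleavage site (CS) on the genome.

## The method

1. **Read processing** — whole-read quality filter (keep iff ≥ 80% of
   bases ≥ Q20), optional adapter clipping, detection of maximal terminal
   A/T runs (≥ 10 nt; N breaks a run; longer end wins, ties prefer 3'-A),
   trimming and orientation to the sense strand.
2. **Cleavage-site calling** — unique exact-match placement on the genome
   (or SAM import for externally aligned data); the oriented 3' end is the
   CS, recorded as a 0-based between-base coordinate. Sites whose
   downstream 20 nt of genomic sequence contain ≥ 8 consecutive As are
   removed as internal-priming artifacts (oligo(dT) priming on genomic
   adenine, not a real tail).
3. **Clustering** — single-linkage merging of cleavage sites ≤ 20 nt
   apart (same chromosome and strand) into pA clusters; the
   highest-support member is the representative. Cleavage heterogeneity
   (1, 2, > 2 members per cluster) is summarized.
4. **Signal analysis** — ±100 nt sense-strand contexts (CS at position 0),
   positional mono-/dinucleotide profiles, an exhaustive positional scan
   of all 4096 hexamers with a peak-versus-scatter score, and assignment
   of one of 14 PAS motifs (AAUAAA, AUUAAA, UAUAAA, AGUAAA, AAGAAA,
   AAUAUA, AAUACA, CAUAAA, GAUAAA, AAUGAA, UUUAAA, ACUAAA, AAUAGA,
   AAAAAG) or *none* per cluster from the 40 nt upstream of the CS, in
   descending-frequency hierarchy order.
5. **APA annotation** — cluster-to-gene assignment against a GFF3
   annotation with a strand-aware 2 kb 3' extension, feature
   classification (3'UTR > 5'UTR > exon(CDS) > intron), per-gene site
   counts (APA = ≥ 2 sites), and per-chromosome summaries.

See `vignettes/polya-site-calling.Rmd` for the model, parameter
rationale, and what the synthetic benchmark does and does not establish.

## Worked example

```r
library(polyAcall)

cfg <- sim_config(seed = 7, n_chromosomes = 1, chrom_length = 200000,
                  n_genes = 60, n_reads = 20000,
                  n_intergenic_clusters = 10, n_a_runs = 20)
ds <- simulate_dataset(cfg, out_dir = "readme_fx")

pcfg <- pipeline_config(genome_fasta = ds$paths[["genome"]],
                        reads_fastq = ds$paths[["fastq"]],
                        gff3 = ds$paths[["gff3"]],
                        out_dir = "readme_out", seed = 7)
res <- run_pipeline(pcfg)

str(res$summary$counts)
#> List of 7
#>  $ raw_reads               : int 20000
#>  $ tail_containing_reads   : int 17248
#>  $ uniquely_mapped         : int 14497
#>  $ cleavage_sites          : int 500
#>  $ internal_priming_removed: int 23
#>  $ retained_sites          : int 477
#>  $ pa_clusters             : int 194
```

Of 20,000 simulated reads, 17,248 carry a qualifying tail; their trimmed
forms map uniquely to 500 distinct cleavage sites, 23 of which are
discarded as internal-priming artifacts; the rest merge into 194 pA
clusters. PAS assignment recovers the planted motif mixture:

```r
head(res$pas$frequency[, c("motif", "motif_dna", "count", "percent")], 4)
#>    motif motif_dna count percent
#> 1 AAUAAA    AATAAA   107   55.15
#> 2 AUUAAA    ATTAAA    23   11.86
#> 3 UAUAAA    TATAAA    10    5.15
#> 4 AGUAAA    AGTAAA     5    2.58

res$peaks$AAUAAA[c("score", "is_signal", "peak_pos")]
#> $score: 10.5   $is_signal: TRUE   $peak_pos: -18
```

AAUAAA occurs 10.5× more often per position in the upstream signal window
than in the downstream background — a sharp positional peak at start
position −18 (motif body −18..−13, inside the canonical −10..−25 placement
zone), so it is called a true signal. Annotation summaries report that
94.8% of clusters fall in genes (the planted intergenic fraction accounts
for the rest) and 80% of genes use two or more pA sites:

```r
res$summary$annotation$genic_fraction          #> 0.948
res$summary$annotation$frac_genes_ge2_sites    #> 0.800
```

All artifacts (BED6 clusters, TSV tables, profile matrices, a summary
JSON) are written under `readme_out/`. A thin command-line wrapper with
subcommands (`simulate`, `filter-reads`, `call-sites`, `profile`, `pas`,
`annotate`, `run`, `report`) is installed at `inst/cli/polyAcall.R`:

```sh
Rscript inst/cli/polyAcall.R simulate --seed 1 --out fixture/
Rscript inst/cli/polyAcall.R run --genome fixture/genome.fa \
    --fastq fixture/reads.fastq --gff3 fixture/annotation.gff3 \
    --out-dir results/
```

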