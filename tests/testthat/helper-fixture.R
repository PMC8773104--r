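# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

# Reference end-to-end fixture: 2 x 250 kb genome, 200 genes, ~600 planted
# clusters, 100,000 reads, error rate 0.002, internal-priming rate 0.05.
reference_fixture <- function() {
  if (!exists("fx", envir = .fixture_cache)) {
    cfg <- sim_config(seed = 101L)
    ds <- suppressWarnings(simulate_dataset(cfg, out_dir = file.path(
      tempdir(), "polyAcall_fixture")))
    out_dir <- file.path(tempdir(), "polyAcall_run1")
    pcfg <- pipeline_config(genome_fasta = ds$paths[["genome"]],
                            reads_fastq = ds$paths[["fastq"]],
                            gff3 = ds$paths[["gff3"]],
                            out_dir = out_dir, seed = 101L)
    res <- run_pipeline(pcfg)
    assign("fx", list(cfg = cfg, ds = ds, pcfg = pcfg, res = res),
           envir = .fixture_cache)
  }
  get("fx", envir = .fixture_cache)
}

# small dataset for unit tests that need a full (genome, truth, reads) set
small_fixture <- function() {
  if (!exists("small", envir = .fixture_cache)) {
    cfg <- sim_config(seed = 7L, n_chromosomes = 1L, chrom_length = 60000L,
                      n_genes = 12L, n_reads = 4000L,
                      n_intergenic_clusters = 5L, n_a_runs = 10L)
    ds <- suppressWarnings(simulate_dataset(cfg))
    assign("small", list(cfg = cfg, ds = ds), envir = .fixture_cache)
  }
  get("small", envir = .fixture_cache)
}

# fraction of planted clusters with an observed cluster representative
# within +/- tol nt
cluster_recovery <- function(truth_clusters, called_clusters, tol = 5L) {
  hit <- vapply(seq_len(nrow(truth_clusters)), function(i) {
    any(called_clusters$chrom == truth_clusters$chrom[i] &
        called_clusters$strand == truth_clusters$strand[i] &
        abs(called_clusters$representative_pos -
            truth_clusters$rep_pos[i]) <= tol)
  }, logical(1))
  mean(hit)
}

random_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

make_contexts <- function(seqs_rna, flank = 100L) {
  polyAcall:::new_site_contexts(seqs_rna,
                                sprintf("c%03d", seq_along(seqs_rna)),
                                flank)
}
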