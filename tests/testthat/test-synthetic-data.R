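test_that("genome simulation respects configured sizes and is deterministic", {
  cfg <- sim_config(seed = 1L, n_chromosomes = 2L, chrom_length = 5000L,
                    n_genes = 2L)
  g1 <- simulate_genome(cfg)
  expect_named(g1, c("chr1", "chr2"))
  expect_equal(unname(nchar(g1)), c(5000L, 5000L))
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_error(sim_config(chrom_length = 0), "chrom_length")
})

test_that("gene models have the requested structure on both strands", {
  cfg <- sim_config(seed = 3L, n_chromosomes = 1L, chrom_length = 60000L,
                    n_genes = 10L, exons_per_gene = c(2L, 4L))
  genome <- simulate_genome(cfg)
  models <- simulate_gene_models(genome, cfg)
  expect_equal(nrow(models$genes), 10L)
  expect_setequal(unique(models$genes$strand), c("+", "-"))
  exon_counts <- table(models$features$gene_id[
    models$features$type == "exon"])
  expect_true(all(exon_counts >= 2L))
  # minus-strand geometry: the 3'UTR owns the smallest genomic coordinates
  for (g in models$genes$gene_id[models$genes$strand == "-"]) {
    f <- models$features[models$features$gene_id == g, ]
    utr3_start <- min(f$start0[f$type == "three_prime_UTR"])
    expect_equal(utr3_start, min(f$start0))
  }
  # capacity error when genes cannot fit
  tiny <- sim_config(seed = 3L, n_chromosomes = 1L, chrom_length = 9000L,
                     n_genes = 10L)
  expect_error(simulate_gene_models(simulate_genome(tiny), tiny),
               "too small")
})

test_that("emitted GFF3 round-trips through the annotation reader", {
  cfg <- sim_config(seed = 5L, n_chromosomes = 1L, chrom_length = 40000L,
                    n_genes = 6L)
  genome <- simulate_genome(cfg)
  models <- simulate_gene_models(genome, cfg)
  path <- tempfile(fileext = ".gff3")
  write_gff3(models, path)
  reread <- load_annotation(path)
  expect_equal(reread$genes, models$genes)
  expect_equal(reread$features, models$features)
})

test_that("motif planting writes the motif at the drawn offset", {
  # degenerate distribution: single motif, sd 0 -> always 16 nt upstream
  cfg <- sim_config(seed = 11L, n_chromosomes = 1L, chrom_length = 60000L,
                    n_genes = 8L, motif_frequency_table = c(AATAAA = 1,
                                                            none = 0),
                    pas_offset_sd = 0,
                    heterogeneity_dist = c(`1` = 1),
                    n_intergenic_clusters = 0L, n_a_runs = 0L)
  genome <- simulate_genome(cfg)
  models <- simulate_gene_models(genome, cfg)
  planted <- plant_pa_sites(genome, models, cfg)
  tr <- planted$clusters
  expect_true(all(tr$motif == "AATAAA"))
  expect_true(all(tr$motif_start_idx == -16L))
  for (i in seq_len(nrow(tr))) {
    found <- sense_window(planted$genome[[tr$chrom[i]]], tr$rep_pos[i],
                          tr$strand[i], -16L, -11L)
    expect_identical(found, "AATAAA")
  }
  # all-singleton heterogeneity -> one member per cluster
  expect_true(all(tr$n_members == 1L))
  expect_equal(nrow(planted$members), nrow(tr))
})

test_that("planted truth satisfies its own invariants", {
  fx <- small_fixture()
  tr <- fx$ds$truth
  # member spans within 20 nt
  spans <- tapply(tr$members$pos, tr$members$cluster_id,
                  function(p) max(p) - min(p))
  expect_true(all(spans <= 20L))
  # every planted motif is findable verbatim at its recorded coordinates
  with_motif <- tr$clusters[tr$clusters$motif != "none", ]
  for (i in seq_len(nrow(with_motif))) {
    cl <- with_motif[i, ]
    seen <- sense_window(fx$ds$genome[[cl$chrom]], cl$rep_pos, cl$strand,
                         cl$motif_start_idx, cl$motif_start_idx + 5L)
    expect_identical(seen, cl$motif)
  }
  # decoy A-runs are findable on the sense strand
  ar <- tr$a_runs
  for (i in seq_len(nrow(ar))) {
    win <- sense_window(fx$ds$genome[[ar$chrom[i]]], ar$site_pos[i],
                        ar$strand[i], 0L, ar$run_len[i] - 1L)
    expect_identical(win, strrep("A", ar$run_len[i]))
  }
})

test_that("planted motif frequencies follow the frequency table", {
  # chi-square goodness of fit over directly generated contexts
  cfg <- sim_config(seed = 23L)
  sim <- simulate_contexts(5000L, cfg)
  tab <- table(factor(sim$truth$motif,
                      levels = names(cfg$motif_frequency_table)))
  gof <- suppressWarnings(
    chisq.test(as.integer(tab), p = cfg$motif_frequency_table))
  expect_gt(gof$p.value, 0.01)
})

test_that("planted member counts follow the heterogeneity distribution", {
  fx <- reference_fixture()
  hd <- fx$cfg$heterogeneity_dist
  counts <- table(factor(fx$ds$truth$clusters$n_members,
                         levels = names(hd)))
  gof <- suppressWarnings(chisq.test(as.integer(counts), p = hd))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated reads reconstruct as fragment plus tail", {
  cfg <- sim_config(seed = 13L, n_chromosomes = 1L, chrom_length = 60000L,
                    n_genes = 10L, n_reads = 300L, error_rate = 0,
                    internal_priming_rate = 0, background_rate = 0,
                    low_quality_rate = 0, n_intergenic_clusters = 0L,
                    n_a_runs = 0L)
  ds <- suppressWarnings(simulate_dataset(cfg))
  expect_true(all(ds$reads$origin == "cluster"))
  for (i in sample(nrow(ds$reads), 25L)) {
    r <- ds$reads[i, ]
    seq <- if (r$flipped) revcomp(r$seq) else r$seq
    tail_len <- nchar(seq) - nchar(sub("A+$", "", seq))
    expect_gte(tail_len, 10L)
    frag <- substr(seq, 1L, nchar(seq) - tail_len)
    mem <- ds$truth$members[ds$truth$members$cluster_id == r$origin_id, ]
    hit <- FALSE
    for (j in seq_len(nrow(mem))) {
      expected <- sense_window(ds$genome[[mem$chrom[j]]], r$member_pos,
                               mem$strand[j], -nchar(frag), -1L)
      if (expected == frag) { hit <- TRUE; break }
    }
    # the trailing genomic base may be absorbed into the tail estimate;
    # accept a fragment that maps back exactly by substring search
    if (!hit) {
      hit <- grepl(frag, ds$genome[[mem$chrom[1]]], fixed = TRUE) ||
        grepl(frag, revcomp(ds$genome[[mem$chrom[1]]]), fixed = TRUE)
    }
    expect_true(hit)
  }
})

test_that("read simulation is deterministic and honours the artifact rate", {
  fx <- small_fixture()
  planted <- list(genome = fx$ds$genome, clusters = fx$ds$truth$clusters,
                  members = fx$ds$truth$members, a_runs = fx$ds$truth$a_runs)
  r1 <- simulate_reads(fx$ds$genome, planted, fx$cfg)
  expect_identical(r1, fx$ds$reads)
  cfg0 <- fx$cfg
  cfg0$internal_priming_rate <- 0
  r0 <- simulate_reads(fx$ds$genome, planted, cfg0)
  expect_false(any(r0$origin == "artifact"))
})

test_that("dataset files are byte-identical across runs with one seed", {
  cfg <- sim_config(seed = 17L, n_chromosomes = 1L, chrom_length = 40000L,
                    n_genes = 6L, n_reads = 500L,
                    n_intergenic_clusters = 2L, n_a_runs = 4L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  suppressWarnings(simulate_dataset(cfg, d1))
  suppressWarnings(simulate_dataset(cfg, d2))
  for (f in c("genome.fa", "annotation.gff3", "reads.fastq",
              "truth_clusters.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})
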