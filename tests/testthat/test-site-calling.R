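test_that("the built-in aligner finds unique exact matches on both strands", {
  set.seed(55)
  genome <- c(chrA = paste(sample(c("A", "C", "G", "T"), 5000,
                                  replace = TRUE), collapse = ""))
  fwd <- substr(genome[[1]], 1001, 1040)           # 0-based [1000, 1040)
  reads <- data.frame(read_id = c("f", "r"),
                      seq = c(fwd, revcomp(substr(genome[[1]], 2001, 2030))),
                      stringsAsFactors = FALSE)
  aln <- align_trimmed_reads(genome, reads)
  expect_equal(nrow(aln), 2L)
  f <- aln[aln$read_id == "f", ]
  expect_equal(c(f$strand, f$start0, f$end0), c("+", "1000", "1040"))
  r <- aln[aln$read_id == "r", ]
  expect_equal(c(r$strand, r$start0, r$end0), c("-", "2000", "2030"))
  # a repeated read is dropped as non-unique
  rep_seq <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                   collapse = "")
  genome2 <- c(chrA = paste0(rep_seq, strrep("C", 100), rep_seq))
  aln2 <- align_trimmed_reads(genome2, data.frame(read_id = "dup",
                                                  seq = rep_seq))
  expect_equal(nrow(aln2), 0L)
})

test_that("SAM import honours flags, MAPQ and CIGAR reference widths", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chrA\tLN:10000",
    # 40M forward read at 1-based pos 1001 -> [1000, 1040)
    paste("r1", 0, "chrA", 1001, 42, "40M", "*", 0, 0,
          strrep("A", 40), "*", sep = "\t"),
    # reverse read with deletion: 20M5D15M consumes 40 reference nt
    paste("r2", 16, "chrA", 2001, 42, "20M5D15M", "*", 0, 0,
          strrep("A", 35), "*", sep = "\t"),
    # insertion does not consume reference: 20M5I15M -> 35 nt
    paste("r3", 0, "chrA", 3001, 42, "20M5I15M", "*", 0, 0,
          strrep("A", 40), "*", sep = "\t"),
    paste("r4", 4, "*", 0, 0, "*", "*", 0, 0, strrep("A", 40), "*",
          sep = "\t"),                                  # unmapped
    paste("r5", 256, "chrA", 1001, 42, "40M", "*", 0, 0, "*", "*",
          sep = "\t"),                                  # secondary
    paste("r6", 0, "chrA", 1001, 0, "40M", "*", 0, 0, strrep("A", 40),
          "*", sep = "\t")                              # MAPQ 0
  ), sam)
  aln <- import_sam(sam)
  expect_setequal(aln$read_id, c("r1", "r2", "r3"))
  expect_equal(aln$end0[aln$read_id == "r1"], 1040L)
  expect_equal(aln$start0[aln$read_id == "r2"], 2000L)
  expect_equal(aln$end0[aln$read_id == "r2"], 2040L)
  expect_equal(aln$end0[aln$read_id == "r3"], 3035L)
  expect_equal(aln$strand[aln$read_id == "r2"], "-")
  headerless <- tempfile(fileext = ".sam")
  writeLines("r1\t0\tchrA\t100\t42\t10M\t*\t0\t0\tAAAAAAAAAA\t*",
             headerless)
  expect_error(import_sam(headerless), "format error")
})

test_that("cleavage sites sit at the oriented 3' end and aggregate support", {
  aln <- data.frame(read_id = c("a", "b", "c"),
                    chrom = "chrA", strand = c("+", "-", "+"),
                    start0 = c(1000L, 2000L, 990L),
                    end0 = c(1040L, 2030L, 1040L), stringsAsFactors = FALSE)
  sites <- infer_cleavage_sites(aln)
  expect_equal(nrow(sites), 2L)
  plus <- sites[sites$strand == "+", ]
  expect_equal(plus$pos, 1040L)
  expect_equal(plus$support, 2L)
  expect_equal(sites$pos[sites$strand == "-"], 2000L)
})

test_that("internal-priming filter flags qualifying downstream A-runs", {
  down_art <- paste0(strrep("A", 8), "TCGATCGATCGA")   # 8 As then mixed
  down_ok <- paste0(strrep("A", 7), "TCGATCGATCGAT")   # only 7 As
  genome <- c(chrA = paste0(strrep("C", 100), down_art,
                            strrep("C", 100), down_ok, strrep("C", 100)))
  sites <- data.frame(chrom = "chrA", strand = "+",
                      pos = c(100L, 220L), support = 1L,
                      stringsAsFactors = FALSE)
  out <- filter_internal_priming(sites, genome)
  expect_equal(out$artifact, c(TRUE, FALSE))
  # minus strand: an upstream T-run is a sense-strand A-run
  genome2 <- c(chrA = paste0(strrep("C", 100), strrep("T", 9),
                             strrep("C", 100)))
  site2 <- data.frame(chrom = "chrA", strand = "-", pos = 109L,
                      support = 1L, stringsAsFactors = FALSE)
  expect_true(filter_internal_priming(site2, genome2)$artifact)
  # truncated window at the chromosome end is examined as-is
  genome3 <- c(chrA = paste0(strrep("C", 50), strrep("A", 10)))
  site3 <- data.frame(chrom = "chrA", strand = "+", pos = 50L,
                      support = 1L, stringsAsFactors = FALSE)
  expect_true(filter_internal_priming(site3, genome3)$artifact)
})

test_that("internal-priming decisions match a run-length oracle", {
  set.seed(77)
  wins <- vapply(seq_len(5000), function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE, prob =
                   c(0.55, 0.15, 0.15, 0.15)), collapse = "")
  }, character(1))
  genome <- c(chrA = paste(wins, collapse = ""))
  sites <- data.frame(chrom = "chrA", strand = "+",
                      pos = seq(0L, by = 20L, length.out = 5000L),
                      support = 1L, stringsAsFactors = FALSE)
  got <- filter_internal_priming(sites, genome)$artifact
  want <- vapply(wins, oracle_has_a_run, logical(1), USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("single-linkage clustering chains sites within the gap", {
  sites <- data.frame(chrom = "chrA", strand = "+",
                      pos = c(100L, 115L, 140L),
                      support = c(3L, 1L, 2L), stringsAsFactors = FALSE)
  cl <- cluster_sites(sites, max_gap = 20L)
  expect_equal(nrow(cl$clusters), 2L)
  expect_equal(cl$clusters$n_members, c(2L, 1L))
  expect_equal(cl$clusters$representative_pos, c(100L, 140L))
  # same position, opposite strands -> separate clusters
  both <- data.frame(chrom = "chrA", strand = c("+", "-"), pos = 100L,
                     support = 1L, stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_sites(both)$clusters), 2L)
  # single site is its own cluster and representative
  one <- cluster_sites(data.frame(chrom = "chrA", strand = "+",
                                  pos = 5L, support = 4L))
  expect_equal(one$clusters$representative_pos, 5L)
  expect_equal(one$clusters$n_members, 1L)
  # representative tie-break: equal support -> smallest position
  tie <- cluster_sites(data.frame(chrom = "chrA", strand = "+",
                                  pos = c(10L, 20L), support = 2L))
  expect_equal(tie$clusters$representative_pos, 10L)
})

test_that("clustering is a support-conserving, order-invariant partition", {
  set.seed(88)
  for (trial in 1:25) {
    n <- sample(5:30, 1)
    sites <- data.frame(
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      pos = sample(1:300, n), support = sample(1:5, n, replace = TRUE),
      stringsAsFactors = FALSE)
    cl <- cluster_sites(sites)
    expect_equal(nrow(cl$members), n)
    expect_equal(sum(cl$clusters$total_support), sum(sites$support))
    shuffled <- sites[sample(n), ]
    cl2 <- cluster_sites(shuffled)
    expect_identical(cl$clusters, cl2$clusters)
    # inter-cluster nearest-member distance exceeds the gap
    for (ch in unique(sites$chrom)) for (sd_ in c("+", "-")) {
      m <- cl$members[cl$members$chrom == ch & cl$members$strand == sd_, ]
      if (nrow(m) < 2L) next
      m <- m[order(m$pos), ]
      adjacent <- diff(m$pos) <= 20L
      same_cluster <- m$cluster_id[-1] == m$cluster_id[-nrow(m)]
      expect_identical(adjacent, same_cluster)
    }
  }
})

test_that("clustering matches the exhaustive pairwise-distance oracle", {
  set.seed(89)
  for (trial in 1:40) {
    n <- sample(3:30, 1)
    sites <- data.frame(
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      pos = sample(1:400, n), support = 1L, stringsAsFactors = FALSE)
    cl <- cluster_sites(sites)
    want <- oracle_partition(sites)
    expect_identical(partition_signature(cl$members, cl$members$cluster_id),
                     partition_signature(sites, want))
  }
})

test_that("heterogeneity summary computes fractions and handles emptiness", {
  cl <- data.frame(n_members = c(1L, 1L, 2L, 3L))
  h <- heterogeneity_summary(cl)
  expect_equal(unname(h$fractions), c(0.50, 0.25, 0.25))
  expect_equal(sum(h$fractions), 1)
  h0 <- heterogeneity_summary(data.frame(n_members = integer(0)))
  expect_equal(unname(h0$counts), c(0L, 0L, 0L))
  expect_true(all(is.na(h0$fractions)))
})
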