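test_that("context extraction obeys the indexing and strand contracts", {
  set.seed(31)
  chrom <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                 collapse = "")
  genome <- c(chrA = chrom)
  p <- 250L
  ctx <- extract_contexts(genome, data.frame(chrom = "chrA", strand = "+",
                                             pos = p), flank = 100L)
  s <- ctx$seq[1]
  # index -1 holds base p-1, index 0 holds base p (1-based offsets 100, 101)
  expect_identical(substr(s, 100, 100),
                   dna_to_rna(substr(chrom, p, p)))
  expect_identical(substr(s, 101, 101),
                   dna_to_rna(substr(chrom, p + 1, p + 1)))
  # a minus-strand site on the complementary sequence gives the same context
  genome_rc <- c(chrA = revcomp(chrom))
  p_rc <- 500L - p
  ctx_rc <- extract_contexts(genome_rc,
                             data.frame(chrom = "chrA", strand = "-",
                                        pos = p_rc), flank = 100L)
  expect_identical(ctx_rc$seq[1], s)
  # chromosome-edge truncation is padded
  edge <- extract_contexts(genome, data.frame(chrom = "chrA", strand = "+",
                                              pos = 10L), flank = 100L)
  expect_identical(substr(edge$seq[1], 1, 90), strrep("-", 90))
  expect_error(extract_contexts(genome,
                                data.frame(chrom = "chrA", strand = "+",
                                           pos = 9999L)), "outside")
})

test_that("planted motifs are readable at their offsets in the context", {
  fx <- small_fixture()
  tr <- fx$ds$truth$clusters
  with_motif <- tr[tr$motif != "none", ][1:10, ]
  ctx <- extract_contexts(fx$ds$genome,
                          data.frame(chrom = with_motif$chrom,
                                     strand = with_motif$strand,
                                     pos = with_motif$rep_pos))
  for (i in seq_len(nrow(with_motif))) {
    off <- with_motif$motif_start_idx[i]
    expect_identical(substr(ctx$seq[i], 101 + off, 106 + off),
                     dna_to_rna(with_motif$motif[i]))
  }
})

test_that("mononucleotide profile normalizes and reflects planted structure", {
  ctx <- make_contexts(c(paste0("AU", strrep("C", 199)),
                         paste0("AG", strrep("C", 199))))
  prof <- mononucleotide_profile(ctx)
  expect_equal(unname(prof$freq["A", 1]), 1.0)
  sums <- colSums(prof$freq)
  expect_true(all(abs(sums - 1) < 1e-9))
  # CA planted at every cleavage site drives A at position 0 towards 1
  sim <- simulate_contexts(300L, sim_config(seed = 37L))
  pf <- mononucleotide_profile(sim$contexts)
  expect_gt(pf$freq["A", pf$positions == 0], 0.95)
  expect_gt(pf$freq["C", pf$positions == -1], 0.95)
  # downstream U enrichment from the U/GU element
  u_down <- mean(pf$freq["U", pf$positions %in% 5:25])
  u_bg <- mean(pf$freq["U", pf$positions %in% -100:-50])
  expect_gt(u_down, u_bg + 0.2)
  expect_error(mononucleotide_profile(make_contexts(character(0))))
})

test_that("dinucleotide profile counts pairs at their left position", {
  s <- paste0(strrep("G", 99), "CA", strrep("G", 100))   # CA at (-1, 0)
  prof <- dinucleotide_profile(make_contexts(s))
  expect_equal(unname(prof$freq["CA", prof$positions == -1]), 1)
  sums <- colSums(prof$freq)
  expect_true(all(abs(sums - 1) < 1e-9))
  # uniform random contexts: all 16 dinucleotides near 1/16 (5 SD bound,
  # since 16 x 200 cells are tested simultaneously)
  set.seed(41)
  rnd <- make_contexts(chartr("T", "U", random_dna(400, 201)))
  pr <- dinucleotide_profile(rnd)
  expect_true(all(abs(pr$freq - 1 / 16) <
                    5 * sqrt((1 / 16) * (15 / 16) / 400)))
  # planted U/GU element elevates UU downstream relative to background
  sim <- simulate_contexts(300L, sim_config(seed = 43L))
  pu <- dinucleotide_profile(sim$contexts)
  uu_down <- mean(pu$freq["UU", pu$positions %in% 5:24])
  uu_bg <- mean(pu$freq["UU", pu$positions %in% -100:-50])
  expect_gt(uu_down, uu_bg + 0.1)
})

test_that("hexamer counting handles overlaps and is complete", {
  set.seed(47)
  s <- paste0(strrep("A", 7),
              paste(sample(c("C", "G", "U"), 194, replace = TRUE),
                    collapse = ""))
  ctx <- make_contexts(s)
  hx <- hexamer_positional_counts(ctx)
  aaa <- hexamer_distribution(hx, "AAAAAA")
  expect_equal(unname(aaa[c("-100", "-99")]), c(1L, 1L))
  expect_equal(sum(aaa), 2L)
  # completeness: per start position, counts over all hexamers = coverage
  expect_equal(unname(colSums(hx$counts)), hx$coverage)
})

test_that("hexamer counts match the substring-dictionary oracle", {
  set.seed(49)
  ctx <- make_contexts(chartr("T", "U", random_dna(100, 201)), flank = 100L)
  hx <- hexamer_positional_counts(ctx)
  want <- oracle_hexamer_counts(ctx)
  # every oracle entry is present with the same count
  for (key in sample(names(want), 500)) {
    parts <- strsplit(key, " ")[[1]]
    expect_equal(unname(hexamer_distribution(hx, parts[1])[parts[2]]),
                 want[[key]])
  }
  expect_equal(sum(hx$counts), sum(unlist(want)))
})

test_that("peak score follows the stated ratio formula", {
  pos <- seq(-100L, 95L)
  counts <- setNames(integer(length(pos)), pos)
  counts[pos >= -30 & pos <= -11] <- 5L              # 100 occurrences
  p <- peak_score(counts, n_contexts = 1000L)
  expect_equal(p$score, 5 / 0.5)                     # background floored
  expect_true(p$is_signal)
  expect_true(p$peak_pos >= -30 && p$peak_pos <= -11)
  # uniform scatter scores about 1 and is not a signal
  unif <- setNames(rep(2L, length(pos)), pos)
  pu <- peak_score(unif, n_contexts = 1000L)
  expect_equal(pu$score, 1)
  expect_false(pu$is_signal)
  # low-abundance peak fails the total-occurrence gate
  low <- setNames(integer(length(pos)), pos)
  low[pos == -16] <- 3L
  expect_false(peak_score(low, n_contexts = 1000L)$is_signal)
  expect_error(peak_score(counts, 10L, signal_window = c(-30, 30),
                          background_window = c(20, 95)), "overlap")
})

test_that("PAS assignment follows hierarchy, window and 3'-most rules", {
  base <- strrep("C", 201)
  put <- function(s, idx, motif) {
    substr(s, 101 + idx, 101 + idx + 5) <- motif
    s
  }
  # hierarchy precedence: AAUAAA beats AUUAAA wherever it sits
  s <- put(put(base, -30, "AUUAAA"), -16, "AAUAAA")
  a <- assign_pas(make_contexts(s))
  expect_equal(a$motif, "AAUAAA")
  expect_equal(a$start_idx, -16L)
  expect_equal(a$rank, 1L)
  # two occurrences of the winner: the most 3' is recorded
  s <- put(put(base, -35, "AAUAAA"), -16, "AAUAAA")
  a <- assign_pas(make_contexts(s))
  expect_equal(a$start_idx, -16L)
  # a motif outside the upstream window does not count
  s <- put(base, -60, "AAUAAA")
  a <- assign_pas(make_contexts(s))
  expect_equal(a$motif, "none")
  # window edge: start -6 keeps the body within the upstream 40 nt
  s <- put(base, -6, "AAUAAA")
  expect_equal(assign_pas(make_contexts(s))$start_idx, -6L)
  s <- put(base, -5, "AAUAAA")
  expect_equal(assign_pas(make_contexts(s))$motif, "none")
})

test_that("assignments are consistent with the hexamer counts", {
  sim <- simulate_contexts(200L, sim_config(seed = 53L))
  hx <- hexamer_positional_counts(sim$contexts)
  a <- assign_pas(sim$contexts)
  hit <- a[a$motif != "none", ]
  for (i in sample(nrow(hit), 30L)) {
    d <- hexamer_distribution(hx, hit$motif[i])
    expect_gte(unname(d[as.character(hit$start_idx[i])]), 1L)
  }
})

test_that("removing a motif from the hierarchy only demotes its clusters", {
  sim <- simulate_contexts(400L, sim_config(seed = 59L))
  full <- pas_motifs("RNA")
  reduced <- setdiff(full, "AUUAAA")
  a1 <- assign_pas(sim$contexts, full)
  a2 <- assign_pas(sim$contexts, reduced)
  moved <- a1$motif == "AUUAAA"
  expect_identical(a1$motif[!moved], a2$motif[!moved])
  # demoted clusters fall to lower-ranked motifs or none, never higher
  r1 <- match(a2$motif[moved], full)
  expect_true(all(is.na(r1) | r1 > match("AUUAAA", full)))
})

test_that("the frequency table reports percentages in hierarchy order", {
  ctx <- make_contexts(c(
    sub("C{6}$", "", paste0(strrep("C", 80), "AAUAAA", strrep("C", 121))),
    sub("C{6}$", "", paste0(strrep("C", 80), "AAUAAA", strrep("C", 121))),
    sub("C{6}$", "", paste0(strrep("C", 80), "AUUAAA", strrep("C", 121))),
    strrep("C", 201)))
  tab <- pas_frequency_table(assign_pas(ctx))
  expect_equal(tab$percent[tab$motif == "AAUAAA"], 50)
  expect_equal(tab$percent[tab$motif == "AUUAAA"], 25)
  expect_equal(tab$percent[tab$motif == "none"], 25)
  expect_lt(abs(sum(tab$percent) - 100), 0.1)
  # all-none planting yields a 100% none table
  none <- pas_frequency_table(
    assign_pas(make_contexts(rep(strrep("G", 201), 5))))
  expect_equal(none$percent[none$motif == "none"], 100)
})
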