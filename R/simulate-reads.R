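#' Simulate tail-bearing reads from planted truth
#'
#' Cluster reads are sense-strand genomic fragments ending exactly at a
#' member cleavage position with a non-templated poly(A) tail appended
#' (length `tail_min + Poisson(tail_mean - tail_min)`); internal-priming
#' reads are fragments ending at a planted genomic A-run decoy (the
#' genomic run downstream mimics a tail-priming site); background reads
#' are tailless uniform genomic fragments. Half of all reads are emitted
#' reverse-complemented (so tailed reads begin with a poly(T) run).
#' Per-base substitution errors are applied at `error_rate`; a fraction
#' of reads receive uniformly low Phred qualities so the quality filter is
#' exercisable.
#'
#' @param genome named character vector (the planted genome).
#' @param truth list returned by [plant_pa_sites()].
#' @param config a [sim_config()] object.
#' @return data frame with columns read_id, seq, qual (Phred+33 string),
#'   origin ("cluster", "artifact" or "background"), origin_id (cluster id,
#'   A-run id or NA), member_pos (planted cleavage position or NA), flipped
#'   (logical: emitted as reverse complement).
#' @export
simulate_reads <- function(genome, truth, config) {
  config <- validate_sim_config(config)
  genome <- as_genome_strings(genome)
  set.seed(config$seed + 3L)
  n <- config$n_reads

  origin <- sample(c("artifact", "background", "cluster"), n, replace = TRUE,
                   prob = c(config$internal_priming_rate,
                            config$background_rate,
                            1 - config$internal_priming_rate -
                              config$background_rate))
  if (config$internal_priming_rate > 0 && nrow(truth$a_runs) == 0L) {
    origin[origin == "artifact"] <- "background"
  }

  chrom <- character(n); strand <- character(n)
  pos <- integer(n)                    # cleavage position (tailed reads)
  origin_id <- rep(NA_character_, n)
  member_pos <- rep(NA_integer_, n)

  is_cl <- origin == "cluster"
  if (any(is_cl)) {
    # clusters are sampled uniformly; within a cluster the representative
    # (dominant) cleavage site receives 60% of the reads and the minor
    # sites share the rest, reflecting the major/minor site structure of
    # cleavage micro-heterogeneity
    mem <- truth$members
    rep_of <- truth$clusters$rep_pos[match(mem$cluster_id,
                                           truth$clusters$cluster_id)]
    k <- table(mem$cluster_id)[mem$cluster_id]
    w <- ifelse(k == 1L, 1, ifelse(mem$pos == rep_of, 0.6,
                                   0.4 / (as.integer(k) - 1L)))
    mi <- sample(nrow(mem), sum(is_cl), replace = TRUE, prob = w)
    chrom[is_cl] <- truth$members$chrom[mi]
    strand[is_cl] <- truth$members$strand[mi]
    pos[is_cl] <- truth$members$pos[mi]
    origin_id[is_cl] <- truth$members$cluster_id[mi]
    member_pos[is_cl] <- truth$members$pos[mi]
  }
  is_ar <- origin == "artifact"
  if (any(is_ar)) {
    ai <- sample(nrow(truth$a_runs), sum(is_ar), replace = TRUE)
    chrom[is_ar] <- truth$a_runs$chrom[ai]
    strand[is_ar] <- truth$a_runs$strand[ai]
    pos[is_ar] <- truth$a_runs$site_pos[ai]
    origin_id[is_ar] <- truth$a_runs$arun_id[ai]
  }

  tail_len <- integer(n)
  tailed <- origin != "background"
  tail_len[tailed] <- config$tail_min +
    rpois(sum(tailed), max(0, config$tail_mean - config$tail_min))
  frag_len <- pmax(30L, config$read_length - tail_len)

  seqs <- character(n)
  for (ch in unique(chrom[tailed])) {
    cseq <- genome[[ch]]
    clen <- nchar(cseq)
    for (sd_ in c("+", "-")) {
      sel <- which(tailed & chrom == ch & strand == sd_)
      if (!length(sel)) next
      if (sd_ == "+") {
        s0 <- pmax(0L, pos[sel] - frag_len[sel]); e0 <- pos[sel]
        seqs[sel] <- substring(cseq, s0 + 1L, e0)
      } else {
        s0 <- pos[sel]; e0 <- pmin(clen, pos[sel] + frag_len[sel])
        seqs[sel] <- revcomp(substring(cseq, s0 + 1L, e0))
      }
    }
  }
  is_bg <- origin == "background"
  if (any(is_bg)) {
    bg_chrom <- sample(names(genome), sum(is_bg), replace = TRUE)
    chrom[is_bg] <- bg_chrom
    strand[is_bg] <- sample(c("+", "-"), sum(is_bg), replace = TRUE)
    for (ch in unique(bg_chrom)) {
      cseq <- genome[[ch]]
      sel <- which(is_bg & chrom == ch)
      st <- sample.int(nchar(cseq) - config$read_length, length(sel),
                       replace = TRUE)
      raw <- substring(cseq, st, st + config$read_length - 1L)
      flip <- strand[sel] == "-"
      raw[flip] <- revcomp(raw[flip])
      seqs[sel] <- raw
    }
  }
  seqs[tailed] <- paste0(seqs[tailed], strrep("A", tail_len[tailed]))

  # per-base substitution errors
  if (config$error_rate > 0) {
    len <- nchar(seqs)
    n_err <- rbinom(n, len, config$error_rate)
    for (i in which(n_err > 0L)) {
      at <- sample.int(len[i], n_err[i])
      for (p in at) {
        old <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old),
                                        1L)
      }
    }
  }

  # half the reads emitted reverse-complemented
  flipped <- runif(n) < 0.5
  seqs[flipped] <- revcomp(seqs[flipped])

  low_q <- runif(n) < config$low_quality_rate
  qual <- strrep(ifelse(low_q, rawToChar(as.raw(33L + 10L)),
                        rawToChar(as.raw(33L + 36L))), nchar(seqs))

  data.frame(read_id = sprintf("read%06d", seq_len(n)),
             seq = seqs, qual = qual, origin = origin,
             origin_id = origin_id, member_pos = member_pos,
             flipped = flipped, stringsAsFactors = FALSE)
}

#' Write simulated reads to FASTQ (Phred+33)
#'
#' @param reads data frame from [simulate_reads()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$read_id)
  out[seq(2, length(out), 4)] <- reads$seq
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file into the package's read table
#'
#' @param path FASTQ path (Phred+33).
#' @return data frame with read_id, seq, qual.
#' @export
read_fastq <- function(path) {
  x <- readLines(path)
  if (length(x) %% 4L != 0L) stop("malformed FASTQ: ", path)
  data.frame(read_id = sub("^@", "", sub("\\s.*$", "",
                                         x[seq(1, length(x), 4)])),
             seq = toupper(x[seq(2, length(x), 4)]),
             qual = x[seq(4, length(x), 4)],
             stringsAsFactors = FALSE)
}

#' Simulate cleavage-site contexts directly (no reads)
#'
#' Generates sense-strand +/-`flank` nt context windows around a cleavage
#' site with the same planted structure as the genome generator (PAS motif
#' drawn from the frequency table at `offset ~ Normal(pas_offset_mean,
#' pas_offset_sd)` upstream, CA at -1..0, U/GU element at +5..+25), on a
#' uniform random background. Used for motif-recovery analyses where the
#' read layer is not of interest.
#'
#' @param n number of contexts.
#' @param config a [sim_config()] object.
#' @param flank context half-width (nt).
#' @param plant_motifs set `FALSE` to generate motif-free contexts (the
#'   Monte-Carlo background oracle): CA/UG are still planted but no PAS
#'   hexamer is ever written.
#' @return list: `contexts` (a `site_contexts` object, RNA alphabet) and
#'   `truth` (data frame: context_id, motif (DNA or "none"),
#'   motif_start_idx).
#' @export
simulate_contexts <- function(n, config = sim_config(), flank = 100L,
                              plant_motifs = TRUE) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 4L)
  width <- 2L * flank + 1L
  base <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = "")
  }, character(1))
  motifs <- if (plant_motifs) {
    sample(names(config$motif_frequency_table), n, replace = TRUE,
           prob = config$motif_frequency_table)
  } else rep("none", n)
  start_idx <- rep(NA_integer_, n)
  col <- function(idx) flank + 1L + idx      # context index -> string offset
  for (i in seq_len(n)) {
    if (config$downstream_ug_enrichment) {
      ug <- paste(sample(c("T", "G"), 21L, replace = TRUE,
                         prob = c(0.6, 0.4)), collapse = "")
      substr(base[i], col(5L), col(25L)) <- ug
      substr(base[i], col(-1L), col(0L)) <- "CA"
    }
    if (motifs[i] != "none") {
      off <- as.integer(round(rnorm(1, config$pas_offset_mean,
                                    config$pas_offset_sd)))
      off <- max(6L, min(40L, off))
      substr(base[i], col(-off), col(-off + 5L)) <- motifs[i]
      start_idx[i] <- -off
    }
  }
  ids <- sprintf("ctx%05d", seq_len(n))
  ctx <- new_site_contexts(dna_to_rna(base), ids, flank)
  list(contexts = ctx,
       truth = data.frame(context_id = ids, motif = motifs,
                          motif_start_idx = start_idx,
                          stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs [simulate_genome()], [simulate_gene_models()], [plant_pa_sites()]
#' and [simulate_reads()] and writes genome FASTA (60-column),
#' annotation GFF3, reads FASTQ (Phred+33), truth tables (TSV) and the
#' configuration (YAML) into `out_dir`.
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @return list: genome, models, truth (clusters/members/a_runs), reads,
#'   paths (named vector of written files, or NULL).
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  genome0 <- simulate_genome(config)
  models <- simulate_gene_models(genome0, config)
  planted <- plant_pa_sites(genome0, models, config)
  reads <- simulate_reads(planted$genome, planted, config)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      genome = file.path(out_dir, "genome.fa"),
      gff3 = file.path(out_dir, "annotation.gff3"),
      fastq = file.path(out_dir, "reads.fastq"),
      clusters = file.path(out_dir, "truth_clusters.tsv"),
      members = file.path(out_dir, "truth_members.tsv"),
      a_runs = file.path(out_dir, "truth_aruns.tsv"),
      read_origins = file.path(out_dir, "truth_read_origins.tsv"),
      config = file.path(out_dir, "sim_config.yaml"))
    write_genome_fasta(planted$genome, paths[["genome"]])
    write_gff3(models, paths[["gff3"]])
    write_fastq(reads, paths[["fastq"]])
    write_tsv(planted$clusters, paths[["clusters"]])
    write_tsv(planted$members, paths[["members"]])
    write_tsv(planted$a_runs, paths[["a_runs"]])
    write_tsv(reads[, c("read_id", "origin", "origin_id", "member_pos")],
              paths[["read_origins"]])
    write_config(config, paths[["config"]])
  }
  list(genome = planted$genome, models = models,
       truth = planted[c("clusters", "members", "a_runs")],
       reads = reads, paths = paths)
}
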