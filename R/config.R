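#' Default PAS motif frequency table
#'
#' Planting probabilities for the 14 PAS hexamers plus the "none" class.
#' Motifs are given in the DNA alphabet; probabilities sum to 1.
#'
#' @return named numeric vector (names are DNA hexamers plus `"none"`).
#' @export
default_motif_table <- function() {
  # reference percentages; they carry rounding (sum 100.02) and are
  # normalized to exact probabilities
  x <- c(AATAAA = 50.96, ATTAAA = 12.39, TATAAA = 4.45, AGTAAA = 3.93,
         AAGAAA = 2.63, AATATA = 2.25, AATACA = 2.23, CATAAA = 2.25,
         GATAAA = 2.09, AATGAA = 0.59, TTTAAA = 1.15, ACTAAA = 1.36,
         AATAGA = 1.21, AAAAAG = 1.89, none  = 10.64)
  x / sum(x)
}

#' PAS motif hierarchy
#'
#' The 14 PAS hexamers in descending-frequency order with the canonical
#' AAUAAA first; used as the default disambiguation order when several
#' motifs co-occur upstream of a cleavage site.
#'
#' @param alphabet "RNA" (default) or "DNA".
#' @return character vector of 14 hexamers.
#' @export
pas_motifs <- function(alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  m <- c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
         "AATACA", "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA",
         "AATAGA", "AAAAAG")
  if (alphabet == "RNA") dna_to_rna(m) else m
}

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-data generator.
#' The defaults describe the package's reference fixture: a 2 x 250 kb
#' genome carrying 200 genes whose 3' ends receive pA clusters planted with
#' PAS hexamers at the field's reference frequencies, cleavage
#' micro-heterogeneity within a 20 nt span, poly(A) read tails of at least
#' 10 nt, sequencing errors, and genomic A-run internal-priming decoys.
#'
#' @param seed integer RNG seed.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length (nt).
#' @param n_genes total number of genes over all chromosomes.
#' @param exons_per_gene integer range (length-2 vector) of exons per gene.
#' @param motif_frequency_table named probability vector over DNA hexamers
#'   plus `"none"`; must sum to 1.
#' @param pas_offset_mean mean distance (nt) from the motif start to the
#'   cleavage site; the motif is written so that it starts
#'   `offset` nt upstream of the representative cleavage position. Must lie
#'   in `[10, 30]`, the canonical PAS placement window.
#' @param pas_offset_sd standard deviation of the motif offset (nt).
#' @param heterogeneity_dist named probability vector over the number of
#'   cleavage sites per cluster (names "1","2",... ; supports 1, 2 and >2).
#' @param tail_min,tail_mean minimum and mean poly(A) tail length; tails are
#'   `tail_min + Poisson(tail_mean - tail_min)`, so the minimum is respected.
#' @param read_length total read length (fragment plus tail), nt.
#' @param n_reads number of reads to simulate.
#' @param error_rate per-base substitution probability.
#' @param internal_priming_rate fraction of reads generated from genomic
#'   A-run decoys.
#' @param background_rate fraction of reads drawn uniformly from the genome
#'   without any tail.
#' @param low_quality_rate fraction of reads emitted with uniformly low
#'   Phred qualities (exercises the quality filter).
#' @param downstream_ug_enrichment plant the CA cleavage dinucleotide and a
#'   U/GU-rich (T/GT in DNA) downstream element at each cluster.
#' @param apa_fraction fraction of genes receiving two or more pA clusters.
#' @param max_extra_clusters APA genes receive `1..max_extra_clusters`
#'   additional clusters (uniform).
#' @param n_intergenic_clusters pA clusters planted away from any gene.
#' @param n_a_runs internal-priming decoy A-runs planted per genome
#'   (half on each strand), in introns and intergenic space.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 250000L,
                       n_genes = 200L,
                       exons_per_gene = c(2L, 4L),
                       motif_frequency_table = default_motif_table(),
                       pas_offset_mean = 16,
                       pas_offset_sd = 2,
                       heterogeneity_dist = c(`1` = 0.3376, `2` = 0.1941,
                                              `3` = 0.2342, `4` = 0.2341),
                       tail_min = 10L,
                       tail_mean = 15,
                       read_length = 100L,
                       n_reads = 100000L,
                       error_rate = 0.002,
                       internal_priming_rate = 0.05,
                       background_rate = 0.10,
                       low_quality_rate = 0.02,
                       downstream_ug_enrichment = TRUE,
                       apa_fraction = 0.8,
                       max_extra_clusters = 4L,
                       n_intergenic_clusters = 30L,
                       n_a_runs = 40L) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              motif_frequency_table = motif_frequency_table,
              pas_offset_mean = pas_offset_mean,
              pas_offset_sd = pas_offset_sd,
              heterogeneity_dist = heterogeneity_dist,
              tail_min = as.integer(tail_min),
              tail_mean = tail_mean,
              read_length = as.integer(read_length),
              n_reads = as.integer(n_reads),
              error_rate = error_rate,
              internal_priming_rate = internal_priming_rate,
              background_rate = background_rate,
              low_quality_rate = low_quality_rate,
              downstream_ug_enrichment = isTRUE(downstream_ug_enrichment),
              apa_fraction = apa_fraction,
              max_extra_clusters = as.integer(max_extra_clusters),
              n_intergenic_clusters = as.integer(n_intergenic_clusters),
              n_a_runs = as.integer(n_a_runs))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  cfg_err <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  counts <- c("n_chromosomes", "chrom_length", "n_genes", "read_length",
              "n_reads", "tail_min")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L) {
      cfg_err(f, "must be a positive count")
    }
  }
  if (length(cfg$exons_per_gene) != 2L ||
      any(cfg$exons_per_gene < 1L) ||
      cfg$exons_per_gene[1] > cfg$exons_per_gene[2]) {
    cfg_err("exons_per_gene", "must be an increasing positive range")
  }
  mt <- cfg$motif_frequency_table
  if (is.null(names(mt)) || !"none" %in% names(mt)) {
    cfg_err("motif_frequency_table", "must be named and include 'none'")
  }
  if (abs(sum(mt) - 1) > 1e-9) {
    cfg_err("motif_frequency_table",
            sprintf("probabilities must sum to 1 (got %.12f)", sum(mt)))
  }
  hex <- setdiff(names(mt), "none")
  if (any(nchar(hex) != 6L) || any(grepl("[^ACGT]", hex))) {
    cfg_err("motif_frequency_table", "motifs must be DNA hexamers")
  }
  if (cfg$pas_offset_mean < 10 || cfg$pas_offset_mean > 30) {
    cfg_err("pas_offset_mean", "must lie within [10, 30]")
  }
  hd <- cfg$heterogeneity_dist
  if (is.null(names(hd)) || abs(sum(hd) - 1) > 1e-9 ||
      any(is.na(suppressWarnings(as.integer(names(hd))))) ||
      any(as.integer(names(hd)) < 1L)) {
    cfg_err("heterogeneity_dist",
            "must be probabilities over member counts >= 1 summing to 1")
  }
  if (cfg$tail_min < 10L) cfg_err("tail_min", "tails must be >= 10 nt")
  rates <- c("error_rate", "internal_priming_rate", "background_rate",
             "low_quality_rate")
  for (f in rates) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) cfg_err(f, "must be in [0, 1]")
  }
  if (cfg$internal_priming_rate + cfg$background_rate >= 1) {
    cfg_err("internal_priming_rate",
            "artifact + background fractions must leave room for signal reads")
  }
  if (cfg$apa_fraction < 0 || cfg$apa_fraction > 1) {
    cfg_err("apa_fraction", "must be in [0, 1]")
  }
  cfg
}

#' Pipeline configuration
#'
#' Stage parameters for the analysis pipeline, with the package defaults.
#'
#' @param genome_fasta path to the genome FASTA.
#' @param reads_fastq path to reads (FASTQ, Phred+33; or FASTA for
#'   quality-free EST-like input).
#' @param sam path to a pre-aligned SAM of oriented, tail-trimmed reads;
#'   when given, the built-in aligner is bypassed.
#' @param gff3 path to the gene annotation (GFF3); `NULL` skips the
#'   annotation stages.
#' @param out_dir output directory.
#' @param adapter optional adapter sequence clipped from reads.
#' @param min_run minimum terminal A/T run length to call a tail (nt).
#' @param q_threshold,min_fraction quality filter: keep a read iff at least
#'   `min_fraction` of its bases have Phred quality >= `q_threshold`.
#' @param min_mappable minimum post-trim read length retained (nt).
#' @param ip_window,ip_min_run internal-priming filter: flag a site whose
#'   downstream `ip_window` nt contain a run of >= `ip_min_run` consecutive
#'   A on the sense strand.
#' @param cluster_gap maximum gap (nt) between consecutive cleavage sites
#'   merged into one cluster.
#' @param flank context half-width around the cleavage site (nt).
#' @param pas_window upstream window searched for PAS motifs (nt).
#' @param peak_signal_window,peak_background_window hexamer start-position
#'   windows (inclusive index ranges) used by [peak_score()].
#' @param peak_threshold,peak_min_total_frac signal call thresholds for
#'   [peak_score()].
#' @param extension 3' extension (nt) applied to gene spans when assigning
#'   sites to genes.
#' @param seed RNG seed recorded for provenance.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(genome_fasta = NULL,
                            reads_fastq = NULL,
                            sam = NULL,
                            gff3 = NULL,
                            out_dir = "polyAcall_out",
                            adapter = NULL,
                            min_run = 10L,
                            q_threshold = 20L,
                            min_fraction = 0.8,
                            min_mappable = 20L,
                            ip_window = 20L,
                            ip_min_run = 8L,
                            cluster_gap = 20L,
                            flank = 100L,
                            pas_window = 40L,
                            peak_signal_window = c(-30L, -11L),
                            peak_background_window = c(20L, 95L),
                            peak_threshold = 3.0,
                            peak_min_total_frac = 0.005,
                            extension = 2000L,
                            seed = 1L) {
  cfg <- list(genome_fasta = genome_fasta, reads_fastq = reads_fastq,
              sam = sam, gff3 = gff3, out_dir = out_dir, adapter = adapter,
              min_run = as.integer(min_run),
              q_threshold = as.integer(q_threshold),
              min_fraction = min_fraction,
              min_mappable = as.integer(min_mappable),
              ip_window = as.integer(ip_window),
              ip_min_run = as.integer(ip_min_run),
              cluster_gap = as.integer(cluster_gap),
              flank = as.integer(flank),
              pas_window = as.integer(pas_window),
              peak_signal_window = as.integer(peak_signal_window),
              peak_background_window = as.integer(peak_background_window),
              peak_threshold = peak_threshold,
              peak_min_total_frac = peak_min_total_frac,
              extension = as.integer(extension),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  pos <- c("min_run", "q_threshold", "min_mappable", "ip_window",
           "ip_min_run", "cluster_gap", "flank", "pas_window")
  for (f in pos) {
    if (cfg[[f]] <= 0L) {
      stop(sprintf("pipeline_config field '%s' must be positive", f),
           call. = FALSE)
    }
  }
  if (cfg$extension < 0L) stop("extension must be >= 0", call. = FALSE)
  if (cfg$pas_window > cfg$flank) {
    stop("pas_window must not exceed flank", call. = FALSE)
  }
  if (cfg$min_fraction < 0 || cfg$min_fraction > 1) {
    stop("min_fraction must be in [0, 1]", call. = FALSE)
  }
  cfg
}

#' Read/write configurations as YAML
#'
#' @param cfg a `sim_config` or `pipeline_config` object.
#' @param path file path.
#' @return `write_config` returns the path invisibly; `read_config` returns
#'   the rebuilt, validated configuration object.
#' @export
write_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$.class <- class(cfg)[1]
  # named vectors must be written as YAML maps, not bare sequences
  for (f in c("motif_frequency_table", "heterogeneity_dist")) {
    if (!is.null(lst[[f]])) lst[[f]] <- as.list(lst[[f]])
  }
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  cls <- lst$.class %||% "pipeline_config"
  lst$.class <- NULL
  # yaml flattens named vectors into lists; rebuild through the constructor
  for (f in c("motif_frequency_table", "heterogeneity_dist")) {
    if (!is.null(lst[[f]])) lst[[f]] <- unlist(lst[[f]])
  }
  ctor <- if (cls == "sim_config") sim_config else pipeline_config
  do.call(ctor, lst)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
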