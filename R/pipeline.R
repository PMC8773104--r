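#' Read FASTA reads (EST-like input, no qualities)
#'
#' @param path FASTA path.
#' @return data frame with read_id, seq, qual (NA).
#' @export
read_fasta_reads <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x), qual = NA_character_,
             stringsAsFactors = FALSE)
}

#' Run the full pA-site pipeline
#'
#' Executes read processing -> site calling -> signal analysis -> APA
#' annotation, writing all stage artifacts and a summary JSON to
#' `config$out_dir` (when set). Stages are pure functions of their inputs
#' and the configuration, so re-running with the same inputs reproduces
#' identical outputs. When no annotation is supplied the pipeline stops
#' after signal analysis and the annotation block of the summary is
#' `NULL`.
#'
#' @param config a [pipeline_config()] object.
#' @param genome optional in-memory genome (named character vector),
#'   overriding `config$genome_fasta`.
#' @param reads optional in-memory read table (read_id, seq, qual),
#'   overriding `config$reads_fastq`.
#' @param models optional in-memory `gene_models`, overriding
#'   `config$gff3`.
#' @return list: processed (read-processing output), alignments, sites
#'   (with artifact flags), clusters (`pa_clusters`), contexts, profiles
#'   (mono/di), hexamers (`hexamer_counts`), peaks (per-PAS-motif peak
#'   scores), pas (assignments + frequency table), annotation (or NULL)
#'   and summary (the summary-JSON structure).
#' @export
run_pipeline <- function(config, genome = NULL, reads = NULL,
                         models = NULL) {
  config <- validate_pipeline_config(config)
  set.seed(config$seed)

  if (is.null(genome)) {
    if (is.null(config$genome_fasta)) stop("no genome supplied")
    genome <- as_genome_strings(config$genome_fasta)
  } else genome <- as_genome_strings(genome)

  use_sam <- !is.null(config$sam)
  if (is.null(reads) && !use_sam) {
    if (is.null(config$reads_fastq)) stop("no reads supplied")
    reads <- if (grepl("\\.(fa|fasta)$", config$reads_fastq)) {
      read_fasta_reads(config$reads_fastq)
    } else read_fastq(config$reads_fastq)
  }

  # --- read processing & alignment ---------------------------------------
  if (use_sam) {
    processed <- NULL
    alignments <- import_sam(config$sam)
    n_raw <- NA_integer_; n_tailed <- NA_integer_
  } else {
    processed <- process_reads(reads, adapter = config$adapter,
                               q_threshold = config$q_threshold,
                               min_fraction = config$min_fraction,
                               min_run = config$min_run,
                               min_mappable = config$min_mappable)
    alignments <- align_trimmed_reads(genome, processed$reads,
                                      seed_len = config$min_mappable)
    n_raw <- unname(processed$counts["input"])
    n_tailed <- unname(processed$counts["emitted"]) +
      unname(processed$counts["too_short"])
  }
  message(sprintf("[site_calling] %d uniquely mapped reads",
                  nrow(alignments)))

  # --- site calling ------------------------------------------------------
  sites <- infer_cleavage_sites(alignments)
  sites <- filter_internal_priming(sites, genome, window = config$ip_window,
                                   min_run = config$ip_min_run)
  retained <- sites[!sites$artifact, , drop = FALSE]
  clusters <- cluster_sites(retained, max_gap = config$cluster_gap)
  het <- heterogeneity_summary(clusters)

  # --- signal analysis ---------------------------------------------------
  contexts <- extract_contexts(genome, clusters, flank = config$flank)
  mono <- mononucleotide_profile(contexts)
  di <- dinucleotide_profile(contexts)
  hex <- hexamer_positional_counts(contexts)
  peaks <- lapply(pas_motifs("RNA"), function(m) {
    ps <- peak_score(hexamer_distribution(hex, m), hex$n_contexts,
                     signal_window = config$peak_signal_window,
                     background_window = config$peak_background_window,
                     threshold = config$peak_threshold,
                     min_total_frac = config$peak_min_total_frac)
    c(list(hexamer = m), ps)
  })
  names(peaks) <- pas_motifs("RNA")
  assignments <- assign_pas(contexts,
                            search_window = c(-config$pas_window,
                                              -6L))
  freq_tab <- pas_frequency_table(assignments)

  # --- APA annotation ----------------------------------------------------
  annotation <- NULL
  if (!is.null(models) || !is.null(config$gff3)) {
    if (is.null(models)) models <- load_annotation(config$gff3)
    gene_assign <- assign_sites_to_genes(clusters, models,
                                         extension = config$extension)
    apa <- apa_site_counts(gene_assign)
    chrom_dist <- chromosome_distribution(gene_assign, models)
    fc <- feature_class_fractions(gene_assign)
    annotation <- list(models = models, assignments = gene_assign,
                       apa = apa, chrom_dist = chrom_dist,
                       feature_fractions = fc)
  } else {
    message("[annotate] no annotation supplied; annotation stages skipped")
  }

  summary <- build_summary(config, n_raw, n_tailed, alignments, sites,
                           clusters, het, peaks, freq_tab, annotation)
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(config$out_dir, processed, sites, clusters,
                           contexts, mono, di, hex, peaks, assignments,
                           freq_tab, annotation, summary)
  }
  list(processed = processed, alignments = alignments, sites = sites,
       clusters = clusters, contexts = contexts,
       profiles = list(mono = mono, di = di), hexamers = hex,
       peaks = peaks,
       pas = list(assignments = assignments, frequency = freq_tab),
       annotation = annotation, summary = summary)
}

build_summary <- function(config, n_raw, n_tailed, alignments, sites,
                          clusters, het, peaks, freq_tab, annotation) {
  params <- unclass(config)
  params$genome_fasta <- NULL; params$reads_fastq <- NULL
  params$sam <- NULL; params$gff3 <- NULL; params$out_dir <- NULL
  s <- list(
    counts = list(
      raw_reads = n_raw,
      tail_containing_reads = n_tailed,
      uniquely_mapped = length(unique(alignments$read_id)),
      cleavage_sites = nrow(sites),
      internal_priming_removed = sum(sites$artifact),
      retained_sites = nrow(sites) - sum(sites$artifact),
      pa_clusters = nrow(clusters$clusters)),
    heterogeneity = list(counts = as.list(het$counts),
                         fractions = as.list(het$fractions)),
    pas_frequency = freq_tab,
    pas_signals = lapply(peaks, function(p) {
      list(score = round(p$score, 4), is_signal = p$is_signal,
           peak_pos = p$peak_pos, total = p$total)
    }),
    parameters = params)
  if (!is.null(annotation)) {
    s$annotation <- list(
      genic_fraction = annotation$chrom_dist$genic_fraction,
      feature_class_fractions = as.list(annotation$feature_fractions),
      apa_histogram = as.list(annotation$apa$histogram),
      frac_genes_ge2_sites = annotation$apa$frac_ge2,
      chromosomes = annotation$chrom_dist$table)
  }
  s
}

write_pipeline_outputs <- function(out_dir, processed, sites, clusters,
                                   contexts, mono, di, hex, peaks,
                                   assignments, freq_tab, annotation,
                                   summary) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  if (!is.null(processed)) {
    Biostrings::writeXStringSet(
      setNames(Biostrings::DNAStringSet(processed$reads$seq),
               processed$reads$read_id), fp("oriented_trimmed.fasta"))
    write_tsv(processed$tails, fp("tail_calls.tsv"))
  }
  write_tsv(sites, fp("cleavage_sites.tsv"))
  write_clusters_bed(clusters, fp("clusters.bed"))
  write_tsv(clusters$clusters, fp("clusters.tsv"))
  write_tsv(clusters$members, fp("cluster_members.tsv"))
  ctx_df <- data.frame(cluster_id = contexts$ids, seq_rna = contexts$seq,
                       seq_dna = rna_to_dna(contexts$seq),
                       stringsAsFactors = FALSE)
  write_tsv(ctx_df, fp("contexts.tsv"))
  write_profile_tsv(mono, fp("profile_mononucleotide.tsv"))
  write_profile_tsv(di, fp("profile_dinucleotide.tsv"))
  peak_df <- do.call(rbind, lapply(peaks, function(p) {
    data.frame(hexamer = p$hexamer, score = round(p$score, 4),
               is_signal = p$is_signal, peak_pos = p$peak_pos,
               total = p$total, stringsAsFactors = FALSE)
  }))
  write_tsv(peak_df, fp("pas_peak_scores.tsv"))
  out_assign <- assignments
  out_assign$motif_dna <- ifelse(out_assign$motif == "none", "none",
                                 rna_to_dna(out_assign$motif))
  write_tsv(out_assign, fp("pas_assignments.tsv"))
  write_tsv(freq_tab, fp("pas_frequency.tsv"))
  if (!is.null(annotation)) {
    write_tsv(annotation$assignments, fp("gene_assignments.tsv"))
    write_tsv(annotation$apa$per_gene, fp("apa_per_gene.tsv"))
    write_tsv(data.frame(bin = names(annotation$apa$histogram),
                         n_genes = annotation$apa$histogram),
              fp("apa_histogram.tsv"))
    write_tsv(annotation$chrom_dist$table, fp("chromosome_table.tsv"))
  }
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, na = "null")
  invisible(out_dir)
}
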