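#' Simulate a random genome
#'
#' Generates `n_chromosomes` chromosomes of uniform random base composition.
#' Deterministic for a given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return named character vector of chromosome sequences
#'   (`chr1`, `chr2`, ...).
#' @export
simulate_genome <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  out <- vapply(seq_len(config$n_chromosomes), function(i) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  names(out) <- paste0("chr", seq_len(config$n_chromosomes))
  out
}

#' Write a genome to FASTA
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param path output FASTA path (60-column wrap).
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  g <- Biostrings::DNAStringSet(as_genome_strings(genome))
  Biostrings::writeXStringSet(g, path, width = 60L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models

new_gene_models <- function(genes, features) {
  genes <- genes[order(genes$chrom, genes$start0, genes$gene_id), ,
                 drop = FALSE]
  features <- features[order(features$gene_id, features$type,
                             features$start0), , drop = FALSE]
  rownames(genes) <- NULL
  rownames(features) <- NULL
  structure(list(genes = genes, features = features), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d features on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$features),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Simulate gene models
#'
#' Places non-overlapping multi-exon genes with 5'UTR, CDS, introns and
#' 3'UTR on both strands (alternating), distributed evenly over the
#' chromosomes.
#'
#' @param genome named character vector of chromosome sequences.
#' @param config a [sim_config()] object.
#' @return a `gene_models` object: `$genes` is a data frame
#'   (gene_id, chrom, strand, start0, end0) and `$features` a data frame
#'   (gene_id, chrom, strand, type, start0, end0) with 0-based half-open
#'   coordinates. Types: five_prime_UTR, exon, CDS, intron,
#'   three_prime_UTR.
#' @export
simulate_gene_models <- function(genome, config) {
  config <- validate_sim_config(config)
  genome <- as_genome_strings(genome)
  set.seed(config$seed + 1L)
  n_chrom <- length(genome)
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = n_chrom + 1)))
  genes <- list(); feats <- list(); gi <- 0L
  for (ci in seq_len(n_chrom)) {
    chrom <- names(genome)[ci]
    clen <- nchar(genome[[ci]])
    cursor <- 3000L                       # leave flank-sized margins
    for (k in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      strand <- if (gi %% 2L == 1L) "+" else "-"
      st <- build_gene_structure(config)
      gap <- sample(300:700, 1L)
      if (cursor + st$span + gap + 3000L > clen) {
        stop(sprintf(
          "genome too small: placed %d of %d genes before running out of space on %s",
          gi - 1L, config$n_genes, chrom), call. = FALSE)
      }
      gene_id <- sprintf("gene%03d", gi)
      f <- mirror_structure(st$features, cursor, st$span, strand)
      f$gene_id <- gene_id
      f$chrom <- chrom
      f$strand <- strand
      genes[[gi]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                strand = strand, start0 = cursor,
                                end0 = cursor + st$span,
                                stringsAsFactors = FALSE)
      feats[[gi]] <- f
      cursor <- cursor + st$span + gap
    }
  }
  genes <- do.call(rbind, genes)
  feats <- do.call(rbind, feats)
  new_gene_models(genes, feats[, c("gene_id", "chrom", "strand", "type",
                                   "start0", "end0")])
}

# Transcript-forward gene structure: features in coordinates relative to the
# transcript 5' end (0-based half-open).
build_gene_structure <- function(config) {
  n_exons <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
                    1L)
  utr5 <- sample(60:120, 1L)
  utr3 <- sample(150:400, 1L)
  first_cds <- sample(60:150, 1L)
  last_cds <- sample(60:150, 1L)
  mid_lens <- if (n_exons > 2L) sample(120:300, n_exons - 2L,
                                       replace = TRUE) else integer(0)
  intron_lens <- sample(150:400, n_exons - 1L, replace = TRUE)
  exon_lens <- if (n_exons == 1L) utr5 + first_cds + last_cds + utr3
               else c(utr5 + first_cds, mid_lens, last_cds + utr3)
  rows <- list()
  pos <- 0L
  for (i in seq_len(n_exons)) {
    e0 <- pos; e1 <- pos + exon_lens[i]
    rows[[length(rows) + 1L]] <- data.frame(type = "exon", start0 = e0,
                                            end0 = e1)
    if (i == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(type = "five_prime_UTR",
                                              start0 = e0, end0 = e0 + utr5)
      cds0 <- e0 + utr5
    } else cds0 <- e0
    if (i == n_exons) {
      rows[[length(rows) + 1L]] <- data.frame(type = "three_prime_UTR",
                                              start0 = e1 - utr3, end0 = e1)
      cds1 <- e1 - utr3
    } else cds1 <- e1
    if (cds1 > cds0) {
      rows[[length(rows) + 1L]] <- data.frame(type = "CDS", start0 = cds0,
                                              end0 = cds1)
    }
    if (i < n_exons) {
      rows[[length(rows) + 1L]] <- data.frame(type = "intron", start0 = e1,
                                              end0 = e1 + intron_lens[i])
      pos <- e1 + intron_lens[i]
    }
  }
  feats <- do.call(rbind, rows)
  span <- max(feats$end0)
  list(features = feats, span = span)
}

# Map transcript-forward feature coordinates onto the genome at `start`,
# flipping for the minus strand (so the 3'UTR gets the smallest genomic
# coordinates).
mirror_structure <- function(feats, start, span, strand) {
  if (strand == "+") {
    feats$start0 <- start + feats$start0
    feats$end0 <- start + feats$end0
  } else {
    s <- start + span - feats$end0
    e <- start + span - feats$start0
    feats$start0 <- s
    feats$end0 <- e
  }
  feats
}

#' Write gene models as GFF3
#'
#' Emits gene / mRNA / exon / CDS / five_prime_UTR / three_prime_UTR
#' features (1-based inclusive, per the GFF3 standard) with ID/Parent
#' links; one transcript per gene. Introns are implicit (derivable from
#' exon gaps) and are not emitted, matching standard annotations.
#'
#' @param models a `gene_models` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    f <- models$features[models$features$gene_id == g$gene_id, ]
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(
      gff3_line(g$chrom, "gene", g$start0, g$end0, g$strand, ".",
                sprintf("ID=%s", g$gene_id)),
      gff3_line(g$chrom, "mRNA", g$start0, g$end0, g$strand, ".",
                sprintf("ID=%s;Parent=%s", tid, g$gene_id))
    )
    emit <- f[f$type %in% c("exon", "CDS", "five_prime_UTR",
                            "three_prime_UTR"), ]
    emit <- emit[order(emit$start0, emit$type), ]
    phase_next <- 0L
    cds <- emit[emit$type == "CDS", ]
    # phases follow translation order (genomic order on +, reversed on -)
    cds_order <- if (g$strand == "+") order(cds$start0) else
      order(-cds$start0)
    phases <- integer(nrow(cds))
    for (j in seq_along(cds_order)) {
      phases[cds_order[j]] <- phase_next
      phase_next <- (3L - ((cds$end0[cds_order[j]] -
                            cds$start0[cds_order[j]] - phase_next) %% 3L)) %% 3L
    }
    ci <- 0L
    for (j in seq_len(nrow(emit))) {
      ph <- "."
      if (emit$type[j] == "CDS") { ci <- ci + 1L; ph <- phases[ci] }
      lines <- c(lines, gff3_line(g$chrom, emit$type[j], emit$start0[j],
                                  emit$end0[j], g$strand, ph,
                                  sprintf("Parent=%s", tid)))
    }
    writeLines(lines, con)
  }
  invisible(path)
}

gff3_line <- function(chrom, type, start0, end0, strand, phase, attrs) {
  paste(chrom, "polyAcall_sim", type, start0 + 1L, end0, ".", strand, phase,
        attrs, sep = "\t")
}
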