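#' Load gene models from a GFF3 annotation
#'
#' Parses gene / mRNA / exon / CDS / five_prime_UTR / three_prime_UTR
#' features, takes the union of intervals over all transcripts of each
#' gene (the analysis is transcript-agnostic), and derives introns as the
#' gaps between the merged exons. Coordinates are converted to the
#' package's internal 0-based half-open convention.
#'
#' @param gff3_path path to a GFF3 file with ID/Parent links.
#' @return a `gene_models` object (see [simulate_gene_models()]).
#' @export
load_annotation <- function(gff3_path) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parents <- md$Parent
  first_parent <- vapply(seq_along(gr), function(i) {
    p <- parents[[i]]
    if (length(p)) p[1] else NA_character_
  }, character(1))

  gi <- which(type == "gene")
  if (!length(gi)) stop("GFF3 format error: no gene features in ", gff3_path)
  genes <- data.frame(gene_id = ids[gi],
                      chrom = as.character(GenomicRanges::seqnames(gr)[gi]),
                      strand = as.character(GenomicRanges::strand(gr)[gi]),
                      start0 = GenomicRanges::start(gr)[gi] - 1L,
                      end0 = GenomicRanges::end(gr)[gi],
                      stringsAsFactors = FALSE)

  ti <- which(type %in% c("mRNA", "transcript"))
  tx2gene <- setNames(first_parent[ti], ids[ti])
  if (any(is.na(tx2gene)) || any(!tx2gene %in% genes$gene_id)) {
    bad <- ids[ti][is.na(tx2gene) | !tx2gene %in% genes$gene_id]
    stop("GFF3 format error: transcripts with missing/unknown parents: ",
         paste(bad, collapse = ", "))
  }

  fi <- which(type %in% c("exon", "CDS", "five_prime_UTR",
                          "three_prime_UTR"))
  fgene <- tx2gene[first_parent[fi]]
  # features attached directly to genes are accepted too
  direct <- is.na(fgene) & first_parent[fi] %in% genes$gene_id
  fgene[direct] <- first_parent[fi][direct]
  if (any(is.na(fgene))) {
    stop("GFF3 format error: features with unresolvable parents at lines of type ",
         paste(unique(type[fi][is.na(fgene)]), collapse = ","))
  }
  fdf <- data.frame(gene_id = unname(fgene), type = type[fi],
                    start0 = GenomicRanges::start(gr)[fi] - 1L,
                    end0 = GenomicRanges::end(gr)[fi],
                    stringsAsFactors = FALSE)
  gmeta <- genes[match(fdf$gene_id, genes$gene_id), ]
  if (any(fdf$start0 < 0L) || any(fdf$end0 <= fdf$start0)) {
    stop("GFF3 format error: out-of-bounds feature coordinates")
  }
  fdf$chrom <- gmeta$chrom
  fdf$strand <- gmeta$strand

  # union over transcripts per gene/type, then derive introns
  out <- list()
  for (g in unique(fdf$gene_id)) {
    sub <- fdf[fdf$gene_id == g, ]
    for (ty in unique(sub$type)) {
      ss <- sub[sub$type == ty, ]
      ir <- IRanges::reduce(IRanges::IRanges(ss$start0 + 1L, ss$end0))
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, chrom = ss$chrom[1], strand = ss$strand[1], type = ty,
        start0 = IRanges::start(ir) - 1L, end0 = IRanges::end(ir),
        stringsAsFactors = FALSE)
    }
    ex <- sub[sub$type == "exon", ]
    if (nrow(ex) > 1L) {
      ir <- IRanges::reduce(IRanges::IRanges(ex$start0 + 1L, ex$end0))
      gaps <- IRanges::gaps(ir, start = min(IRanges::start(ir)),
                            end = max(IRanges::end(ir)))
      if (length(gaps)) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, chrom = ex$chrom[1], strand = ex$strand[1],
          type = "intron", start0 = IRanges::start(gaps) - 1L,
          end0 = IRanges::end(gaps), stringsAsFactors = FALSE)
      }
    }
  }
  feats <- do.call(rbind, out)
  new_gene_models(genes, feats[, c("gene_id", "chrom", "strand", "type",
                                   "start0", "end0")])
}

# strand-aware extended gene interval and 3'-end anchor (between-base)
gene_geometry <- function(genes, extension) {
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             strand = genes$strand,
             ext_start0 = ifelse(genes$strand == "+", genes$start0,
                                 genes$start0 - extension),
             ext_end0 = ifelse(genes$strand == "+",
                               genes$end0 + extension, genes$end0),
             tp_end = ifelse(genes$strand == "+", genes$end0,
                             genes$start0),
             stringsAsFactors = FALSE)
}

#' Assign pA clusters to genes and classify their feature location
#'
#' A cluster is assigned to a gene iff its representative cleavage
#' position lies within the gene span or within the strand-aware
#' `extension` nt 3' extension, same strand only. When several genes
#' qualify, the gene whose annotated 3' end is nearest wins. Assigned
#' clusters are classified with precedence 3'UTR > 5'UTR > exon(CDS) >
#' intron over the gene's (possibly overlapping) merged intervals;
#' positions in the extension are classified `extended_3UTR` (reported
#' with the 3'UTR class — the transcript end is by construction a 3'
#' terminus). Unassigned clusters are `intergenic`.
#'
#' @param clusters a `pa_clusters` object or its `$clusters` data frame.
#' @param models a `gene_models` object.
#' @param extension 3' extension (nt).
#' @return data frame: cluster_id, chrom, strand, representative_pos,
#'   gene_id (NA = intergenic), feature_class, distance_to_3p (signed:
#'   positive = downstream of the annotated 3' end).
#' @export
assign_sites_to_genes <- function(clusters, models, extension = 2000L) {
  cl <- if (inherits(clusters, "pa_clusters")) clusters$clusters else
    clusters
  geo <- gene_geometry(models$genes, extension)
  n <- nrow(cl)
  gene_id <- rep(NA_character_, n)
  feat <- rep("intergenic", n)
  dist3 <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- cl$representative_pos[i]
    # the transcript's 3'-terminal base decides membership
    c0 <- if (cl$strand[i] == "+") p - 1L else p
    cand <- geo[geo$chrom == cl$chrom[i] & geo$strand == cl$strand[i] &
                c0 >= geo$ext_start0 & c0 < geo$ext_end0, ]
    if (nrow(cand) == 0L) next
    d <- abs(p - cand$tp_end)
    g <- cand[order(d, cand$gene_id)[1], ]
    gene_id[i] <- g$gene_id
    dist3[i] <- if (cl$strand[i] == "+") p - g$tp_end else g$tp_end - p
    feat[i] <- classify_feature(c0, cl$strand[i], g$gene_id, models,
                                extension)
  }
  data.frame(cluster_id = cl$cluster_id, chrom = cl$chrom,
             strand = cl$strand, representative_pos = cl$representative_pos,
             gene_id = gene_id, feature_class = feat,
             distance_to_3p = dist3, stringsAsFactors = FALSE)
}

#' Classify a genomic position against one gene's features
#'
#' Precedence where intervals overlap or abut: 3'UTR > 5'UTR > exon(CDS)
#' > intron; positions past the annotated 3' end (within the extension)
#' are `extended_3UTR`.
#'
#' @param pos0 0-based genomic position of the transcript 3'-terminal
#'   base.
#' @param strand cluster strand.
#' @param gene_id the assigned gene.
#' @param models a `gene_models` object.
#' @param extension extension used at assignment time (nt).
#' @return one of "3UTR", "5UTR", "exon(CDS)", "intron", "extended_3UTR".
#' @export
classify_feature <- function(pos0, strand, gene_id, models,
                             extension = 2000L) {
  f <- models$features[models$features$gene_id == gene_id, ]
  within <- function(ty) {
    ff <- f[f$type == ty, , drop = FALSE]
    nrow(ff) > 0L && any(pos0 >= ff$start0 & pos0 < ff$end0)
  }
  if (within("three_prime_UTR")) return("3UTR")
  if (within("five_prime_UTR")) return("5UTR")
  if (within("CDS") || within("exon")) return("exon(CDS)")
  if (within("intron")) return("intron")
  g <- models$genes[models$genes$gene_id == gene_id, ]
  in_ext <- if (g$strand == "+") {
    pos0 >= g$end0 && pos0 < g$end0 + extension
  } else {
    pos0 < g$start0 && pos0 >= g$start0 - extension
  }
  if (in_ext) return("extended_3UTR")
  stop(sprintf(
    "classification error: position %d not in any interval of %s",
    pos0, gene_id))
}

#' Feature-class fractions over genic clusters
#'
#' `extended_3UTR` is folded into the 3'UTR class for reporting.
#'
#' @param assignments data frame from [assign_sites_to_genes()].
#' @return named numeric vector over 3UTR / intron / `exon(CDS)` / 5UTR,
#'   summing to 1 (NA if there are no genic clusters).
#' @export
feature_class_fractions <- function(assignments) {
  genic <- assignments[!is.na(assignments$gene_id), ]
  classes <- c("3UTR", "intron", "exon(CDS)", "5UTR")
  if (nrow(genic) == 0L) return(setNames(rep(NA_real_, 4), classes))
  fc <- ifelse(genic$feature_class == "extended_3UTR", "3UTR",
               genic$feature_class)
  counts <- table(factor(fc, levels = classes))
  setNames(as.numeric(counts) / nrow(genic), classes)
}

#' Per-gene pA site counts and the APA histogram
#'
#' @param assignments data frame from [assign_sites_to_genes()].
#' @return list: `per_gene` (gene_id, n_sites), `histogram` (named counts
#'   over bins 1, 2, 3, 4, 5, ">5") and `frac_ge2` (fraction of
#'   site-bearing genes with two or more pA sites).
#' @export
apa_site_counts <- function(assignments) {
  genic <- assignments[!is.na(assignments$gene_id), ]
  per_gene <- as.data.frame(table(genic$gene_id),
                            stringsAsFactors = FALSE)
  names(per_gene) <- c("gene_id", "n_sites")
  bins <- c("1", "2", "3", "4", "5", ">5")
  binned <- ifelse(per_gene$n_sites > 5L, ">5",
                   as.character(per_gene$n_sites))
  histogram <- table(factor(binned, levels = bins))
  frac_ge2 <- if (nrow(per_gene)) mean(per_gene$n_sites >= 2L) else
    NA_real_
  list(per_gene = per_gene,
       histogram = setNames(as.integer(histogram), bins),
       frac_ge2 = frac_ge2)
}

#' Per-chromosome gene and pA cluster distribution
#'
#' @param assignments data frame from [assign_sites_to_genes()].
#' @param models a `gene_models` object.
#' @return list: `table` (chrom, n_genes, n_clusters, genic, intergenic)
#'   and `genic_fraction` (global fraction of clusters assigned to a
#'   gene).
#' @export
chromosome_distribution <- function(assignments, models) {
  chroms <- sort(unique(c(models$genes$chrom, assignments$chrom)))
  tab <- do.call(rbind, lapply(chroms, function(ch) {
    a <- assignments[assignments$chrom == ch, ]
    data.frame(chrom = ch,
               n_genes = sum(models$genes$chrom == ch),
               n_clusters = nrow(a),
               genic = sum(!is.na(a$gene_id)),
               intergenic = sum(is.na(a$gene_id)),
               stringsAsFactors = FALSE)
  }))
  genic_fraction <- if (nrow(assignments)) {
    mean(!is.na(assignments$gene_id))
  } else NA_real_
  list(table = tab, genic_fraction = genic_fraction)
}
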