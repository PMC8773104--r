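# Occupancy registry: per-chromosome matrix of planted element footprints
# (0-based half-open), used to keep planted elements from overwriting each
# other. Implemented as growing two-column matrices in an environment.
new_registry <- function(chroms) {
  reg <- new.env(parent = emptyenv())
  for (ch in chroms) assign(ch, matrix(numeric(0), ncol = 2), envir = reg)
  reg
}

reg_conflicts <- function(reg, chrom, start0, end0) {
  occ <- get(chrom, envir = reg)
  if (nrow(occ) == 0L) return(FALSE)
  any(occ[, 1] < end0 & occ[, 2] > start0)
}

reg_add <- function(reg, chrom, start0, end0) {
  occ <- get(chrom, envir = reg)
  assign(chrom, rbind(occ, c(start0, end0)), envir = reg)
}

#' Plant pA clusters, PAS motifs and internal-priming decoys into a genome
#'
#' Every gene receives one pA cluster whose representative cleavage site is
#' the annotated transcript 3' end; a fraction (`apa_fraction`) receive
#' additional clusters inside the 3'UTR or within the downstream 3'
#' extension region. Per cluster, a PAS hexamer is drawn from
#' `motif_frequency_table` and written on the sense strand starting
#' `offset ~ Normal(pas_offset_mean, pas_offset_sd)` nt upstream of the
#' representative cleavage position ("none"-class clusters receive no
#' motif); when `downstream_ug_enrichment` is on, the cleavage dinucleotide
#' CA is written at positions -1..0 of every member cleavage site and a
#' U/GU-rich (T/GT) element at +5..+25 of the representative. Member
#' cleavage positions are drawn per `heterogeneity_dist` within a 20 nt
#' span. Genomic A-run internal-priming decoys are planted in introns and
#' intergenic space. Elements that would overwrite an already-planted
#' element are re-drawn up to a bounded retry count, then skipped with a
#' warning.
#'
#' @param genome named character vector of chromosome sequences.
#' @param gene_models a `gene_models` object from [simulate_gene_models()].
#' @param config a [sim_config()] object.
#' @return list with elements `genome` (modified sequences), `clusters`
#'   (truth data frame: cluster_id, chrom, strand, rep_pos, motif,
#'   motif_start_idx, n_members, in_gene, location), `members` (cluster_id,
#'   chrom, strand, pos) and `a_runs` (arun_id, chrom, strand, run_start0,
#'   run_len, site_pos).
#' @export
plant_pa_sites <- function(genome, gene_models, config) {
  config <- validate_sim_config(config)
  genome <- as_genome_strings(genome)
  set.seed(config$seed + 2L)
  reg <- new_registry(names(genome))
  anchors <- list()   # cluster anchors, kept >= 100 nt apart

  genes <- gene_models$genes
  feats <- gene_models$features
  clusters <- list(); members <- list()
  cid <- 0L

  plant_cluster <- function(chrom, strand, rep_pos, in_gene, location) {
    cid <<- cid + 1L
    cluster_id <- sprintf("pac%04d", cid)
    cseq <- genome[[chrom]]

    # member cleavage positions: representative plus extras, spacing >= 2,
    # all within a 20 nt span
    k <- sample(as.integer(names(config$heterogeneity_dist)), 1L,
                prob = config$heterogeneity_dist)
    offs <- 0L
    cand <- c(-10:-2, 2:10)
    while (length(offs) < k && length(cand) > 0L) {
      d <- if (length(cand) == 1L) cand else sample(cand, 1L)
      if (all(abs(d - offs) >= 2L)) offs <- c(offs, d)
      cand <- setdiff(cand, d)
    }
    offs <- sort(offs)
    mem_pos <- rep_pos + offs

    if (config$downstream_ug_enrichment) {
      # CA cleavage dinucleotide at -1..0 of every member (written before
      # the motif and the UG element so that the realized member counts
      # follow heterogeneity_dist)
      kept <- logical(length(mem_pos))
      for (j in seq_along(mem_pos)) {
        fp <- sense_footprint(mem_pos[j], strand, -1L, 2L)
        if (reg_conflicts(reg, chrom, fp[1], fp[2])) {
          kept[j] <- mem_pos[j] == rep_pos  # never drop the representative
          next
        }
        upd <- write_sense(cseq, mem_pos[j], strand, -1L, "CA")
        if (!is.null(upd)) {
          cseq <- upd
          reg_add(reg, chrom, fp[1], fp[2])
          kept[j] <- TRUE
        } else kept[j] <- mem_pos[j] == rep_pos
      }
      mem_pos <- mem_pos[kept]
    }

    # PAS motif
    motif <- sample(names(config$motif_frequency_table), 1L,
                    prob = config$motif_frequency_table)
    motif_start_idx <- NA_integer_
    if (motif != "none") {
      placed <- FALSE
      for (try in 1:20) {
        off <- as.integer(round(rnorm(1, config$pas_offset_mean,
                                      config$pas_offset_sd)))
        off <- max(6L, min(40L, off))
        fp <- sense_footprint(rep_pos, strand, -off, 6L)
        if (!reg_conflicts(reg, chrom, fp[1], fp[2])) {
          upd <- write_sense(cseq, rep_pos, strand, -off, motif)
          if (!is.null(upd)) {
            cseq <- upd
            reg_add(reg, chrom, fp[1], fp[2])
            motif_start_idx <- -off
            placed <- TRUE
            break
          }
        }
      }
      if (!placed) {
        warning(sprintf("cluster %s: could not place motif %s, skipped",
                        cluster_id, motif))
        motif <- "none"
      }
    }

    if (config$downstream_ug_enrichment) {
      # U/GU-rich downstream element at +5..+25 of the representative,
      # written base-by-base so member CA plantings are preserved
      ug <- sample(c("T", "G"), 21L, replace = TRUE, prob = c(0.6, 0.4))
      for (j in 0:20) {
        idx <- 5L + j
        fp <- sense_footprint(rep_pos, strand, idx, 1L)
        if (reg_conflicts(reg, chrom, fp[1], fp[2])) next
        upd <- write_sense(cseq, rep_pos, strand, idx, ug[j + 1L])
        if (!is.null(upd)) cseq <- upd
      }
      fp <- sense_footprint(rep_pos, strand, 5L, 21L)
      reg_add(reg, chrom, fp[1], fp[2])
    }

    genome[[chrom]] <<- cseq
    anchors[[length(anchors) + 1L]] <<- data.frame(chrom = chrom,
                                                   pos = rep_pos)
    clusters[[cid]] <<- data.frame(
      cluster_id = cluster_id, chrom = chrom, strand = strand,
      rep_pos = rep_pos, motif = motif, motif_start_idx = motif_start_idx,
      n_members = length(mem_pos), in_gene = in_gene, location = location,
      stringsAsFactors = FALSE)
    members[[cid]] <<- data.frame(cluster_id = cluster_id, chrom = chrom,
                                  strand = strand, pos = mem_pos,
                                  stringsAsFactors = FALSE)
  }

  anchor_clear <- function(chrom, pos) {
    if (length(anchors) == 0L) return(TRUE)
    a <- do.call(rbind, anchors)
    !any(a$chrom == chrom & abs(a$pos - pos) < 100L)
  }

  # genic clusters: one at every annotated 3' end, extras for APA genes
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    rep_pos <- if (g$strand == "+") g$end0 else g$start0
    plant_cluster(g$chrom, g$strand, rep_pos, g$gene_id, "3UTR_end")
    if (runif(1) < config$apa_fraction) {
      utr3 <- feats[feats$gene_id == g$gene_id &
                    feats$type == "three_prime_UTR", ]
      utr3_len <- sum(utr3$end0 - utr3$start0)
      n_extra <- sample(seq_len(config$max_extra_clusters), 1L)
      for (e in seq_len(n_extra)) {
        placed <- FALSE
        for (try in 1:20) {
          in_utr <- utr3_len >= 250L && runif(1) < 0.4
          if (in_utr) {
            d <- sample(100:(utr3_len - 100L), 1L)  # upstream, inside 3'UTR
            pos <- if (g$strand == "+") g$end0 - d else g$start0 + d
            loc <- "3UTR_internal"
          } else {
            d <- sample(100:800, 1L)                # downstream extension
            pos <- if (g$strand == "+") g$end0 + d else g$start0 - d
            loc <- "extension"
          }
          if (anchor_clear(g$chrom, pos)) {
            plant_cluster(g$chrom, g$strand, pos, g$gene_id, loc)
            placed <- TRUE
            break
          }
        }
        if (!placed) warning(sprintf(
          "gene %s: could not place extra cluster, skipped", g$gene_id))
      }
    }
  }

  # intergenic clusters: away from every gene span (plus extension margin)
  if (config$n_intergenic_clusters > 0L) {
    for (e in seq_len(config$n_intergenic_clusters)) {
      placed <- FALSE
      for (try in 1:50) {
        chrom <- sample(names(genome), 1L)
        clen <- nchar(genome[[chrom]])
        pos <- sample(200:(clen - 200L), 1L)
        strand <- sample(c("+", "-"), 1L)
        gsel <- genes$chrom == chrom
        near_gene <- any(gsel & pos >= genes$start0 - 3000L &
                         pos <= genes$end0 + 3000L)
        if (!near_gene && anchor_clear(chrom, pos)) {
          plant_cluster(chrom, strand, pos, NA_character_, "intergenic")
          placed <- TRUE
          break
        }
      }
      if (!placed) warning("could not place intergenic cluster, skipped")
    }
  }

  # internal-priming decoys: A-runs (T-runs for minus-strand decoys) in
  # introns/intergenic space, clear of clusters and planted elements
  a_runs <- list()
  exonic <- feats[feats$type %in% c("exon", "five_prime_UTR",
                                    "three_prime_UTR", "CDS"), ]
  anchor_df <- do.call(rbind, anchors)
  for (r in seq_len(config$n_a_runs)) {
    strand <- if (r %% 2L == 1L) "+" else "-"
    placed <- FALSE
    for (try in 1:50) {
      chrom <- sample(names(genome), 1L)
      clen <- nchar(genome[[chrom]])
      run_len <- sample(8:12, 1L)
      run_start <- sample(200:(clen - 200L - run_len), 1L)
      run_end <- run_start + run_len
      esel <- exonic$chrom == chrom
      in_exon <- any(esel & exonic$start0 < run_end + 50L &
                     exonic$end0 > run_start - 50L)
      near_anchor <- any(anchor_df$chrom == chrom &
                         abs(anchor_df$pos - run_start) < 300L)
      if (!in_exon && !near_anchor &&
          !reg_conflicts(reg, chrom, run_start - 30L, run_end + 30L)) {
        base <- if (strand == "+") "A" else "T"
        s <- genome[[chrom]]
        substr(s, run_start + 1L, run_end) <- strrep(base, run_len)
        genome[[chrom]] <- s
        reg_add(reg, chrom, run_start, run_end)
        site_pos <- if (strand == "+") run_start else run_end
        a_runs[[length(a_runs) + 1L]] <- data.frame(
          arun_id = sprintf("arun%03d", r), chrom = chrom, strand = strand,
          run_start0 = run_start, run_len = run_len, site_pos = site_pos,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) warning("could not place internal-priming decoy, skipped")
  }

  clusters <- do.call(rbind, clusters)
  members <- do.call(rbind, members)
  clusters$n_members <- vapply(clusters$cluster_id, function(id) {
    sum(members$cluster_id == id)
  }, integer(1))
  list(genome = genome,
       clusters = clusters,
       members = members,
       a_runs = if (length(a_runs)) do.call(rbind, a_runs) else
         data.frame(arun_id = character(0), chrom = character(0),
                    strand = character(0), run_start0 = integer(0),
                    run_len = integer(0), site_pos = integer(0)))
}
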