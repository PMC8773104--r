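#' Place oriented trimmed reads on the genome (exact match, unique only)
#'
#' Built-in aligner for synthetic genomes: each read is anchored by its
#' 3'-terminal `seed_len`-mer (Aho-Corasick dictionary match over every
#' chromosome and both strands) and verified by full-length exact
#' comparison. Only reads with exactly one genomic match (counting the
#' reverse complement) are retained. For real data, use [import_sam()]
#' instead.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param reads data frame with read_id and seq columns (oriented, trimmed,
#'   all at least `seed_len` nt).
#' @param seed_len anchor length (nt).
#' @return data frame of unique alignments: read_id, chrom, strand,
#'   start0, end0 (0-based half-open reference interval).
#' @export
align_trimmed_reads <- function(genome, reads, seed_len = 20L) {
  genome <- as_genome_strings(genome)
  if (nrow(reads) == 0L) {
    return(data.frame(read_id = character(0), chrom = character(0),
                      strand = character(0), start0 = integer(0),
                      end0 = integer(0)))
  }
  if (any(nchar(reads$seq) < seed_len)) {
    stop("all reads must be at least seed_len nt; filter first")
  }
  useq <- unique(reads$seq)
  L <- nchar(useq)
  rcseq <- revcomp(useq)
  fwd_seed <- substr(useq, L - seed_len + 1L, L)
  rc_seed <- substr(rcseq, 1L, seed_len)
  pd_fwd <- Biostrings::PDict(fwd_seed)
  pd_rc <- Biostrings::PDict(rc_seed)

  hit_list <- list()
  for (ch in names(genome)) {
    subject <- Biostrings::DNAString(genome[[ch]])
    clen <- length(subject)
    m <- Biostrings::matchPDict(pd_fwd, subject)
    cnt <- S4Vectors::elementNROWS(m)
    if (any(cnt > 0L)) {
      pid <- rep.int(seq_along(cnt), cnt)
      ends <- unlist(IRanges::end(m), use.names = FALSE)
      # full read occupies [e - L + 1, e] (1-based)
      starts <- ends - L[pid] + 1L
      ok <- starts >= 1L
      pid <- pid[ok]; starts <- starts[ok]; ends <- ends[ok]
      if (length(pid)) {
        ver <- substring(genome[[ch]], starts, ends) == useq[pid]
        if (any(ver)) {
          hit_list[[length(hit_list) + 1L]] <- data.frame(
            pid = pid[ver], chrom = ch, strand = "+",
            start0 = starts[ver] - 1L, end0 = ends[ver],
            stringsAsFactors = FALSE)
        }
      }
    }
    m <- Biostrings::matchPDict(pd_rc, subject)
    cnt <- S4Vectors::elementNROWS(m)
    if (any(cnt > 0L)) {
      pid <- rep.int(seq_along(cnt), cnt)
      starts <- unlist(IRanges::start(m), use.names = FALSE)
      ends <- starts + L[pid] - 1L
      ok <- ends <= clen
      pid <- pid[ok]; starts <- starts[ok]; ends <- ends[ok]
      if (length(pid)) {
        ver <- substring(genome[[ch]], starts, ends) == rcseq[pid]
        if (any(ver)) {
          hit_list[[length(hit_list) + 1L]] <- data.frame(
            pid = pid[ver], chrom = ch, strand = "-",
            start0 = starts[ver] - 1L, end0 = ends[ver],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hit_list) == 0L) {
    return(data.frame(read_id = character(0), chrom = character(0),
                      strand = character(0), start0 = integer(0),
                      end0 = integer(0)))
  }
  hits <- do.call(rbind, hit_list)
  n_hits <- tabulate(hits$pid, nbins = length(useq))
  hits <- hits[n_hits[hits$pid] == 1L, , drop = FALSE]
  map <- match(reads$seq, useq)
  row <- match(map, hits$pid)            # unique hit row per read, or NA
  keep <- !is.na(row)
  data.frame(read_id = reads$read_id[keep],
             chrom = hits$chrom[row[keep]],
             strand = hits$strand[row[keep]],
             start0 = hits$start0[row[keep]],
             end0 = hits$end0[row[keep]],
             stringsAsFactors = FALSE)
}

#' Import alignments of oriented, tail-trimmed reads from a SAM file
#'
#' Drops unmapped, secondary and supplementary records and records with
#' mapping quality 0 (multi-mappers, per the bowtie2 convention). The
#' reference end is computed from the CIGAR reference-consuming
#' operations.
#'
#' @param sam_path path to a SAM file with headers.
#' @return data frame: read_id, chrom, strand, start0, end0.
#' @export
import_sam <- function(sam_path) {
  head_lines <- readLines(sam_path, n = 100L)
  if (!any(startsWith(head_lines, "@SQ"))) {
    stop("SAM format error in ", sam_path, ": no @SQ header lines",
         call. = FALSE)
  }
  bam <- tryCatch(
    Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE),
    error = function(e) stop("SAM format error in ", sam_path, ": ",
                             conditionMessage(e), call. = FALSE))
  x <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar")))[[1]]
  flag <- x$flag
  keep <- !bitwAnd(flag, 0x4) & !bitwAnd(flag, 0x100) &
    !bitwAnd(flag, 0x800) & !is.na(x$mapq) & x$mapq > 0L & !is.na(x$pos)
  refw <- cigar_ref_width(x$cigar[keep])
  data.frame(read_id = x$qname[keep],
             chrom = as.character(x$rname[keep]),
             strand = ifelse(bitwAnd(flag[keep], 0x10) > 0L, "-", "+"),
             start0 = x$pos[keep] - 1L,
             end0 = x$pos[keep] - 1L + refw,
             stringsAsFactors = FALSE)
}

# reference-consumed width from CIGAR (M, D, N, =, X consume the reference)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    m <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    ops <- regmatches(cg, list(m))[[1]]
    op <- substring(ops, nchar(ops), nchar(ops))
    len <- as.integer(substring(ops, 1L, nchar(ops) - 1L))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Infer cleavage sites from alignments
#'
#' For an oriented read (3' end abutting the tail), a + strand alignment
#' puts the cleavage site at the reference end and a - strand alignment at
#' the reference start (0-based between-base coordinates). Reads sharing a
#' site aggregate into its support.
#'
#' @param alignments data frame from [align_trimmed_reads()] or
#'   [import_sam()].
#' @return data frame of cleavage sites: chrom, strand, pos, support,
#'   sorted by (chrom, strand, pos).
#' @export
infer_cleavage_sites <- function(alignments) {
  if (nrow(alignments) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      pos = integer(0), support = integer(0)))
  }
  pos <- ifelse(alignments$strand == "+", alignments$end0,
                alignments$start0)
  key <- paste(alignments$chrom, alignments$strand, pos, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    strand = vapply(parts, `[`, "", 2L),
                    pos = as.integer(vapply(parts, `[`, "", 3L)),
                    support = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$strand, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Internal-priming filter
#'
#' Examines the sense-strand genomic window of `window` nt immediately
#' downstream of each cleavage site (for - strand sites: the reverse
#' complement of the upstream genomic window) and flags the site as an
#' internal-priming artifact iff the window contains a run of at least
#' `min_run` consecutive A. Windows truncated at chromosome ends are
#' examined as-is.
#'
#' @param sites data frame from [infer_cleavage_sites()].
#' @param genome named character vector or `DNAStringSet`.
#' @param window downstream window length (nt).
#' @param min_run minimum qualifying A-run length (nt).
#' @return the input with logical column `artifact` appended.
#' @export
filter_internal_priming <- function(sites, genome, window = 20L,
                                    min_run = 8L) {
  genome <- as_genome_strings(genome)
  win <- downstream_windows(sites, genome, window)
  sites$artifact <- grepl(strrep("A", min_run), win, fixed = TRUE)
  sites
}

# sense-strand downstream windows for a site table (vectorized)
downstream_windows <- function(sites, genome, window) {
  win <- character(nrow(sites))
  for (ch in unique(sites$chrom)) {
    cseq <- genome[[ch]]
    if (is.null(cseq)) stop("site on unknown chromosome: ", ch)
    clen <- nchar(cseq)
    sel <- which(sites$chrom == ch & sites$strand == "+")
    if (length(sel)) {
      s0 <- pmin(sites$pos[sel], clen)
      e0 <- pmin(sites$pos[sel] + window, clen)
      win[sel] <- substring(cseq, s0 + 1L, e0)
    }
    sel <- which(sites$chrom == ch & sites$strand == "-")
    if (length(sel)) {
      s0 <- pmax(sites$pos[sel] - window, 0L)
      e0 <- pmax(sites$pos[sel], 0L)
      win[sel] <- revcomp(substring(cseq, s0 + 1L, e0))
    }
  }
  win
}

#' Merge cleavage sites into pA clusters
#'
#' Single-linkage chaining: consecutive sites on the same chromosome and
#' strand whose positions differ by at most `max_gap` nt join one
#' cluster. The representative is the member with the highest read
#' support (ties: smallest position). The partition is order-invariant
#' (input is sorted internally).
#'
#' @param sites data frame of cleavage sites (chrom, strand, pos,
#'   support); the `artifact` column, if present, must already be
#'   filtered out by the caller.
#' @param max_gap maximum gap between chained neighbours (nt).
#' @return list of class `pa_clusters`: `$clusters` (cluster_id, chrom,
#'   strand, start, end (member-position span, inclusive),
#'   representative_pos, n_members, total_support) and `$members` (the
#'   sites with a cluster_id column), both sorted.
#' @export
cluster_sites <- function(sites, max_gap = 20L) {
  sites <- sites[order(sites$chrom, sites$strand, sites$pos), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  n <- nrow(sites)
  if (n == 0L) {
    clusters <- data.frame(cluster_id = character(0), chrom = character(0),
                           strand = character(0), start = integer(0),
                           end = integer(0), representative_pos = integer(0),
                           n_members = integer(0), total_support = integer(0))
    return(structure(list(clusters = clusters, members = sites),
                     class = "pa_clusters"))
  }
  new_grp <- c(TRUE, sites$chrom[-1] != sites$chrom[-n] |
                 sites$strand[-1] != sites$strand[-n] |
                 sites$pos[-1] - sites$pos[-n] > max_gap)
  grp <- cumsum(new_grp)
  sites$cluster_id <- sprintf("PAC%05d", grp)
  sp <- split(seq_len(n), grp)
  clusters <- do.call(rbind, lapply(sp, function(ix) {
    s <- sites[ix, ]
    best <- ix[which(s$support == max(s$support))]
    rep_pos <- min(sites$pos[best])           # tie-break: smallest position
    data.frame(cluster_id = s$cluster_id[1], chrom = s$chrom[1],
               strand = s$strand[1], start = min(s$pos), end = max(s$pos),
               representative_pos = rep_pos, n_members = nrow(s),
               total_support = sum(s$support), stringsAsFactors = FALSE)
  }))
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, members = sites),
            class = "pa_clusters")
}

#' @export
print.pa_clusters <- function(x, ...) {
  cat(sprintf("pa_clusters: %d clusters over %d cleavage sites\n",
              nrow(x$clusters), nrow(x$members)))
  invisible(x)
}

#' Cleavage-site heterogeneity summary
#'
#' Fractions of clusters with exactly one, exactly two, or more than two
#' member cleavage sites.
#'
#' @param clusters a `pa_clusters` object or its `$clusters` data frame.
#' @return list: `counts` (named integer vector n1/n2/n_gt2) and
#'   `fractions` (same names, summing to 1; all NA when there are no
#'   clusters).
#' @export
heterogeneity_summary <- function(clusters) {
  cl <- if (inherits(clusters, "pa_clusters")) clusters$clusters else
    clusters
  counts <- c(n1 = sum(cl$n_members == 1L),
              n2 = sum(cl$n_members == 2L),
              n_gt2 = sum(cl$n_members > 2L))
  total <- sum(counts)
  fractions <- if (total == 0L) {
    c(n1 = NA_real_, n2 = NA_real_, n_gt2 = NA_real_)
  } else counts / total
  list(counts = counts, fractions = fractions)
}

#' Write pA clusters as BED6
#'
#' BED columns: chrom, span start, span end (half-open), cluster id, total
#' support (score), strand.
#'
#' @param clusters a `pa_clusters` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  cl <- clusters$clusters
  bed <- data.frame(cl$chrom, cl$start, pmax(cl$end, cl$start + 1L),
                    cl$cluster_id, cl$total_support, cl$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
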