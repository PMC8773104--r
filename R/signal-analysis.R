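# site_contexts: sense-strand windows around cleavage sites in the RNA
# reporting alphabet (A/C/G/U), indexed -flank..+flank with the cleavage
# site at 0 (index 0 holds the first base downstream of cleavage).
# Chromosome-end truncation is padded with "-".
new_site_contexts <- function(seq, ids, flank) {
  stopifnot(all(nchar(seq) == 2L * flank + 1L))
  structure(list(seq = seq, ids = ids, flank = as.integer(flank)),
            class = "site_contexts")
}

#' @export
print.site_contexts <- function(x, ...) {
  cat(sprintf("site_contexts: %d windows of +/-%d nt around the cleavage site\n",
              length(x$seq), x$flank))
  invisible(x)
}

#' @export
length.site_contexts <- function(x) length(x$seq)

#' Extract +/-flank nt sense-strand contexts around cluster representatives
#'
#' For a + strand cluster at position `p`, context index `i` holds the
#' genomic base at `p + i`; for a - strand cluster, the base at
#' `p - 1 - i`, complemented — so index 0 is always the first base
#' downstream of the cleavage site and upstream of the site is at negative
#' indices. T is reported as U; windows truncated at chromosome ends are
#' padded with `-`.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param clusters a `pa_clusters` object, or a data frame with chrom,
#'   strand and representative_pos (or pos) columns.
#' @param flank half-width (nt).
#' @return a `site_contexts` object (ids are cluster ids when available).
#' @export
extract_contexts <- function(genome, clusters, flank = 100L) {
  genome <- as_genome_strings(genome)
  cl <- if (inherits(clusters, "pa_clusters")) clusters$clusters else
    clusters
  pos <- cl$representative_pos %||% cl$pos
  ids <- cl$cluster_id %||% sprintf("site%05d", seq_len(nrow(cl)))
  bad <- pos < 0L | pos > nchar(genome[cl$chrom])
  if (any(bad)) {
    stop("representative position outside chromosome for cluster ",
         ids[which(bad)[1]])
  }
  seqs <- vapply(seq_len(nrow(cl)), function(i) {
    sense_window(genome[[cl$chrom[i]]], pos[i], cl$strand[i],
                 -flank, flank)
  }, character(1))
  new_site_contexts(dna_to_rna(seqs), ids, flank)
}

context_matrix <- function(contexts) {
  M <- matrix(unlist(strsplit(contexts$seq, ""), use.names = FALSE),
              nrow = length(contexts$seq), byrow = TRUE)
  colnames(M) <- as.character(seq(-contexts$flank, contexts$flank))
  M
}

#' Positional mononucleotide profile
#'
#' Per-position frequencies of A, C, G and U over a set of contexts.
#' Padded (and any non-ACGU) symbols are excluded from the denominator, so
#' frequencies sum to 1 at every position with coverage.
#'
#' @param contexts a `site_contexts` object.
#' @return object of class `positional_profile`: `$freq` (symbols x
#'   positions matrix), `$positions`, `$denominator` (per-position counted
#'   contexts).
#' @export
mononucleotide_profile <- function(contexts) {
  if (length(contexts) == 0L) stop("no contexts supplied")
  M <- context_matrix(contexts)
  symbols <- c("A", "C", "G", "U")
  counts <- vapply(symbols, function(s) colSums(M == s),
                   numeric(ncol(M)))
  denom <- rowSums(counts)                 # rows = positions here
  freq <- t(counts / ifelse(denom == 0, NA, denom))
  structure(list(freq = freq, symbols = symbols,
                 positions = seq(-contexts$flank, contexts$flank),
                 denominator = as.integer(denom)),
            class = "positional_profile")
}

#' Positional dinucleotide profile
#'
#' The dinucleotide at position `i` pairs the symbols at `(i, i + 1)`;
#' frequencies over the 16 dinucleotides sum to 1 per position (positions
#' `-flank .. flank - 1`). Pairs touching padding are excluded from the
#' denominator.
#'
#' @param contexts a `site_contexts` object.
#' @return a `positional_profile` with 16 symbols.
#' @export
dinucleotide_profile <- function(contexts) {
  if (length(contexts) == 0L) stop("no contexts supplied")
  M <- context_matrix(contexts)
  W <- ncol(M)
  di <- matrix(paste0(M[, -W], M[, -1]), nrow = nrow(M))
  symbols <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                             paste0))
  symbols <- sort(symbols)
  counts <- vapply(symbols, function(s) {
    if (nrow(di) == 1L) as.numeric(di == s) else colSums(di == s)
  }, numeric(W - 1L))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, symbols))
  denom <- rowSums(counts)
  freq <- t(counts / ifelse(denom == 0, NA, denom))
  structure(list(freq = freq, symbols = symbols,
                 positions = seq(-contexts$flank, contexts$flank - 1L),
                 denominator = as.integer(denom)),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf("positional_profile: %d symbols x positions %d..%d\n",
              length(x$symbols), min(x$positions), max(x$positions)))
  invisible(x)
}

#' Positional counts for every observed hexamer
#'
#' For each hexamer and each start position `s` (hexamer body at
#' `s..s+5`), counts the contexts whose window contains that hexamer
#' starting at `s`. Multiple occurrences within one context each count
#' once at their own start position.
#'
#' @param contexts a `site_contexts` object.
#' @return object of class `hexamer_counts`: `$counts` (observed-hexamer x
#'   start-position integer matrix), `$positions`, `$n_contexts`,
#'   `$coverage` (contexts with a full ACGU window per start position).
#' @export
hexamer_positional_counts <- function(contexts) {
  if (length(contexts) == 0L) stop("no contexts supplied")
  f <- contexts$flank
  starts <- seq(-f, f - 5L)
  n <- length(contexts$seq)
  hex <- character(0); pos <- integer(0); cov <- integer(length(starts))
  chunks <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    sub <- substr(contexts$seq, j, j + 5L)
    ok <- !grepl("[^ACGU]", sub)
    cov[j] <- sum(ok)
    chunks[[j]] <- sub[ok]
  }
  lens <- lengths(chunks)
  hex <- unlist(chunks, use.names = FALSE)
  pos <- rep.int(starts, lens)
  tab <- table(factor(hex), factor(pos, levels = starts))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), as.character(starts)))
  structure(list(counts = counts, positions = starts, n_contexts = n,
                 coverage = cov),
            class = "hexamer_counts")
}

#' @export
print.hexamer_counts <- function(x, ...) {
  cat(sprintf("hexamer_counts: %d observed hexamers x %d start positions (%d contexts)\n",
              nrow(x$counts), length(x$positions), x$n_contexts))
  invisible(x)
}

#' Positional count vector for one hexamer
#'
#' @param hx a `hexamer_counts` object.
#' @param hexamer RNA hexamer (6-symbol string over ACGU).
#' @return named integer vector over start positions (zero where unseen).
#' @export
hexamer_distribution <- function(hx, hexamer) {
  if (hexamer %in% rownames(hx$counts)) {
    setNames(hx$counts[hexamer, ], colnames(hx$counts))
  } else {
    setNames(integer(length(hx$positions)), as.character(hx$positions))
  }
}

#' Peak-versus-scatter score for a hexamer's positional distribution
#'
#' A true PAS hexamer shows a sharp positional peak upstream of the
#' cleavage site, whereas random hexamers scatter. The score is the mean
#' count per position inside the signal window divided by the mean count
#' per position inside the background window (the background mean is
#' floored at a pseudo-count of 0.5 to avoid division by zero). The
#' hexamer is called a signal iff the score reaches `threshold` and its
#' total occurrence count reaches `min_total_frac` of the contexts.
#'
#' @param counts named positional count vector (from
#'   [hexamer_distribution()]).
#' @param n_contexts number of contexts behind the counts.
#' @param signal_window inclusive start-position range of the signal
#'   window (default -30..-11: a motif whose body lies within -25..-10
#'   starts there... the window covers hexamer start positions).
#' @param background_window inclusive start-position range of the
#'   background window.
#' @param threshold minimum score for a signal call.
#' @param min_total_frac minimum total occurrences as a fraction of
#'   contexts.
#' @return list: score, is_signal, peak_pos (start-position mode of the
#'   distribution; smallest on ties), total.
#' @export
peak_score <- function(counts, n_contexts,
                       signal_window = c(-30L, -11L),
                       background_window = c(20L, 95L),
                       threshold = 3.0, min_total_frac = 0.005) {
  if (signal_window[1] <= background_window[2] &&
      background_window[1] <= signal_window[2]) {
    stop("signal and background windows must not overlap")
  }
  pos <- as.integer(names(counts))
  sig <- counts[pos >= signal_window[1] & pos <= signal_window[2]]
  bg <- counts[pos >= background_window[1] & pos <= background_window[2]]
  if (!length(sig) || !length(bg)) stop("windows outside count positions")
  mean_sig <- mean(sig)
  mean_bg <- max(mean(bg), 0.5)
  score <- mean_sig / mean_bg
  total <- sum(counts)
  peak_pos <- pos[which.max(counts)]
  list(score = score,
       is_signal = score >= threshold && total >= min_total_frac * n_contexts,
       peak_pos = peak_pos, total = total)
}

#' Assign a PAS motif to each context
#'
#' Scans the upstream search window (hexamer start positions
#' `search_window[1]..search_window[2]`, keeping the whole motif within
#' the upstream region) for the motifs in hierarchy order; the first
#' motif in the hierarchy with at least one occurrence wins, and among its
#' occurrences the most 3' (closest to the cleavage site) is recorded.
#' Contexts with no motif in the window are assigned "none".
#'
#' @param contexts a `site_contexts` object.
#' @param motif_hierarchy RNA hexamers in precedence order.
#' @param search_window inclusive hexamer start-position range (default
#'   -40..-6: the motif body stays within the 40 nt upstream of the
#'   cleavage site).
#' @return data frame: context_id, motif (RNA, or "none"), start_idx,
#'   rank.
#' @export
assign_pas <- function(contexts, motif_hierarchy = pas_motifs("RNA"),
                       search_window = c(-40L, -6L)) {
  f <- contexts$flank
  lo <- search_window[1]; hi <- search_window[2]
  if (lo < -f || hi + 5L > f) stop("search window exceeds the context")
  sub <- substr(contexts$seq, f + 1L + lo, f + 1L + hi + 5L)
  n <- length(sub)
  motif <- rep("none", n)
  start_idx <- rep(NA_integer_, n)
  rank <- rep(NA_integer_, n)
  todo <- seq_len(n)
  for (r in seq_along(motif_hierarchy)) {
    if (!length(todo)) break
    m <- gregexpr(motif_hierarchy[r], sub[todo], fixed = TRUE)
    last <- vapply(m, function(mm) if (mm[1] == -1L) NA_integer_ else
      max(mm), integer(1))
    hit <- !is.na(last)
    if (any(hit)) {
      ix <- todo[hit]
      motif[ix] <- motif_hierarchy[r]
      start_idx[ix] <- lo + last[hit] - 1L
      rank[ix] <- r
      todo <- todo[!hit]
    }
  }
  data.frame(context_id = contexts$ids, motif = motif,
             start_idx = start_idx, rank = rank, stringsAsFactors = FALSE)
}

#' PAS motif frequency table
#'
#' Percentages of contexts assigned to each motif (plus "none"), in
#' hierarchy order; percentages are rounded to two decimals and sum to
#' 100 within rounding error.
#'
#' @param assignments data frame from [assign_pas()].
#' @param motif_hierarchy RNA hexamers in reporting order.
#' @return data frame: motif (RNA), motif_dna, count, percent.
#' @export
pas_frequency_table <- function(assignments,
                                motif_hierarchy = pas_motifs("RNA")) {
  if (nrow(assignments) == 0L) stop("no assignments supplied")
  levs <- c(motif_hierarchy, "none")
  counts <- table(factor(assignments$motif, levels = levs))
  pct <- round(100 * as.numeric(counts) / nrow(assignments), 2)
  data.frame(motif = levs, motif_dna = c(rna_to_dna(motif_hierarchy), "none"),
             count = as.integer(counts), percent = pct,
             stringsAsFactors = FALSE)
}

#' Write a positional profile as TSV (position x symbol)
#'
#' @param profile a `positional_profile`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(position = profile$positions,
                   t(profile$freq), check.names = FALSE)
  write_tsv(df, path)
}
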