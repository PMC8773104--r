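#' Whole-read quality filter
#'
#' Keeps a read iff at least `min_fraction` of its bases have Phred
#' quality >= `q_threshold` (boundary inclusive on both the quality and
#' the fraction). FASTA input without qualities bypasses this stage.
#'
#' @param qual character vector of Phred+33 quality strings.
#' @param seq character vector of read sequences (for the length check);
#'   `NULL` skips the consistency check.
#' @param q_threshold minimum per-base Phred quality.
#' @param min_fraction minimum fraction of bases meeting the threshold.
#' @param read_id optional ids used in error messages.
#' @return logical vector: `TRUE` = keep.
#' @export
quality_filter <- function(qual, seq = NULL, q_threshold = 20L,
                           min_fraction = 0.8, read_id = NULL) {
  if (!is.null(seq) && any(bad <- nchar(qual) != nchar(seq))) {
    id <- if (!is.null(read_id)) read_id[which(bad)[1]] else
      as.character(which(bad)[1])
    stop("malformed record: sequence/quality length mismatch for read ", id)
  }
  thr_char <- rawToChar(as.raw(33L + q_threshold))
  # count bases at or above the threshold character (Phred+33 is monotone)
  n_ok <- vapply(qual, function(q) {
    sum(utf8ToInt(q) >= utf8ToInt(thr_char))
  }, integer(1), USE.NAMES = FALSE)
  len <- nchar(qual)
  len > 0L & n_ok / pmax(len, 1L) >= min_fraction
}

#' Clip an adapter from reads
#'
#' Removes the first exact occurrence of the adapter and everything 3' of
#' it. With `adapter = NULL` this is the identity.
#'
#' @param seq character vector of read sequences.
#' @param adapter adapter sequence (exact match) or `NULL`.
#' @return character vector of clipped sequences (possibly empty strings,
#'   left for the downstream length filter to discard).
#' @export
clip_adapter <- function(seq, adapter = NULL) {
  if (is.null(adapter) || !nzchar(adapter)) return(seq)
  at <- regexpr(adapter, seq, fixed = TRUE)
  hit <- at > 0L
  seq[hit] <- substr(seq[hit], 1L, at[hit] - 1L)
  seq
}

#' Detect terminal poly(A)/poly(T) tails
#'
#' Measures the maximal uninterrupted run of A at the 3' end and of T at
#' the 5' end of each read (N breaks a run and never counts). A read has a
#' tail iff either run is at least `min_run` nt; when both qualify the
#' longer run wins, with exact ties resolved in favour of the 3'-A run
#' (the canonical library orientation). A 3'-A tail means the read is
#' already sense; a 5'-T tail means the read is the reverse complement of
#' the sense transcript.
#'
#' @param seq character vector of uppercase ACGTN sequences.
#' @param min_run minimum qualifying run length (nt).
#' @return data frame with one row per read: has_tail, side ("3p"/"5p"),
#'   base ("A"/"T"), run_length, orientation ("sense"/"antisense").
#'   Non-qualifying reads have has_tail = FALSE and NA calls.
#' @export
detect_tail <- function(seq, min_run = 10L) {
  n <- length(seq)
  a3 <- integer(n); t5 <- integer(n)
  m <- regexpr("A+$", seq)
  hit <- m > 0L
  a3[hit] <- attr(m, "match.length")[hit]
  m <- regexpr("^T+", seq)
  hit <- m > 0L
  t5[hit] <- attr(m, "match.length")[hit]
  a_ok <- a3 >= min_run
  t_ok <- t5 >= min_run
  use_a <- a_ok & (!t_ok | a3 >= t5)    # ties prefer the 3'-A tail
  use_t <- t_ok & !use_a
  has <- use_a | use_t
  data.frame(
    has_tail = has,
    side = ifelse(use_a, "3p", ifelse(use_t, "5p", NA_character_)),
    base = ifelse(use_a, "A", ifelse(use_t, "T", NA_character_)),
    run_length = ifelse(use_a, a3, ifelse(use_t, t5, NA_integer_)),
    orientation = ifelse(use_a, "sense",
                         ifelse(use_t, "antisense", NA_character_)),
    stringsAsFactors = FALSE)
}

#' Trim the tail and orient reads to the sense strand
#'
#' Removes the full called run; antisense reads (5'-T tails) are
#' reverse-complemented (and their qualities reversed) so that every
#' emitted read's 3' end abuts the cleavage site. Reads shorter than
#' `min_mappable` after trimming are discarded.
#'
#' @param seq character vector of read sequences.
#' @param tails data frame from [detect_tail()] (same order).
#' @param qual optional Phred+33 quality strings, trimmed and reversed
#'   alongside.
#' @param min_mappable minimum post-trim length retained (nt).
#' @return data frame of retained reads: idx (input row), seq, qual (NA if
#'   not supplied), plus a `n_too_short` attribute with the discarded
#'   count.
#' @export
trim_and_orient <- function(seq, tails, qual = NULL, min_mappable = 20L) {
  keep0 <- which(tails$has_tail)
  s <- seq[keep0]
  tl <- tails[keep0, , drop = FALSE]
  len <- nchar(s)
  sense <- tl$orientation == "sense"
  out_seq <- character(length(s))
  out_seq[sense] <- substr(s[sense], 1L, len[sense] - tl$run_length[sense])
  out_seq[!sense] <- revcomp(substr(s[!sense], tl$run_length[!sense] + 1L,
                                    len[!sense]))
  out_qual <- rep(NA_character_, length(s))
  if (!is.null(qual)) {
    q <- qual[keep0]
    out_qual[sense] <- substr(q[sense], 1L, len[sense] -
                                tl$run_length[sense])
    anti <- which(!sense)
    out_qual[anti] <- vapply(anti, function(i) {
      paste(rev(strsplit(substr(q[i], tl$run_length[i] + 1L, len[i]),
                         "")[[1]]), collapse = "")
    }, character(1))
  }
  long_enough <- nchar(out_seq) >= min_mappable
  res <- data.frame(idx = keep0[long_enough], seq = out_seq[long_enough],
                    qual = out_qual[long_enough], stringsAsFactors = FALSE)
  attr(res, "n_too_short") <- sum(!long_enough)
  res
}

#' Full read-processing stage
#'
#' Quality filter (FASTQ input only), adapter clipping, tail detection and
#' trim/orientation, with per-stage counts.
#'
#' @param reads data frame with read_id, seq and optionally qual columns
#'   (see [read_fastq()]); FASTA-derived input may omit qual.
#' @param adapter optional adapter sequence.
#' @param q_threshold,min_fraction quality-filter parameters.
#' @param min_run minimum tail run length (nt).
#' @param min_mappable minimum post-trim length (nt).
#' @return list: `reads` (data frame read_id, seq, qual of oriented
#'   trimmed reads), `tails` (per-emitted-read tail calls: read_id, side,
#'   base, run_length, orientation) and `counts` (named vector: input,
#'   quality_discarded, no_tail, too_short, emitted).
#' @export
process_reads <- function(reads, adapter = NULL, q_threshold = 20L,
                          min_fraction = 0.8, min_run = 10L,
                          min_mappable = 20L) {
  n_input <- nrow(reads)
  has_qual <- "qual" %in% names(reads) && !all(is.na(reads$qual))
  if (has_qual) {
    keep <- quality_filter(reads$qual, reads$seq, q_threshold, min_fraction,
                           reads$read_id)
    reads <- reads[keep, , drop = FALSE]
  }
  n_qc <- n_input - nrow(reads)
  reads$seq <- clip_adapter(reads$seq, adapter)
  tails <- detect_tail(reads$seq, min_run)
  n_no_tail <- sum(!tails$has_tail)
  trimmed <- trim_and_orient(reads$seq, tails,
                             if (has_qual) reads$qual else NULL,
                             min_mappable)
  n_too_short <- attr(trimmed, "n_too_short")
  out <- data.frame(read_id = reads$read_id[trimmed$idx], seq = trimmed$seq,
                    qual = trimmed$qual, stringsAsFactors = FALSE)
  tl <- tails[trimmed$idx, , drop = FALSE]
  tail_tab <- data.frame(read_id = out$read_id, side = tl$side,
                         base = tl$base, run_length = tl$run_length,
                         orientation = tl$orientation,
                         stringsAsFactors = FALSE)
  list(reads = out, tails = tail_tab,
       counts = c(input = n_input, quality_discarded = n_qc,
                  no_tail = n_no_tail, too_short = n_too_short,
                  emitted = nrow(out)))
}
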