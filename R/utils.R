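#' @import methods
#' @importFrom stats rbinom rnorm rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

# Coordinate conventions used throughout the package
# --------------------------------------------------
# All internal coordinates are 0-based. A cleavage site `p` is a between-base
# coordinate: the index of the first genomic base NOT included in the
# transcript. On the + strand the last transcribed base is p-1 and the first
# downstream base is p; on the - strand the last transcribed base is p and the
# first downstream base is p-1 (transcription runs towards decreasing
# coordinates). GFF3 and SAM are converted to/from 1-based at the boundary.

#' Normalize a genome to a named character vector
#'
#' Accepts a `Biostrings::DNAStringSet`, a named character vector, or a path
#' to a FASTA file. Plain character storage is used internally because the
#' pipeline does a large number of substring extractions.
#'
#' @param genome genome in any accepted representation.
#' @return named character vector, one element per chromosome, uppercase.
#' @export
as_genome_strings <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(toupper(out))
  }
  if (is.character(genome)) {
    if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
      stop("genome character vector must be named by chromosome")
    }
    return(toupper(genome))
  }
  stop("unsupported genome representation: ", class(genome)[1])
}

#' Reverse-complement a vector of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Extract 0-based half-open [start0, end0) substrings from one chromosome
# string; callers guarantee bounds.
substr0 <- function(chrom_seq, start0, end0) {
  substring(chrom_seq, start0 + 1L, end0)
}

#' Sense-strand genomic window around a cleavage site
#'
#' Returns the sense-strand sequence covering context indices
#' `from_idx..to_idx` (cleavage-site coordinates, index 0 = first base
#' downstream of cleavage). Windows truncated at chromosome ends are padded
#' with `pad`.
#'
#' @param chrom_seq chromosome sequence (single string).
#' @param pos 0-based between-base cleavage position.
#' @param strand "+" or "-".
#' @param from_idx,to_idx inclusive context index range.
#' @param pad single padding character for out-of-chromosome positions.
#' @return single string of length `to_idx - from_idx + 1`.
#' @export
sense_window <- function(chrom_seq, pos, strand, from_idx, to_idx, pad = "-") {
  n <- nchar(chrom_seq)
  if (strand == "+") {
    g0 <- pos + from_idx          # genomic base of first index
    g1 <- pos + to_idx
    lo <- max(g0, 0L); hi <- min(g1, n - 1L)
    core <- if (lo > hi) "" else substr0(chrom_seq, lo, hi + 1L)
    left <- max(0L, lo - g0); right <- max(0L, g1 - hi)
  } else {
    # index i maps to genomic base pos - 1 - i (complemented)
    g0 <- pos - 1L - to_idx       # smallest genomic coordinate in window
    g1 <- pos - 1L - from_idx
    lo <- max(g0, 0L); hi <- min(g1, n - 1L)
    core <- if (lo > hi) "" else revcomp(substr0(chrom_seq, lo, hi + 1L))
    # truncation on the genomic left end pads the downstream (high-index) side
    left <- max(0L, g1 - hi); right <- max(0L, lo - g0)
  }
  paste0(strrep(pad, left), core, strrep(pad, right))
}

# Write a sense-strand string `s` into the genome so that it occupies context
# indices start_idx .. start_idx + nchar(s) - 1 around (pos, strand).
# Returns the modified chromosome string, or NULL if out of bounds.
write_sense <- function(chrom_seq, pos, strand, start_idx, s) {
  L <- nchar(s)
  n <- nchar(chrom_seq)
  if (strand == "+") {
    g0 <- pos + start_idx
    g1 <- g0 + L - 1L
    if (g0 < 0L || g1 >= n) return(NULL)
    substr(chrom_seq, g0 + 1L, g1 + 1L) <- s
  } else {
    g1 <- pos - 1L - start_idx         # genomic base of first char (highest)
    g0 <- g1 - L + 1L
    if (g0 < 0L || g1 >= n) return(NULL)
    substr(chrom_seq, g0 + 1L, g1 + 1L) <- revcomp(s)
  }
  chrom_seq
}

# Genomic footprint [start0, end0) of a sense-strand element at context
# indices start_idx .. start_idx+L-1 around (pos, strand).
sense_footprint <- function(pos, strand, start_idx, L) {
  if (strand == "+") c(pos + start_idx, pos + start_idx + L)
  else c(pos - start_idx - L, pos - start_idx)
}

#' Convert DNA to the RNA reporting alphabet
#' @param x character vector of DNA strings.
#' @return character vector with T replaced by U.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' Convert RNA to DNA
#' @param x character vector of RNA strings.
#' @return character vector with U replaced by T.
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# deterministic TSV writers (byte-stable across runs)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

# Length of the longest run of `base` in each string (0 if absent).
longest_run <- function(x, base) {
  m <- gregexpr(paste0(base, "+"), x)
  vapply(m, function(mm) {
    if (mm[1] == -1L) 0L else max(attr(mm, "match.length"))
  }, integer(1))
}
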