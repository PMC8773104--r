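# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths of the package (regex run
# matching, Aho-Corasick dictionaries, vectorized chaining): they walk
# characters and enumerate pairs.

# character-walk tail oracle: longest terminal runs via rle
oracle_tail <- function(seq, min_run = 10L) {
  chars <- strsplit(seq, "")[[1]]
  if (!length(chars)) {
    return(list(has_tail = FALSE, side = NA, base = NA, run_length = NA))
  }
  r <- rle(chars)
  t5 <- if (r$values[1] == "T") r$lengths[1] else 0L
  a3 <- if (r$values[length(r$values)] == "A") r$lengths[length(r$values)]
        else 0L
  a_ok <- a3 >= min_run; t_ok <- t5 >= min_run
  if (!a_ok && !t_ok) {
    return(list(has_tail = FALSE, side = NA, base = NA, run_length = NA))
  }
  if (a_ok && (!t_ok || a3 >= t5)) {
    list(has_tail = TRUE, side = "3p", base = "A", run_length = a3)
  } else {
    list(has_tail = TRUE, side = "5p", base = "T", run_length = t5)
  }
}

# run-length oracle for the internal-priming window decision
oracle_has_a_run <- function(window, min_run = 8L) {
  chars <- strsplit(window, "")[[1]]
  if (!length(chars)) return(FALSE)
  r <- rle(chars)
  any(r$values == "A" & r$lengths >= min_run)
}

# substring-dictionary oracle for hexamer positional counts
oracle_hexamer_counts <- function(contexts) {
  f <- contexts$flank
  starts <- seq(-f, f - 5L)
  counts <- list()
  for (s in contexts$seq) {
    for (j in seq_along(starts)) {
      h <- substr(s, j, j + 5L)
      if (grepl("[^ACGU]", h)) next
      key <- paste(h, starts[j])
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  counts
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive pairwise-distance partition oracle: connected components of
# the graph joining same-chromosome/strand sites at distance <= max_gap
oracle_partition <- function(sites, max_gap = 20L) {
  n <- nrow(sites)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (sites$chrom[i] == sites$chrom[j] &&
            sites$strand[i] == sites$strand[j] &&
            abs(sites$pos[i] - sites$pos[j]) <= max_gap &&
            comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# canonical form of a partition for comparison: sorted site keys per group
partition_signature <- function(sites, grouping) {
  key <- paste(sites$chrom, sites$strand, sites$pos)
  unname(sort(vapply(split(key, grouping),
                     function(k) paste(sort(k), collapse = "|"),
                     character(1))))
}
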