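# Independent oracles, deliberately written without reference to the
# package's implementation paths.

# Full-matrix dynamic-programming Levenshtein distance.
lev_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av)
  m <- length(bv)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L,
                               d[i, j] + (av[i] != bv[j]))
    }
  }
  d[n + 1L, m + 1L]
}

# Benjamini-Hochberg step-up, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force sliding-window Hamming scan: best full-length match position
# of `pattern` in `subject` (substitutions only), or NA.
hamming_scan_oracle <- function(subject, pattern) {
  sv <- strsplit(subject, "")[[1L]]
  pv <- strsplit(pattern, "")[[1L]]
  np <- length(pv)
  last <- length(sv) - np + 1L
  if (last < 1L) return(list(start = NA_integer_, mismatches = NA_integer_))
  mm <- vapply(seq_len(last), function(s)
    sum(sv[s:(s + np - 1L)] != pv), 0L)
  list(start = which.min(mm), mismatches = min(mm))
}

# Tiny fixed reference used across tests: well-separated 20-nt uptags.
tiny_reference <- function() {
  barcode_reference(
    strain_id = c("sA", "sB", "sC"),
    gene = c("YAL001C", "YBL002W", "YCL003C"),
    uptag = c("ACGTACGTACGTACGTACGT",
              "TTTTCCCCGGGGAAAATTTT",
              "GACTGACTGACTGACTGACT"))
}

# Write a FASTQ file from bare sequences (constant quality).
write_fastq <- function(seqs, path) {
  qual <- strrep("I", nchar(seqs))
  lines <- as.vector(rbind(sprintf("@read_%d", seq_along(seqs)),
                           seqs, "+", qual))
  writeLines(lines, path)
  path
}

mutate_one_base <- function(seq, pos, to) {
  substr(seq, pos, pos) <- to
  seq
}
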