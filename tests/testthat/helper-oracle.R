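# Independent brute-force Smith-Waterman (affine gaps, gap of length k
# costs open + k * ext), written directly from the recurrences and kept
# free of the package's C++ path. Used as the oracle for translated-search
# scores.
oracle_sw <- function(q, s, submat, gap_open, gap_ext) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  m <- length(qv)
  n <- length(sv)
  H <- matrix(0, m + 1, n + 1)
  X <- matrix(-Inf, m + 1, n + 1)
  Y <- matrix(-Inf, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      X[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_ext,
                             X[i + 1, j] - gap_ext)
      Y[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_ext,
                             Y[i, j + 1] - gap_ext)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + submat[qv[i], sv[j]],
                             X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  max(H)
}

# best translated-search score over all six frames of a contig, by brute
# force: translate each frame with the package's published frame rule and
# run the oracle DP
oracle_translated_best <- function(query, contig, submat, gap_open,
                                   gap_ext) {
  best <- 0
  for (fr in c(1, 2, 3, -1, -2, -3)) {
    s <- if (fr > 0) contig else revcomp(contig)
    f <- abs(fr)
    if (nchar(s) < f + 2) next
    prot <- suppressWarnings(translate_cds(substr(s, f, nchar(s))))
    if (!nzchar(prot)) next
    best <- max(best, oracle_sw(query, prot, submat, gap_open, gap_ext))
  }
  best
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
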