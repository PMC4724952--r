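# helper: back-translate a protein with fixed codons (table 6 compatible)
back_translate <- function(prot) {
  tab <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
           Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
           L = "TTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
           S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")
  paste(tab[strsplit(prot, "")[[1]]], collapse = "")
}

test_that("an exact back-translation aligns cleanly with full coverage", {
  set.seed(51)
  q <- random_protein(60)
  cds <- back_translate(q)
  al <- align_protein_to_dna(q, cds)
  expect_equal(al$strand, "+")
  expect_equal(al$coverage, 1)
  expect_equal(length(al$stop_positions), 0L)
  expect_equal(nrow(al$frameshift_ops), 0L)
  expect_equal(al$region_start, 1L)
  expect_equal(al$region_end, nchar(cds))
  # the reverse complement aligns on the minus strand at the same spot
  al2 <- align_protein_to_dna(q, revcomp(cds))
  expect_equal(al2$strand, "-")
  expect_equal(al2$score, al$score)
  expect_equal(al2$region_start, 1L)
  expect_equal(al2$region_end, nchar(cds))
})

test_that("a single 1-nt insertion is recovered as one +1 frameshift", {
  set.seed(52)
  q <- random_protein(60)
  cds <- back_translate(q)
  mut <- paste0(substr(cds, 1, 90), "G", substr(cds, 91, nchar(cds)))
  al <- align_protein_to_dna(q, mut)
  expect_equal(nrow(al$frameshift_ops), 1L)
  expect_equal(al$frameshift_ops$codon, 31L)
  expect_equal(al$frameshift_ops$shift, 1L)
  expect_equal(al$coverage, 1)
  # a deletion is a -1 frameshift
  mut2 <- paste0(substr(cds, 1, 90), substr(cds, 92, nchar(cds)))
  al2 <- align_protein_to_dna(q, mut2)
  expect_equal(al2$frameshift_ops$shift, -1L)
  expect_equal(nrow(al2$frameshift_ops), 1L)
})

test_that("in-frame TGA records a stop while TAA aligns as glutamine", {
  set.seed(53)
  q <- random_protein(60)
  cds <- back_translate(q)
  substr(cds, 28, 30) <- "TGA"  # codon 10
  al <- align_protein_to_dna(q, cds)
  expect_equal(al$stop_positions, 10L)
  # TAA is Q under table 6: no stop recorded
  q2 <- paste0(substr(q, 1, 9), "Q", substr(q, 11, 60))
  cds2 <- back_translate(q2)
  substr(cds2, 28, 30) <- "TAA"
  al2 <- align_protein_to_dna(q2, cds2)
  expect_equal(length(al2$stop_positions), 0L)
  expect_equal(al2$coverage, 1)
})

test_that("premature-stop calls exclude a terminal stop", {
  cds <- list(stop_positions = c(60L), q_end = 60L,
              frameshift_ops = data.frame(codon = integer(0),
                                          shift = integer(0)))
  call <- call_integrity(cds)
  expect_false(call$has_premature_stop)
  expect_false(call$has_frameshift)
  cds$stop_positions <- c(10L, 60L)
  expect_true(call_integrity(cds)$has_premature_stop)
  cds$frameshift_ops <- data.frame(codon = 5L, shift = 1L)
  expect_true(call_integrity(cds)$has_frameshift)
})

test_that("repair restores frame, masks stops, and is idempotent", {
  set.seed(54)
  q <- random_protein(60)
  cds <- back_translate(q)
  al <- align_protein_to_dna(q, cds)
  expect_equal(repair_sequence(al, cds), cds)
  # one insertion and one stop: repaired length equals the template
  mut <- cds
  substr(mut, 28, 30) <- "TGA"
  mut <- paste0(substr(mut, 1, 90), "G", substr(mut, 91, nchar(mut)))
  al2 <- align_protein_to_dna(q, mut)
  rep2 <- repair_sequence(al2, mut)
  expect_equal(nchar(rep2), nchar(cds))
  expect_equal(length(gregexpr("NNN", rep2, fixed = TRUE)[[1]]), 1L)
  # re-aligning the repaired sequence yields no frameshifts
  al3 <- align_protein_to_dna(q, rep2)
  expect_equal(nrow(al3$frameshift_ops), 0L)
  # low coverage refuses repair
  short <- list(coverage = 0.3)
  expect_error(repair_sequence(structure(short, class = "cds_alignment"),
                               cds), "50%")
})

test_that("the true region outscores shuffled regions", {
  set.seed(55)
  q <- random_protein(80)
  cds <- back_translate(q)
  true_score <- align_protein_to_dna(q, cds)$score
  for (k in 1:5) {
    shuf <- paste(sample(strsplit(cds, "")[[1]]), collapse = "")
    expect_gt(true_score, align_protein_to_dna(q, shuf)$score)
  }
})

test_that("stop profiles average per-copy indicators and find hotspots", {
  calls <- data.frame(
    q_start = rep(1L, 10), q_end = rep(100L, 10),
    stop_positions = c(rep("70", 8), "", "70;90"))
  prof <- stop_profile(calls, 100, hotspot_threshold = 0.10)
  expect_equal(prof$fraction[70], 0.9)
  expect_equal(prof$fraction[90], 0.1)
  expect_equal(prof$hotspots$residue[1], 70L)
  # linearity: profile equals the mean of indicator vectors
  ind <- sapply(seq_len(nrow(calls)), function(i) {
    v <- numeric(100)
    if (nzchar(calls$stop_positions[i])) {
      v[as.integer(strsplit(calls$stop_positions[i], ";")[[1]])] <- 1
    }
    v
  })
  expect_equal(prof$fraction, rowMeans(ind))
  # no stops, no hotspots
  prof0 <- stop_profile(data.frame(q_start = 1L, q_end = 50L,
                                   stop_positions = ""), 50)
  expect_equal(nrow(prof0$hotspots), 0L)
  # denominator counts only copies covering the residue
  calls2 <- data.frame(q_start = c(1L, 60L), q_end = c(50L, 100L),
                       stop_positions = c("", "70"))
  prof2 <- stop_profile(calls2, 100)
  expect_equal(prof2$fraction[70], 1)
  expect_equal(prof2$n_covering[70], 1L)
})
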