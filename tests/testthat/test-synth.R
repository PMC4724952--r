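test_that("family templates carry the telomeric motif and family structure", {
  cfg <- synth_config(seed = 3)
  set.seed(3)
  tpl <- build_templates(cfg)
  expect_named(tpl, c("TBE1", "TBE2.1", "TBE2.2", "TBE3"))
  for (t in tpl) {
    expect_true(startsWith(t$tir_left, "CAAAACCCCAAAACCC"))
    expect_equal(t$tir_right, revcomp(t$tir_left))
    for (role in c("orf42", "orf22", "orf57")) {
      expect_false(grepl("\\*",
                         substr(translate_cds(t[[role]]), 1,
                                nchar(t[[role]]) / 3 - 1)))
    }
  }
  # determinism
  set.seed(3)
  tpl2 <- build_templates(cfg)
  expect_identical(tpl, tpl2)
  # zero between-family divergence collapses the ORFs
  cfg0 <- synth_config(seed = 3, between_family_divergence = 0)
  set.seed(3)
  tpl0 <- build_templates(cfg0)
  expect_identical(tpl0$TBE1$orf42, tpl0$TBE3$orf42)
  expect_identical(tpl0$`TBE2.1`$orf57, tpl0$`TBE2.2`$orf57)
})

test_that("incompatible divergence targets are rejected", {
  expect_error(synth_config(within_family_divergence = 0.3,
                            between_family_divergence = 0.2),
               "incompatible")
})

test_that("codon mutation respects omega and divergence", {
  set.seed(21)
  cds <- rand_cds <- paste(sample(setdiff(
    as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                    c("A","C","G","T"), paste0)), "TGA"),
    200, replace = TRUE), collapse = "")
  expect_identical(mutate_codon_sequence(cds, omega = 1, d = 0), cds)
  m0 <- mutate_codon_sequence(cds, omega = 0, d = 0.3)
  expect_identical(translate_cds(m0), translate_cds(cds))
  expect_false(identical(m0, cds))
  m1 <- mutate_codon_sequence(cds, omega = 0.5, d = 0.3)
  expect_false(grepl("\\*", translate_cds(m1)))
  expect_equal(nchar(m1), nchar(cds))
})

test_that("the mutation process is recovered by NG86 at neutrality", {
  set.seed(22)
  code <- genetic_code(6)
  om <- replicate(12, {
    anc <- paste(rep("ATGGCTAAAGTTCGT", 40), collapse = "")
    a <- mutate_codon_sequence(anc, omega = 1, d = 0.15)
    b <- mutate_codon_sequence(anc, omega = 1, d = 0.15)
    aln <- pairwise_codon_align(a, b)
    ng86(aln, code)$omega
  })
  expect_gt(stats::median(om), 0.75)
  expect_lt(stats::median(om), 1.3)
})

test_that("simulated genomes are deterministic with consistent truth", {
  cfg <- synth_config(seed = 13, n_contigs = 3, contig_length = 4e4,
                      copies_per_family = 2, partial_copy_fraction = 0)
  sim1 <- simulate_genome(cfg)
  sim2 <- simulate_genome(cfg)
  expect_identical(as.character(sim1$genome), as.character(sim2$genome))
  expect_identical(sim1$truth, sim2$truth)
  expect_equal(nrow(sim1$truth), 8L)
  expect_true(all(sim1$truth$completeness == "complete"))
  # truth intervals lie within contigs
  clen <- stats::setNames(Biostrings::width(sim1$genome),
                          names(sim1$genome))
  expect_true(all(sim1$truth$start >= 1 &
                    sim1$truth$end <= clen[sim1$truth$contig]))
  # excising between TSD copies reproduces the recorded TSD on both flanks
  for (i in seq_len(nrow(sim1$truth))) {
    r <- sim1$truth[i, ]
    ctg <- as.character(sim1$genome[[r$contig]])
    k <- nchar(r$tsd)
    expect_equal(substr(ctg, r$start - k, r$start - 1), r$tsd)
    expect_equal(substr(ctg, r$end + 1, r$end + k), r$tsd)
  }
  # truth ORFs translate with stops only at recorded positions (frameshift
  # free copies)
  ot <- sim1$truth_orfs
  for (i in seq_len(nrow(ot))) {
    if (nzchar(ot$frameshifts[i])) next
    s <- substr(as.character(sim1$genome[[ot$contig[i]]]),
                ot$start[i], ot$end[i])
    if (ot$strand[i] == "-") s <- revcomp(s)
    stops <- which(strsplit(translate_cds(s), "")[[1]] == "*")
    want <- if (nzchar(ot$stops[i])) {
      as.integer(strsplit(ot$stops[i], ";")[[1]])
    } else integer(0)
    expect_equal(stops, want)
  }
})

test_that("partial copies and stop hotspots hit their configured rates", {
  cfg <- synth_config(seed = 14, n_contigs = 10, contig_length = 5e4,
                      copies_per_family = 10, partial_copy_fraction = 0.3,
                      stop_hotspots = data.frame(family = "TBE3",
                                                 role = "orf42",
                                                 residue = 70,
                                                 fraction = 0.8))
  sim <- simulate_genome(cfg)
  pfrac <- mean(sim$truth$completeness == "partial")
  expect_gt(pfrac, 0.1)
  expect_lt(pfrac, 0.55)
  o <- sim$truth_orfs
  t3 <- o[o$family == "TBE3" & o$role == "orf42", ]
  hot <- mean(vapply(strsplit(t3$stops, ";"),
                     function(x) "70" %in% x, logical(1)))
  # binomial check: 0.8 +/- sampling at n ~ 10
  expect_gt(hot, 0.4)
  expect_lte(hot, 1)
})

test_that("contig fragmentation bisects elements and remaps coordinates", {
  cfg <- synth_config(seed = 15, n_contigs = 2, contig_length = 5e4,
                      copies_per_family = 1, partial_copy_fraction = 0,
                      fragmentation = 1)
  sim <- simulate_genome(cfg)
  expect_true(all(sim$truth$completeness == "bisected"))
  expect_gt(length(sim$genome), 2L)
  clen <- stats::setNames(Biostrings::width(sim$genome),
                          names(sim$genome))
  expect_true(all(sim$truth$end <= clen[sim$truth$contig]))
})

test_that("placement bias moves insertion points toward the track", {
  set.seed(31)
  ts <- c(10000L, 50000L)
  te <- c(20000L, 60000L)
  near_frac <- function(bias) {
    p <- sample_insertion_points(150, 2e5, ts, te, bias = bias,
                                 window = 500, min_sep = 10)
    mean(p >= ts[1] - 500 & p <= te[1] + 500 |
           p >= ts[2] - 500 & p <= te[2] + 500)
  }
  f1 <- near_frac(1)
  f2 <- near_frac(2)
  f4 <- near_frac(4)
  expect_lt(f1, f2 + 0.1)
  expect_lt(f2, f4 + 0.1)
  expect_gt(f4, f1)
})
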