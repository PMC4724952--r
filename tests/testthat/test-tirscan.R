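test_that("similarity examples behave under both conventions", {
  a <- paste(rep("ACGTTGCA", 10), collapse = "")
  expect_equal(tir_similarity(a, a), 100)
  expect_equal(tir_similarity("AAAA", "AAAT", type = "global"), 75)
})

test_that("the two published TBE2.2 TIR types are 92.5% similar", {
  tirs <- tir_consensus_seqs()
  expect_equal(tir_similarity(tirs[["TBE2.2a"]], tirs[["TBE2.2b"]]),
               92.5, tolerance = 0.005)
})

test_that("telomeric motif scanning separates canonical, variant, absent", {
  expect_equal(scan_telomeric("CAAAACCCCAAAACCCCTTAAT")$status, "canonical")
  expect_equal(scan_telomeric("CAAAACCCCAAAACCCTTTCAG")$status, "variant")
  expect_equal(scan_telomeric("GGGGGGGG")$status, "absent")
  tirs <- tir_consensus_seqs()
  expect_equal(scan_telomeric(tirs[["TBE1"]])$status, "canonical")
  expect_equal(scan_telomeric(tirs[["TBE2.1"]])$status, "variant")
  expect_equal(scan_telomeric(tirs[["TBE1"]])$offset, 1L)
})

test_that("a perfect implanted inverted repeat is recovered exactly", {
  set.seed(41)
  tir <- paste0("CAAAACCCCAAAACCCC", random_dna(61))  # 78 bp
  core <- random_dna(3000)
  elem <- paste0(tir, core, revcomp(tir))
  contig <- paste0(random_dna(600), elem, random_dna(600))
  g <- as_genome(c(c1 = contig))
  ann <- list(elements = data.frame(
    element_id = "el0001", contig = "c1",
    start = 601 + 90, end = 600 + nchar(elem) - 90,
    env_start = 601 + 90, env_end = 600 + nchar(elem) - 90,
    strand = "+", completeness = "complete", n_roles = 3L,
    family = NA_character_, stringsAsFactors = FALSE))
  class(ann) <- "tbe_annotation"
  ann <- detect_tir(ann, g)
  el <- ann$elements
  expect_equal(el$n_tirs, 2L)
  expect_equal(el$tir_similarity, 100)
  expect_equal(el$tir_lstart, 601L)
  expect_equal(el$tir_lend, 600L + 78L)
  expect_equal(el$tir_rstart, 600L + nchar(elem) - 77L)
  expect_equal(el$tir_rend, 600L + nchar(elem))
  # span extended to the TIR termini
  expect_equal(el$start, 601L)
  expect_equal(el$end, 600L + nchar(elem))
  # re-running on the extended span is idempotent
  ann2 <- detect_tir(ann, g)
  expect_equal(ann2$elements$tir_lstart, el$tir_lstart)
  expect_equal(ann2$elements$tir_rend, el$tir_rend)
})

test_that("an element at the contig edge yields at most one TIR side", {
  set.seed(42)
  tir <- paste0("CAAAACCCCAAAACCCC", random_dna(61))
  core <- random_dna(2000)
  contig <- paste0(core, revcomp(tir), random_dna(600))
  g <- as_genome(c(c1 = contig))
  ann <- list(elements = data.frame(
    element_id = "el0001", contig = "c1", start = 30,
    end = 2000, env_start = 30, env_end = 2000, strand = "+",
    completeness = "partial", n_roles = 2L, family = NA_character_,
    stringsAsFactors = FALSE))
  class(ann) <- "tbe_annotation"
  ann <- detect_tir(ann, g)
  expect_lte(ann$elements$n_tirs, 1L)
})

test_that("mutated TIR pairs report similarity near the expected identity", {
  set.seed(43)
  sims <- replicate(12, {
    tir <- paste0("CAAAACCCCAAAACCCC", random_dna(100))
    mut <- function(s, rate) {
      v <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(v)) < rate)
      for (i in hit) v[i] <- sample(setdiff(c("A","C","G","T"), v[i]), 1)
      paste(v, collapse = "")
    }
    elem <- paste0(mut(tir, 0.05), random_dna(2500), revcomp(mut(tir, 0.05)))
    g <- as_genome(c(c1 = paste0(random_dna(500), elem, random_dna(500))))
    ann <- list(elements = data.frame(
      element_id = "e", contig = "c1", start = 601, end = 500 + nchar(elem),
      env_start = 601, env_end = 500 + nchar(elem), strand = "+",
      completeness = "complete", n_roles = 3L, family = NA_character_,
      stringsAsFactors = FALSE))
    class(ann) <- "tbe_annotation"
    detect_tir(ann, g)$elements$tir_similarity
  })
  expect_true(all(!is.na(sims)))
  expect_gt(mean(sims), 85)
  expect_lt(mean(sims), 96)
})

test_that("target-site duplications are called from exact flank identity", {
  set.seed(44)
  elem <- paste0("CAAAACCCCAAAACCCC", random_dna(2000),
                 revcomp("CAAAACCCCAAAACCCC"))
  g <- as_genome(c(c1 = paste0(random_dna(300), "GC", "TA", elem, "TA",
                               "GG", random_dna(300))))
  ann <- list(elements = data.frame(
    element_id = "e", contig = "c1", start = 305, end = 304 + nchar(elem),
    env_start = 305, env_end = 304 + nchar(elem), strand = "+",
    completeness = "complete", n_roles = 3L, family = NA_character_,
    stringsAsFactors = FALSE))
  class(ann) <- "tbe_annotation"
  ann <- call_tsd(ann, g)
  expect_equal(ann$elements$tsd, "TA")
  # no shared flank k-mer: no call
  g2 <- as_genome(c(c1 = paste0(random_dna(300), "AATT", elem, "GGCC",
                                random_dna(300))))
  ann$elements$tsd <- NULL
  ann2 <- call_tsd(ann, g2)
  expect_true(is.na(ann2$elements$tsd))
})

test_that("distance modes break ties toward the smaller distance", {
  expect_equal(tbescan:::stat_mode(c(3, 3, 3, 41)),
               list(mode = 3L, fraction = 0.75))
  expect_equal(tbescan:::stat_mode(c(0, 0)), list(mode = 0L, fraction = 1))
  expect_equal(tbescan:::stat_mode(c(1, 2)), list(mode = 1L, fraction = 0.5))
})

test_that("greedy centroid clustering and consensus behave", {
  set.seed(45)
  base <- random_dna(80)
  noisy <- vapply(1:10, function(i) {
    v <- strsplit(base, "")[[1]]
    hit <- sample(80, 1)  # ~1.2% noise
    v[hit] <- sample(setdiff(c("A","C","G","T"), v[hit]), 1)
    paste(v, collapse = "")
  }, character(1))
  cl <- tir_consensus(noisy, identity_threshold = 0.9)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$consensus, base)
  # two diverged sets under a 0.9 threshold form two clusters
  other <- random_dna(80)
  cl2 <- tir_consensus(c(noisy[1:3], rep(other, 3)),
                       identity_threshold = 0.9)
  expect_equal(nrow(cl2), 2L)
  # a single sequence is its own consensus
  cl3 <- tir_consensus(base)
  expect_equal(cl3$consensus, base)
  expect_equal(cl3$n_members, 1L)
})
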