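mk_hits <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(query = r$role, role = r$role, contig = r$contig %||% "c1",
               start = r$start, end = r$end, strand = r$strand,
               frame = 1L, score = r$score %||% 500,
               bitscore = r$bitscore %||% 200, evalue = 1e-50,
               pident = 90, psim = 95, qcov = r$qcov %||% 0.9,
               stringsAsFactors = FALSE)
  }))
  df[order(df$contig, df$start), ]
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("three ORFs in proximity and orientation form a complete element", {
  h <- mk_hits(list(role = "orf42", start = 1000, end = 2099, strand = "+"),
               list(role = "orf22", start = 2400, end = 2999, strand = "-"),
               list(role = "orf57", start = 3100, end = 4399, strand = "+"))
  ann <- assemble_elements(h)
  expect_equal(nrow(ann$elements), 1L)
  expect_equal(ann$elements$completeness, "complete")
  expect_equal(ann$elements$strand, "+")
  expect_equal(ann$elements$env_start, 1000L)
  expect_equal(ann$elements$env_end, 4399L)
  # every hit assigned to exactly one element
  expect_true(all(!is.na(ann$hits$element_id)))
})

test_that("a gap beyond 1 kb splits the chain into partials", {
  h <- mk_hits(list(role = "orf42", start = 1000, end = 2099, strand = "+"),
               list(role = "orf22", start = 2400, end = 2999, strand = "-"),
               list(role = "orf57", start = 4200, end = 5499, strand = "+"))
  ann <- assemble_elements(h)
  expect_equal(nrow(ann$elements), 2L)
  expect_true(all(ann$elements$completeness == "partial"))
  expect_equal(sort(ann$elements$n_roles), c(1L, 2L))
})

test_that("a lone hit or wrong orientation yields partial elements", {
  ann <- assemble_elements(mk_hits(
    list(role = "orf22", start = 100, end = 700, strand = "-")))
  expect_equal(ann$elements$completeness, "partial")
  # 22kD on the same strand as the flanks violates the orientation rule
  h <- mk_hits(list(role = "orf42", start = 1000, end = 2099, strand = "+"),
               list(role = "orf22", start = 2400, end = 2999, strand = "+"),
               list(role = "orf57", start = 3100, end = 4399, strand = "+"))
  ann2 <- assemble_elements(h)
  expect_true(all(ann2$elements$completeness == "partial"))
})

test_that("minus-strand elements are recognized by the mirrored pattern", {
  h <- mk_hits(list(role = "orf57", start = 1000, end = 2299, strand = "-"),
               list(role = "orf22", start = 2400, end = 2999, strand = "+"),
               list(role = "orf42", start = 3100, end = 4199, strand = "-"))
  ann <- assemble_elements(h)
  expect_equal(ann$elements$completeness, "complete")
  expect_equal(ann$elements$strand, "-")
})

test_that("duplicate role calls keep the best bitscore and seed a partial", {
  h <- mk_hits(list(role = "orf42", start = 300, end = 700, strand = "+",
                    bitscore = 80),
               list(role = "orf42", start = 1000, end = 2099, strand = "+",
                    bitscore = 300),
               list(role = "orf22", start = 2400, end = 2999, strand = "-"),
               list(role = "orf57", start = 3100, end = 4399, strand = "+"))
  ann <- assemble_elements(h)
  expect_equal(sum(ann$elements$completeness == "complete"), 1L)
  expect_equal(sum(ann$elements$completeness == "partial"), 1L)
  comp <- ann$elements[ann$elements$completeness == "complete", ]
  expect_equal(comp$orf42_start, 1000L)
})

test_that("frameshift fragments of one ORF are merged before assembly", {
  h <- mk_hits(list(role = "orf42", start = 1000, end = 1500, strand = "+",
                    qcov = 0.45),
               list(role = "orf42", start = 1503, end = 2099, strand = "+",
                    qcov = 0.5),
               list(role = "orf22", start = 2400, end = 2999, strand = "-"),
               list(role = "orf57", start = 3100, end = 4399, strand = "+"))
  ann <- assemble_elements(h)
  expect_equal(nrow(ann$elements), 1L)
  expect_equal(ann$elements$completeness, "complete")
  expect_equal(ann$elements$orf42_start, 1000L)
  expect_equal(ann$elements$orf42_end, 2099L)
})

test_that("hit conservation holds on the small synthetic run", {
  rep <- small_run()
  expect_equal(sum(!is.na(rep$annotation$hits$element_id)),
               nrow(rep$annotation$hits))
})

test_that("contig-end flags follow the 500 bp window", {
  g <- as_genome(c(c1 = paste(rep("A", 100000), collapse = "")))
  h <- mk_hits(list(role = "orf42", start = 1000, end = 2099, strand = "+"),
               list(role = "orf22", start = 2400, end = 2999, strand = "-"),
               list(role = "orf57", start = 3100, end = 4399, strand = "+"),
               list(role = "orf22", start = 99300, end = 99800,
                    strand = "-"))
  ann <- flag_context(assemble_elements(h), g)
  el <- ann$elements
  expect_false(el$near_contig_end[el$completeness == "complete"])
  expect_true(el$near_contig_end[el$start == 99300])
  # an element spanning nearly the whole contig is near both ends
  g2 <- as_genome(c(c1 = paste(rep("A", 4500), collapse = "")))
  ann2 <- flag_context(assemble_elements(mk_hits(
    list(role = "orf42", start = 100, end = 4400, strand = "+"))), g2)
  expect_true(ann2$elements$near_contig_end)
})

test_that("the element table conserves counts and percentages", {
  rep <- small_run()
  tab <- element_table(rep$annotation)
  expect_equal(sum(tab$n_complete) + sum(tab$n_partial),
               nrow(rep$annotation$elements))
  expect_equal(sum(tab$pct_complete_bp), 100, tolerance = 1e-6)
  empty <- assemble_elements(mk_hits(
    list(role = "orf42", start = 1, end = 2, strand = "+"))[0, ])
  expect_equal(nrow(element_table(empty)), 0L)
})
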