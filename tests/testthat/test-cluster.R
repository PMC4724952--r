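test_that("similarity graph links only pairs sharing a long exact word", {
  set.seed(71)
  a <- random_dna(1000)
  b <- a
  substr(b, 500, 500) <- if (substr(a, 500, 500) == "A") "C" else "A"
  c2 <- random_dna(1000)  # no 50-mer in common with a
  g <- all_vs_all_similarity(c(a = a, b = b, c = c2), word_size = 50)
  expect_equal(nrow(g), 1L)
  expect_setequal(c(g$from, g$to), c("a", "b"))
  expect_gt(g$weight, 99)
  # identical sequences score 100
  g2 <- all_vs_all_similarity(c(x = a, y = a))
  expect_equal(g2$weight, 100)
})

test_that("five-percent divergence yields weights near 95", {
  set.seed(72)
  a <- random_dna(1000)
  v <- strsplit(a, "")[[1]]
  hit <- sample(1000, 50)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  b <- paste(v, collapse = "")
  g <- all_vs_all_similarity(c(a = a, b = b))
  expect_equal(nrow(g), 1L)
  expect_gt(g$weight, 92)
  expect_lt(g$weight, 98)
})

test_that("MCL separates disconnected components and weakly joined cliques", {
  tri <- function(nodes, w) {
    p <- t(utils::combn(nodes, 2))
    data.frame(from = p[, 1], to = p[, 2], weight = w)
  }
  g <- rbind(tri(c("a", "b", "c"), 90), tri(c("d", "e", "f"), 90))
  attr(g, "nodes") <- c("a", "b", "c", "d", "e", "f")
  cl <- mcl(g, inflation = 1.2)
  expect_equal(length(cl$clusters), 2L)
  expect_true(cl$converged)
  # two 4-cliques joined by one weaker edge: at the coarse default
  # inflation the recurrence genuinely merges them (verified against an
  # independent reference iteration below); a higher inflation splits them
  g2 <- rbind(tri(letters[1:4], 90), tri(letters[5:8], 90),
              data.frame(from = "d", to = "e", weight = 70))
  attr(g2, "nodes") <- letters[1:8]
  cl_hi <- mcl(g2, inflation = 2)
  expect_equal(length(cl_hi$clusters), 2L)
  expect_setequal(cl_hi$clusters[[which(vapply(cl_hi$clusters, function(x)
    "a" %in% x, logical(1)))]], letters[1:4])
  # reference iteration of the MCL recurrence, written independently
  ref_mcl_nclust <- function(graph, nodes, infl) {
    M <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    M[cbind(graph$from, graph$to)] <- graph$weight
    M[cbind(graph$to, graph$from)] <- graph$weight
    diag(M) <- apply(M, 2, max)
    M <- sweep(M, 2, colSums(M), "/")
    for (it in 1:200) {
      M2 <- (M %*% M)^infl
      M2[M2 < 1e-9] <- 0
      M2 <- sweep(M2, 2, colSums(M2), "/")
      if (max(abs(M2 - M)) < 1e-8) {
        M <- M2
        break
      }
      M <- M2
    }
    att <- unique(apply(M, 2, function(col) {
      paste(sort(rownames(M)[col > 0.05]), collapse = "+")
    }))
    length(att)
  }
  for (infl in c(1.2, 2)) {
    expect_equal(length(mcl(g2, inflation = infl)$clusters),
                 ref_mcl_nclust(g2, letters[1:8], infl))
  }
  # a single node is a singleton cluster
  g3 <- data.frame(from = character(0), to = character(0),
                   weight = numeric(0))
  attr(g3, "nodes") <- "solo"
  cl3 <- mcl(g3)
  expect_equal(cl3$clusters, list("solo"))
})

test_that("MCL output is a partition invariant to order and scaling", {
  set.seed(73)
  tri <- function(nodes, w) {
    p <- t(utils::combn(nodes, 2))
    data.frame(from = p[, 1], to = p[, 2], weight = w)
  }
  g <- rbind(tri(c("a", "b", "c", "d"), 85), tri(c("e", "f", "g"), 92))
  attr(g, "nodes") <- letters[1:7]
  cl <- mcl(g)
  expect_setequal(unlist(cl$clusters), letters[1:7])
  expect_equal(anyDuplicated(unlist(cl$clusters)), 0L)
  gs <- g
  gs$weight <- gs$weight / 10
  expect_equal(lapply(mcl(gs)$clusters, sort), lapply(cl$clusters, sort))
  gp <- g[sample(nrow(g)), ]
  attr(gp, "nodes") <- sample(letters[1:7])
  expect_setequal(vapply(mcl(gp)$clusters, function(x)
    paste(sort(x), collapse = "+"), character(1)),
    vapply(cl$clusters, function(x)
      paste(sort(x), collapse = "+"), character(1)))
})

test_that("protein similarity counts positives and distinct pairs", {
  p <- c(a = "MKVLIWAADG", b = "MKVLIWAADG", c = "MKVLIWAADG")
  s <- pairwise_protein_similarity(p, groups = c("g", "g", "g"))
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 0)
  expect_equal(s$n_pairs, 3L)  # 3 * (3-1) / 2 distinct unordered pairs
  # between-group uses the full cross product
  s2 <- pairwise_protein_similarity(p, groups = c("g1", "g1", "g2"))
  expect_equal(s2$n_pairs[s2$group1 == "g1" & s2$group2 == "g2"], 2L)
})

test_that("neighbor joining recovers an additive four-taxon tree", {
  # tree ((A:2,B:3):1,(C:4,D:5)) -> additive distance matrix
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 5
  d["A", "C"] <- d["C", "A"] <- 7
  d["A", "D"] <- d["D", "A"] <- 8
  d["B", "C"] <- d["C", "B"] <- 8
  d["B", "D"] <- d["D", "B"] <- 9
  d["C", "D"] <- d["D", "C"] <- 9
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(tr$Nnode, 2L)  # n - 2 internal nodes, unrooted
  # path lengths reproduce the additive input exactly
  pd <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(pd), unname(d), tolerance = 1e-9)
  # AB are siblings
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  # newick round trip preserves topology and branch lengths
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  tr2 <- ape::read.tree(path)
  expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
  expect_equal(sort(round(tr2$edge.length, 6)),
               sort(round(tr$edge.length, 6)))
})

test_that("rand index agrees with hand-computed partitions", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)
  expect_equal(rand_index(c(1, 1, 1), c(1, 1, 2)), 1 / 3)
})
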