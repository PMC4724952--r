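#' Extract element sequences from an annotation
#'
#' @param ann A `tbe_annotation`.
#' @param genome The genome.
#' @param completeness Which elements (`"complete"`, `"partial"` or
#'   `"all"`).
#' @return Named character vector (element id to sequence), oriented so the
#'   element 5' end comes first.
#' @export
element_sequences <- function(ann, genome, completeness = "complete") {
  el <- ann$elements
  if (completeness != "all") {
    el <- el[el$completeness == completeness, , drop = FALSE]
  }
  if (!nrow(el)) return(character(0))
  if (!is(genome, "DNAStringSet")) genome <- as_genome(genome)
  out <- vapply(seq_len(nrow(el)), function(i) {
    s <- substr(as.character(genome[[el$contig[i]]]), el$start[i], el$end[i])
    if (el$strand[i] == "-") revcomp(s) else s
  }, character(1))
  stats::setNames(out, el$element_id)
}

#' All-vs-all element similarity graph
#'
#' Edges connect sequence pairs sharing at least one exact common word of
#' `word_size` nt (the BLASTN `-word_size 50` semantics: diverged families
#' share no long exact word and get no edge). The edge weight is the percent
#' identity of a global alignment of windows extended `window` bp around
#' the first shared word.
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param word_size Exact-match anchor length (nt).
#' @param window Extension (bp) on each side of the anchor word.
#' @return Data frame (`from`, `to`, `weight`) of class
#'   `tbe_similarity_graph`; node names kept in `attr(, "nodes")`.
#' @export
all_vs_all_similarity <- function(seqs, word_size = 50, window = 600) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  n <- length(seqs)
  words <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < word_size) return(character(0))
    substring(s, 1:(L - word_size + 1L), word_size:L)
  })
  # first shared word per pair via a word -> (seq, pos) index
  tab <- data.frame(
    word = unlist(words, use.names = FALSE),
    seq = rep(seq_len(n), lengths(words)),
    pos = unlist(lapply(words, seq_along), use.names = FALSE))
  tab <- tab[tab$word %in% tab$word[duplicated(tab$word)], , drop = FALSE]
  edges <- list()
  seen <- character(0)
  if (nrow(tab)) {
    sp <- split(tab[c("seq", "pos")], tab$word)
    for (grp in sp) {
      us <- unique(grp$seq)
      if (length(us) < 2L) next
      for (a in seq_along(us)) {
        for (b in seq_len(a - 1L)) {
          i <- min(us[a], us[b])
          j <- max(us[a], us[b])
          key <- paste(i, j)
          if (key %in% seen) next
          seen <- c(seen, key)
          pi <- grp$pos[grp$seq == i][1L]
          pj <- grp$pos[grp$seq == j][1L]
          ai <- substr(seqs[i], max(1L, pi - window),
                       min(nchar(seqs[i]), pi + word_size + window))
          aj <- substr(seqs[j], max(1L, pj - window),
                       min(nchar(seqs[j]), pj + word_size + window))
          al <- nt_align(ai, aj, type = "global")
          edges[[key]] <- data.frame(
            from = names(seqs)[i], to = names(seqs)[j],
            weight = 100 * al$matches / al$columns,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  g <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), weight = numeric(0))
  rownames(g) <- NULL
  attr(g, "nodes") <- names(seqs)
  class(g) <- c("tbe_similarity_graph", class(g))
  g
}

#' Markov clustering (MCL)
#'
#' Adds self loops (weight = the node's maximum incident weight), column
#' normalizes to a stochastic matrix, then iterates expansion (matrix
#' squaring) and inflation (entry-wise power, re-normalization, pruning)
#' until the matrix change falls below `epsilon`. Clusters are read from the
#' attractor structure of the converged matrix; every node lands in exactly
#' one cluster.
#'
#' @param graph A `tbe_similarity_graph` (or data frame from/to/weight).
#' @param inflation Inflation exponent (> 1); the clustering granularity
#'   knob (default 1.2, coarse clusters).
#' @param max_iterations,convergence_epsilon,prune_threshold Iteration
#'   controls.
#' @return List of class `tbe_clusters`: `clusters` (list of node-name
#'   vectors, largest first), `membership` (named integer), `iterations`,
#'   `converged`.
#' @export
mcl <- function(graph, inflation = 1.2, max_iterations = 100,
                convergence_epsilon = 1e-6, prune_threshold = 1e-6) {
  stopifnot(inflation > 1)
  nodes <- attr(graph, "nodes")
  if (is.null(nodes)) nodes <- unique(c(graph$from, graph$to))
  n <- length(nodes)
  if (n == 0) stop("empty graph")
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph)) {
    M[cbind(graph$from, graph$to)] <- graph$weight
    M[cbind(graph$to, graph$from)] <- graph$weight
  }
  selfw <- apply(M, 2, max)
  selfw[selfw == 0] <- 1
  diag(M) <- selfw
  normalize <- function(m) sweep(m, 2, colSums(m), "/")
  M <- normalize(M)
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune_threshold] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < convergence_epsilon) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iterations, " iterations")
  }
  # union nodes attracted to shared rows
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (j in seq_len(n)) {
    att <- which(M[, j] > 0.1 * max(M[, j]))
    for (a in att) {
      ra <- find(a)
      rj <- find(j)
      if (ra != rj) parent[ra] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(nodes, roots)
  comp <- comp[order(-lengths(comp))]
  membership <- stats::setNames(rep(seq_along(comp), lengths(comp)),
                                unlist(comp))[nodes]
  structure(list(clusters = unname(comp), membership = membership,
                 iterations = it, converged = converged),
            class = "tbe_clusters")
}

# percent positives (substitution score > 0) over all alignment columns of
# a global protein alignment
protein_similarity <- function(a, b, submat = get_submat("BLOSUM62"),
                               gap_open = 11, gap_ext = 1) {
  al <- Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_ext, type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- !(p == "-" & s == "-")
  p <- p[keep]
  s <- s[keep]
  ok <- p != "-" & s != "-"
  pos <- sum(ok & submat[cbind(match(p, rownames(submat)),
                               match(s, rownames(submat)))] > 0,
             na.rm = TRUE)
  100 * pos / length(p)
}

#' Pairwise percent protein similarity within and between groups
#'
#' Global protein alignments; similarity is the percent of alignment
#' columns with a positive substitution score. Within-group statistics use
#' distinct unordered pairs only.
#'
#' @param proteins Named character vector of protein sequences.
#' @param groups Character/factor of group labels, aligned with `proteins`.
#' @param max_pairs Optional cap on sampled pairs per group pair (keeps
#'   large groups tractable); NULL for all pairs.
#' @return Data frame: group1, group2, n_pairs, mean, sd.
#' @export
pairwise_protein_similarity <- function(proteins, groups, max_pairs = NULL) {
  stopifnot(length(proteins) == length(groups), length(proteins) >= 1)
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  submat <- get_submat("BLOSUM62")
  out <- list()
  for (a in seq_along(gl)) {
    for (b in a:length(gl)) {
      ia <- which(groups == gl[a])
      ib <- which(groups == gl[b])
      prs <- if (a == b) {
        if (length(ia) < 2) matrix(integer(0), ncol = 2) else
          t(utils::combn(ia, 2))
      } else as.matrix(expand.grid(ia, ib))
      if (!is.null(max_pairs) && nrow(prs) > max_pairs) {
        prs <- prs[sample.int(nrow(prs), max_pairs), , drop = FALSE]
      }
      vals <- if (nrow(prs) == 0) numeric(0) else {
        apply(prs, 1, function(pr) {
          protein_similarity(proteins[[pr[1]]], proteins[[pr[2]]], submat)
        })
      }
      out[[length(out) + 1L]] <- data.frame(
        group1 = gl[a], group2 = gl[b], n_pairs = nrow(prs),
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) stats::sd(vals) else
          if (length(vals) == 1) 0 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via ape); for additive matrices the tree's
#' path lengths reproduce the input exactly.
#'
#' @param d Symmetric distance matrix (or `dist`) with >= 3 taxa.
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(m))) stop("distances must be finite")
  ape::nj(stats::as.dist(m))
}

#' Write a tree in newick format
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Rand index of two partitions
#'
#' @param a,b Cluster label vectors over the same items.
#' @return The Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  sum(same_a[up] == same_b[up]) / sum(up)
}

#' Cluster elements into families
#'
#' Main pass: Markov clustering of the whole-element similarity graph at
#' the configured inflation. Second pass: within each main cluster, the
#' 57kD coding regions are re-clustered with a shorter anchor word; a main
#' cluster whose 57kD genes split into well-populated subclusters is
#' subdivided (this is what separates the TBE2 subfamilies, whose 42kD and
#' 22kD genes are indistinguishable but whose 57kD genes are distinct).
#'
#' @param ann A `tbe_annotation`.
#' @param genome The genome.
#' @param inflation MCL inflation (default 1.2).
#' @param word_size Anchor word for whole elements (default 50).
#' @param word_size_57k Anchor word for the 57kD second pass (default 30;
#'   the 57kD gene is shorter than a whole element).
#' @param min_sub Minimum members for a 57kD subcluster to trigger a split.
#' @return List of class `tbe_families`: `membership` (element id to family
#'   label `fam1`, `fam2`, ... with `.1`/`.2` suffixes for split
#'   subfamilies), `main` and `sub` cluster objects.
#' @export
cluster_families <- function(ann, genome, inflation = 1.2, word_size = 50,
                             word_size_57k = 30, min_sub = 2) {
  seqs <- element_sequences(ann, genome, "complete")
  if (length(seqs) < 2) stop("need at least 2 complete elements")
  g <- all_vs_all_similarity(seqs, word_size = word_size)
  main <- mcl(g, inflation = inflation)
  el <- ann$elements
  membership <- stats::setNames(rep(NA_character_, length(seqs)),
                                names(seqs))
  sub_out <- list()
  for (ci in seq_along(main$clusters)) {
    ids <- main$clusters[[ci]]
    lab <- paste0("fam", ci)
    split_done <- FALSE
    if (length(ids) >= 2 * min_sub) {
      w <- el[match(ids, el$element_id), ]
      ok <- !is.na(w$orf57_start)
      if (sum(ok) >= 2 * min_sub) {
        s57 <- vapply(which(ok), function(i) {
          s <- substr(as.character(genome[[w$contig[i]]]),
                      w$orf57_start[i], w$orf57_end[i])
          if (w$orf57_strand[i] == "-") revcomp(s) else s
        }, character(1))
        names(s57) <- w$element_id[ok]
        g57 <- all_vs_all_similarity(s57, word_size = word_size_57k)
        sub <- mcl(g57, inflation = inflation)
        big <- sub$clusters[lengths(sub$clusters) >= min_sub]
        if (length(big) > 1) {
          for (si in seq_along(sub$clusters)) {
            membership[sub$clusters[[si]]] <-
              paste0(lab, ".", min(si, length(big)))
          }
          # members without a 57kD gene stay in the first subfamily
          membership[setdiff(ids, names(s57))] <- paste0(lab, ".1")
          split_done <- TRUE
          sub_out[[lab]] <- sub
        }
      }
    }
    if (!split_done) membership[ids] <- lab
  }
  structure(list(membership = membership, main = main, sub = sub_out),
            class = "tbe_families")
}

#' Apply family labels to an annotation
#'
#' @param ann A `tbe_annotation`.
#' @param families A `tbe_families` (or named character vector of labels).
#' @return The annotation with the `family` column filled for labelled
#'   elements (others stay NA / unclassified).
#' @export
apply_families <- function(ann, families) {
  mem <- if (is.list(families)) families$membership else families
  el <- ann$elements
  w <- match(el$element_id, names(mem))
  el$family <- ifelse(is.na(w), el$family, unname(mem[w]))
  ann$elements <- el
  ann
}
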