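#' Configuration for element assembly
#'
#' @param max_gap_bp Maximum gap (bp) between consecutive ORF hits of one
#'   element ("three ORFs in proximity, within 1 kb of each other").
#' @param contig_end_window_bp Window defining "near a contig end".
#' @param min_role_coverage Minimum query coverage for a role to count
#'   toward completeness; weaker hits still join partial elements.
#' @param merge_gap_bp Hits of the same role and strand closer than this are
#'   merged before assembly (frameshift fragments of one ORF).
#' @return A list of class `annotate_config`.
#' @export
annotate_config <- function(max_gap_bp = 1000, contig_end_window_bp = 500,
                            min_role_coverage = 0.3, merge_gap_bp = 100) {
  stopifnot(max_gap_bp > 0, contig_end_window_bp > 0,
            min_role_coverage > 0, merge_gap_bp > 0)
  structure(list(max_gap_bp = max_gap_bp,
                 contig_end_window_bp = contig_end_window_bp,
                 min_role_coverage = min_role_coverage,
                 merge_gap_bp = merge_gap_bp), class = "annotate_config")
}

# merge frameshift fragments: same contig, role and strand, gap < merge_gap
merge_role_hits <- function(hits, merge_gap) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$contig, hits$start), ]
  key <- paste(hits$contig, hits$role, hits$strand)
  out <- list()
  i <- 1L
  while (i <= nrow(hits)) {
    cur <- hits[i, ]
    j <- i + 1L
    while (j <= nrow(hits) && key[j] == key[i] &&
             hits$start[j] - cur$end - 1L < merge_gap) {
      nxt <- hits[j, ]
      w <- c(cur$qcov, nxt$qcov)
      cur$end <- max(cur$end, nxt$end)
      cur$score <- cur$score + nxt$score
      cur$bitscore <- cur$bitscore + nxt$bitscore
      cur$evalue <- min(cur$evalue, nxt$evalue)
      cur$pident <- sum(c(cur$pident, nxt$pident) * w) / sum(w)
      cur$psim <- sum(c(cur$psim, nxt$psim) * w) / sum(w)
      cur$qcov <- min(1, sum(w))
      j <- j + 1L
    }
    out[[length(out) + 1L]] <- cur
    i <- j
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

role_pattern <- list(
  `+` = list(roles = c("orf42", "orf22", "orf57"),
             strands = c("+", "-", "+")),
  `-` = list(roles = c("orf57", "orf22", "orf42"),
             strands = c("-", "+", "-")))

#' Assemble translated hits into TBE elements
#'
#' Implements the proximity-and-orientation rule: three ORF hits within
#' `max_gap_bp` of each other, in the order 42kD-22kD-57kD along the
#' element strand with the 22kD ORF inverted, form a complete element;
#' everything else groups into partial elements by the same proximity rule.
#' Every hit is assigned to exactly one element. When one role occurs twice
#' in a chain, the higher-bitscore hit stays and the other seeds a separate
#' partial (ties broken by leftmost start).
#'
#' @param hits Hit table from [search_protein()].
#' @param cfg An [annotate_config()].
#' @return A list of class `tbe_annotation` with `elements` (one row per
#'   element; `start`/`end` give the current span and `env_start`/`env_end`
#'   the ORF envelope) and `hits` (input hits plus `element_id`).
#' @export
assemble_elements <- function(hits, cfg = annotate_config()) {
  if (!nrow(hits)) {
    return(structure(list(elements = empty_elements(),
                          hits = cbind(hits, element_id = character(0)),
                          config = cfg), class = "tbe_annotation"))
  }
  hits <- merge_role_hits(hits, cfg$merge_gap_bp)
  hits$element_id <- NA_character_
  elements <- list()
  eid <- 0L
  new_id <- function() {
    eid <<- eid + 1L
    sprintf("el%04d", eid)
  }
  for (ctg in unique(hits$contig)) {
    idx <- which(hits$contig == ctg)
    idx <- idx[order(hits$start[idx], -hits$bitscore[idx])]
    # chains of hits linked by gaps <= max_gap
    gaps <- diff(hits$start[idx]) -
      (hits$end[idx[-length(idx)]] - hits$start[idx[-length(idx)]]) - 1L
    chain_id <- cumsum(c(1L, as.integer(gaps > cfg$max_gap_bp)))
    for (ch in unique(chain_id)) {
      cidx <- idx[chain_id == ch]
      # consecutive hits of the same role and strand are competing calls
      # for one ORF: the higher bitscore stays, the other seeds a partial
      # (adjacent elements never repeat a role on the same strand
      # consecutively, so patterns survive this)
      dup <- logical(length(cidx))
      if (length(cidx) > 1L) {
        for (w in seq_len(length(cidx) - 1L)) {
          a <- cidx[w]
          b <- cidx[w + 1L]
          if (hits$role[a] == hits$role[b] &&
              hits$strand[a] == hits$strand[b]) {
            loser <- if (hits$bitscore[b] > hits$bitscore[a]) a else b
            dup[match(loser, cidx)] <- TRUE
          }
        }
      }
      keep <- cidx[!dup]
      for (d in cidx[dup]) {
        id <- new_id()
        hits$element_id[d] <- id
        elements[[id]] <- make_element(hits[d, , drop = FALSE], id,
                                       "partial", cfg)
      }
      # pattern walk
      i <- 1L
      part <- integer(0)
      flush_partial <- function() {
        if (length(part)) {
          id <- new_id()
          hits$element_id[part] <<- id
          elements[[id]] <<- make_element(hits[part, , drop = FALSE], id,
                                          "partial", cfg)
        }
        part <<- integer(0)
      }
      while (i <= length(keep)) {
        matched <- FALSE
        if (i + 2L <= length(keep)) {
          trio <- keep[i:(i + 2L)]
          g1 <- hits$start[trio[2L]] - hits$end[trio[1L]] - 1L
          g2 <- hits$start[trio[3L]] - hits$end[trio[2L]] - 1L
          for (es in c("+", "-")) {
            pat <- role_pattern[[es]]
            if (identical(hits$role[trio], pat$roles) &&
                identical(hits$strand[trio], pat$strands) &&
                g1 <= cfg$max_gap_bp && g2 <= cfg$max_gap_bp &&
                all(hits$qcov[trio] >= cfg$min_role_coverage)) {
              flush_partial()
              id <- new_id()
              hits$element_id[trio] <- id
              elements[[id]] <- make_element(hits[trio, , drop = FALSE],
                                             id, "complete", cfg,
                                             strand = es)
              i <- i + 3L
              matched <- TRUE
              break
            }
          }
        }
        if (!matched) {
          h <- keep[i]
          if (length(part) &&
              (hits$role[h] %in% hits$role[part])) {
            flush_partial()
          }
          part <- c(part, h)
          i <- i + 1L
        }
      }
      flush_partial()
    }
  }
  el <- do.call(rbind, elements)
  el <- el[order(el$contig, el$start), ]
  rownames(el) <- NULL
  hits <- hits[order(hits$contig, hits$start), ]
  rownames(hits) <- NULL
  structure(list(elements = el, hits = hits, config = cfg),
            class = "tbe_annotation")
}

empty_elements <- function() {
  el <- data.frame(element_id = character(0), contig = character(0),
                   start = integer(0), end = integer(0),
                   env_start = integer(0), env_end = integer(0),
                   strand = character(0), completeness = character(0),
                   n_roles = integer(0), family = character(0),
                   stringsAsFactors = FALSE)
  for (role in c("orf42", "orf22", "orf57")) {
    el[[paste0(role, "_start")]] <- integer(0)
    el[[paste0(role, "_end")]] <- integer(0)
    el[[paste0(role, "_strand")]] <- character(0)
    el[[paste0(role, "_qcov")]] <- numeric(0)
    el[[paste0(role, "_psim")]] <- numeric(0)
  }
  el
}

make_element <- function(h, id, completeness, cfg, strand = NULL) {
  if (is.null(strand)) {
    # partials: orient by the strongest 42kD/57kD hit, else flip the 22kD
    b <- h[order(-h$bitscore), ]
    top <- b[1L, ]
    strand <- if (top$role == "orf22") {
      if (top$strand == "+") "-" else "+"
    } else top$strand
  }
  el <- data.frame(element_id = id, contig = h$contig[1L],
                   start = min(h$start), end = max(h$end),
                   env_start = min(h$start), env_end = max(h$end),
                   strand = strand, completeness = completeness,
                   n_roles = length(unique(h$role)),
                   family = NA_character_, stringsAsFactors = FALSE)
  for (role in c("orf42", "orf22", "orf57")) {
    w <- which(h$role == role)
    if (length(w)) {
      w <- w[which.max(h$bitscore[w])]
      el[[paste0(role, "_start")]] <- h$start[w]
      el[[paste0(role, "_end")]] <- h$end[w]
      el[[paste0(role, "_strand")]] <- h$strand[w]
      el[[paste0(role, "_qcov")]] <- h$qcov[w]
      el[[paste0(role, "_psim")]] <- h$psim[w]
    } else {
      el[[paste0(role, "_start")]] <- NA_integer_
      el[[paste0(role, "_end")]] <- NA_integer_
      el[[paste0(role, "_strand")]] <- NA_character_
      el[[paste0(role, "_qcov")]] <- NA_real_
      el[[paste0(role, "_psim")]] <- NA_real_
    }
  }
  el
}

#' Flag elements near contig ends
#'
#' @param ann A `tbe_annotation`.
#' @param genome The genome.
#' @param cfg An [annotate_config()] (uses `contig_end_window_bp`).
#' @return The annotation with a logical `near_contig_end` column.
#' @export
flag_context <- function(ann, genome, cfg = ann$config) {
  el <- ann$elements
  if (!is(genome, "DNAStringSet")) genome <- as_genome(genome)
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  el$near_contig_end <- pmin(el$start - 1L, clen[el$contig] - el$end) <=
    cfg$contig_end_window_bp
  names(el$near_contig_end) <- NULL
  ann$elements <- el
  ann
}

#' Per-family element summary table
#'
#' Mirrors the genomic-distribution table: per family and completeness
#' class, element counts, total length, percent of class length, the TIR
#' count histogram among complete elements and counts near a track.
#'
#' @param ann A `tbe_annotation`.
#' @param track Optional `GRanges` (e.g. MDSs) for near counts.
#' @param window Distance (bp) defining "near" the track.
#' @return A data frame, one row per family (plus `unclassified` when
#'   present).
#' @export
element_table <- function(ann, track = NULL, window = 500) {
  el <- ann$elements
  if (!nrow(el)) {
    return(data.frame(family = character(0), n_complete = integer(0),
                      complete_bp = integer(0), pct_complete_bp = numeric(0),
                      tir2 = integer(0), tir1 = integer(0), tir0 = integer(0),
                      near_track = integer(0), n_partial = integer(0),
                      partial_bp = integer(0), stringsAsFactors = FALSE))
  }
  fam <- ifelse(is.na(el$family), "unclassified", el$family)
  near <- rep(NA, nrow(el))
  if (!is.null(track) && length(track)) {
    near <- nearest_track_distance(ann, track) <= window
  }
  len <- el$end - el$start + 1L
  comp <- el$completeness == "complete"
  ntir <- if ("n_tirs" %in% names(el)) el$n_tirs else rep(NA_integer_,
                                                          nrow(el))
  rows <- lapply(sort(unique(fam)), function(f) {
    w <- fam == f
    data.frame(
      family = f, n_complete = sum(w & comp),
      complete_bp = sum(len[w & comp]),
      pct_complete_bp = if (sum(len[comp]) > 0)
        100 * sum(len[w & comp]) / sum(len[comp]) else 0,
      tir2 = sum(w & comp & !is.na(ntir) & ntir == 2L),
      tir1 = sum(w & comp & !is.na(ntir) & ntir == 1L),
      tir0 = sum(w & comp & !is.na(ntir) & ntir == 0L),
      near_track = if (all(is.na(near))) NA_integer_ else
        sum(w & comp & near, na.rm = TRUE),
      n_partial = sum(w & !comp),
      partial_bp = sum(len[w & !comp]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
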