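#' Penalties for protein-to-DNA alignment
#'
#' Defaults on the BLOSUM62 scale: a frameshift (-15) is preferred over
#' breaking an alignment of eight or more residues; an in-frame stop (-10)
#' is absorbed rather than terminating the local path.
#'
#' @param frameshift Penalty for a 2-nt or 4-nt codon (one 1-bp indel).
#' @param stop Penalty for aligning a residue to an in-frame stop codon.
#' @param gap_open,gap_ext Affine penalties for whole-residue/whole-codon
#'   gaps.
#' @return A list.
#' @export
p2d_penalties <- function(frameshift = -15, stop = -10, gap_open = 11,
                          gap_ext = 1) {
  list(frameshift = frameshift, stop = stop, gap_open = gap_open,
       gap_ext = gap_ext)
}

nt_encode <- function(seq) {
  v <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 0L
  v - 1L
}

codon_aa_tables <- function(code = genetic_code(6),
                            submat = get_submat("BLOSUM62")) {
  b <- c("A", "C", "G", "T")
  codons <- character(64)
  for (a in 0:3) for (c2 in 0:3) for (d in 0:3) {
    codons[16 * a + 4 * c2 + d + 1] <- paste0(b[a + 1], b[c2 + 1], b[d + 1])
  }
  aa <- unname(code$map[codons])
  idx <- match(aa, rownames(submat))
  idx[is.na(idx)] <- match("X", rownames(submat))
  list(aa_of_codon = idx - 1L, is_stop = aa == "*",
       x_idx = match("X", rownames(submat)) - 1L, codons = codons)
}

#' Frameshift-aware local alignment of a protein to a DNA region
#'
#' Dynamic program over (protein position, nucleotide position) allowing
#' codon advances scored on the table-6 translation, in-frame stops
#' (fixed penalty, recorded), 2-nt and 4-nt frameshift codons (fixed
#' penalty, recorded) and affine residue/codon gaps. Both strands are tried
#' and the better kept. The protein2dna analogue used for coding-sequence
#' extraction.
#'
#' @param query Protein sequence (stop-free).
#' @param region Nucleotide region (>= 30 nt).
#' @param penalties See [p2d_penalties()].
#' @param code Genetic code.
#' @return A list of class `cds_alignment`: `score`, `strand`, `q_start`,
#'   `q_end`, `nt_start`, `nt_end` (coordinates on the *aligned* strand of
#'   the region), `region_start`, `region_end` (forward-strand region
#'   coordinates), `stop_positions` (query residues aligned to TGA),
#'   `frameshift_ops` (data frame codon/shift), `coverage` (aligned query
#'   fraction), `ops` (the raw alignment path) and `region_len`.
#' @export
align_protein_to_dna <- function(query, region, penalties = p2d_penalties(),
                                 code = genetic_code(6)) {
  stopifnot(nchar(region) >= 30)
  if (grepl("\\*", query)) stop("query must be a stop-free protein")
  submat <- get_submat("BLOSUM62")
  tabs <- codon_aa_tables(code, submat)
  qv <- aa_encode(query, submat)
  region <- clean_nuc(region)
  run <- function(seq) {
    .p2d_align(qv, nt_encode(seq), submat, tabs$aa_of_codon, tabs$is_stop,
               tabs$x_idx, penalties$frameshift, penalties$stop,
               penalties$gap_open, penalties$gap_ext)
  }
  fw <- run(region)
  rv <- run(revcomp(region))
  strand <- if (rv$score > fw$score) "-" else "+"
  al <- if (strand == "-") rv else fw
  L <- nchar(region)
  rs <- if (strand == "+") al$nt_start else L - al$nt_end + 1L
  re <- if (strand == "+") al$nt_end else L - al$nt_start + 1L
  ops <- data.frame(op = al$op, ires = al$ires, jnt = al$jnt)
  fs <- ops[ops$op %in% c(3L, 4L), , drop = FALSE]
  structure(list(
    score = al$score, strand = strand, q_start = al$q_start,
    q_end = al$q_end, nt_start = al$nt_start, nt_end = al$nt_end,
    region_start = rs, region_end = re,
    stop_positions = ops$ires[ops$op == 2L],
    frameshift_ops = data.frame(
      codon = fs$ires, shift = ifelse(fs$op == 4L, 1L, -1L)),
    coverage = (al$q_end - al$q_start + 1L) / nchar(query),
    ops = ops, region_len = L, query_len = nchar(query)),
    class = "cds_alignment")
}

#' Premature-stop and frameshift call for one CDS alignment
#'
#' A stop is premature if it sits strictly before the last aligned residue
#' (a stop at the final aligned residue is a terminal stop, not premature).
#'
#' @param cds A `cds_alignment`.
#' @return List with `has_premature_stop` and `has_frameshift`.
#' @export
call_integrity <- function(cds) {
  list(has_premature_stop = any(cds$stop_positions < cds$q_end),
       has_frameshift = nrow(cds$frameshift_ops) > 0L)
}

#' Repair a coding sequence from its alignment
#'
#' Undoes recorded frameshifts (an inserted nucleotide is dropped; a
#' deleted one is restored as N), masks stop codons as NNN, and pads
#' residue deletions with NNN, so the output length is a multiple of 3 and
#' re-aligning it to the query yields no frameshifts. Downstream codon
#' alignment skips N-containing codons.
#'
#' @param cds A `cds_alignment` with coverage >= 0.5.
#' @param region The same nucleotide region the alignment was computed on.
#' @return Repaired coding sequence (character).
#' @export
repair_sequence <- function(cds, region) {
  if (cds$coverage < 0.5) {
    stop("alignment covers ", round(100 * cds$coverage), "% of the query; ",
         "need >= 50% for repair")
  }
  region <- clean_nuc(region)
  seq <- if (cds$strand == "-") revcomp(region) else region
  out <- character(0)
  for (k in seq_len(nrow(cds$ops))) {
    op <- cds$ops$op[k]
    j <- cds$ops$jnt[k]
    piece <- switch(as.character(op),
      "1" = substr(seq, j - 2L, j),
      "2" = "NNN",
      "3" = paste0("N", substr(seq, j - 1L, j)),
      "4" = substr(seq, j - 2L, j),
      "5" = "NNN",
      "6" = "")
    out <- c(out, piece)
  }
  paste(out, collapse = "")
}

#' Protein-guided CDS alignment for every element and role
#'
#' Runs [align_protein_to_dna()] on each annotated ORF hit region (with a
#' small margin) and summarizes integrity per copy.
#'
#' @param ann A `tbe_annotation`.
#' @param genome The genome.
#' @param queries Named protein queries (`orf42`, `orf22`, `orf57`).
#' @param margin Extra bp taken on each side of the hit interval.
#' @param penalties See [p2d_penalties()].
#' @return Data frame, one row per element x present role: scores,
#'   coverage, stop and frameshift calls. The `cds_alignment` objects and
#'   the regions they refer to are attached as `attr(, "alignments")` /
#'   `attr(, "regions")` keyed `elementid.role`.
#' @export
integrity_scan <- function(ann, genome, queries, margin = 30,
                           penalties = p2d_penalties()) {
  el <- ann$elements
  if (!is(genome, "DNAStringSet")) genome <- as_genome(genome)
  rows <- list()
  alns <- list()
  regions <- list()
  for (i in seq_len(nrow(el))) {
    ctg <- as.character(genome[[el$contig[i]]])
    for (role in tbe_roles) {
      hs <- el[[paste0(role, "_start")]][i]
      if (is.na(hs)) next
      he <- el[[paste0(role, "_end")]][i]
      rs <- max(1L, hs - margin)
      re <- min(nchar(ctg), he + margin)
      region <- substr(ctg, rs, re)
      q <- if (is.list(queries) && !is.null(queries[["by_family"]])) {
        fam <- el$family[i]
        if (!is.na(fam) && !is.null(queries$by_family[[fam]])) {
          queries$by_family[[fam]][[role]]
        } else queries$default[[role]]
      } else queries[[role]]
      cds <- align_protein_to_dna(q, region, penalties)
      call <- call_integrity(cds)
      key <- paste0(el$element_id[i], ".", role)
      alns[[key]] <- cds
      regions[[key]] <- region
      rows[[key]] <- data.frame(
        region_gstart = rs, region_gend = re,
        element_id = el$element_id[i],
        family = el$family[i], role = role, score = cds$score,
        strand = cds$strand, q_start = cds$q_start, q_end = cds$q_end,
        coverage = cds$coverage,
        n_stops = length(cds$stop_positions),
        stop_positions = paste(cds$stop_positions, collapse = ";"),
        n_frameshifts = nrow(cds$frameshift_ops),
        frameshift_ops = paste(
          paste0(cds$frameshift_ops$codon, ":",
                 ifelse(cds$frameshift_ops$shift > 0, "+1", "-1")),
          collapse = ";"),
        has_premature_stop = call$has_premature_stop,
        has_frameshift = call$has_frameshift, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element_id = character(0), family = character(0),
               role = character(0))
  rownames(out) <- NULL
  attr(out, "alignments") <- alns
  attr(out, "regions") <- regions
  out
}

#' Per-family consensus protein queries
#'
#' Builds, for each family and role, the majority-rule consensus protein
#' over the repaired coding sequences of that family's copies (stop and
#' masked residues excluded from voting; positions without coverage fall
#' back to the global query). Using the family consensus as the extraction
#' query removes the systematic terminal trimming that a diverged global
#' query causes, which matters for TIR-to-ORF distance modes.
#'
#' @param integ Output of [integrity_scan()] run with the global queries.
#' @param queries The global queries (fallback).
#' @param ann,genome The annotation and genome the scan was run on; when
#'   given, query positions outside every copy's alignment (a diverged
#'   family terminus trimmed by local alignment) are reconstructed from the
#'   flanking DNA of the best-covered copy rather than from the global
#'   query.
#' @param min_coverage Copies below this alignment coverage do not vote.
#' @return A list `list(by_family = <family -> role -> protein>, default =
#'   queries)` accepted by [integrity_scan()].
#' @export
family_consensus_queries <- function(integ, queries, ann = NULL,
                                     genome = NULL, min_coverage = 0.5) {
  alns <- attr(integ, "alignments")
  regions <- attr(integ, "regions")
  fams <- sort(unique(stats::na.omit(integ$family)))
  by_family <- list()
  for (fam in fams) {
    per_role <- list()
    for (role in tbe_roles) {
      qlen <- nchar(queries[[role]])
      w <- which(integ$family == fam & integ$role == role &
                   integ$coverage >= min_coverage)
      if (!length(w)) next
      votes <- matrix(NA_character_, nrow = length(w), ncol = qlen)
      for (vi in seq_along(w)) {
        i <- w[vi]
        key <- paste0(integ$element_id[i], ".", integ$role[i])
        rep <- repair_sequence(alns[[key]], regions[[key]])
        prot <- strsplit(suppressWarnings(translate_cds(rep)), "")[[1]]
        qs <- integ$q_start[i]
        span <- seq_len(min(length(prot), qlen - qs + 1L))
        votes[vi, qs + span - 1L] <- prot[span]
      }
      fb <- strsplit(queries[[role]], "")[[1]]
      if (!is.null(ann) && !is.null(genome)) {
        fb <- exemplar_extend(fb, integ, w, alns, ann, genome)
      }
      cons <- vapply(seq_len(qlen), function(p) {
        v <- votes[, p]
        v <- v[!is.na(v) & v != "*" & v != "X"]
        if (!length(v)) return(fb[p])
        tab <- sort(table(v), decreasing = TRUE)
        names(tab)[1L]
      }, character(1))
      cons[cons == "*" | cons == "X"] <- fb[cons == "*" | cons == "X"]
      per_role[[role]] <- paste(cons, collapse = "")
    }
    if (length(per_role)) by_family[[fam]] <- per_role
  }
  list(by_family = by_family, default = queries)
}

# fill query positions before q_start / after q_end of the family's
# best-covered copy with the translation of that copy's flanking DNA
exemplar_extend <- function(fb, integ, w, alns, ann, genome) {
  k <- w[order(-integ$coverage[w], -integ$score[w])][1L]
  cds <- alns[[paste0(integ$element_id[k], ".", integ$role[k])]]
  el <- ann$elements
  ctg <- as.character(genome[[el$contig[match(integ$element_id[k],
                                              el$element_id)]]])
  gs <- integ$region_gstart[k] + cds$region_start - 1L
  ge <- integ$region_gstart[k] + cds$region_end - 1L
  n_lead <- cds$q_start - 1L
  n_trail <- length(fb) - cds$q_end
  grab <- function(n_aa, upstream) {
    if (n_aa <= 0L) return(character(0))
    if (cds$strand == "+") {
      iv <- if (upstream) c(gs - 3L * n_aa, gs - 1L) else
        c(ge + 1L, ge + 3L * n_aa)
    } else {
      iv <- if (upstream) c(ge + 1L, ge + 3L * n_aa) else
        c(gs - 3L * n_aa, gs - 1L)
    }
    if (iv[1] < 1L || iv[2] > nchar(ctg)) return(character(0))
    s <- substr(ctg, iv[1], iv[2])
    if (cds$strand == "-") s <- revcomp(s)
    strsplit(suppressWarnings(translate_cds(s)), "")[[1]]
  }
  lead <- grab(n_lead, TRUE)
  trail <- grab(n_trail, FALSE)
  if (length(lead) == n_lead && n_lead > 0L) {
    ok <- lead != "*" & lead != "X"
    fb[seq_len(n_lead)][ok] <- lead[ok]
  }
  if (length(trail) == n_trail && n_trail > 0L) {
    ok <- trail != "*" & trail != "X"
    fb[cds$q_end + seq_len(n_trail)][ok] <- trail[ok]
  }
  fb
}

#' Update element ORF coordinates from CDS alignments
#'
#' Replaces the hit-based ORF intervals with the protein-to-DNA alignment
#' spans (and refreshes the ORF envelope), typically after a second
#' [integrity_scan()] with family consensus queries.
#'
#' @param ann A `tbe_annotation`.
#' @param integ Output of [integrity_scan()].
#' @param min_coverage Alignments below this coverage leave the
#'   coordinates untouched.
#' @return The updated annotation.
#' @export
refine_orf_coords <- function(ann, integ, min_coverage = 0.5) {
  el <- ann$elements
  for (k in seq_len(nrow(integ))) {
    if (integ$coverage[k] < min_coverage) next
    i <- match(integ$element_id[k], el$element_id)
    role <- integ$role[k]
    key <- paste0(integ$element_id[k], ".", role)
    cds <- attr(integ, "alignments")[[key]]
    el[[paste0(role, "_start")]][i] <- integ$region_gstart[k] +
      cds$region_start - 1L
    el[[paste0(role, "_end")]][i] <- integ$region_gstart[k] +
      cds$region_end - 1L
    el[[paste0(role, "_strand")]][i] <- cds$strand
  }
  smat <- as.matrix(el[paste0(tbe_roles, "_start")])
  emat <- as.matrix(el[paste0(tbe_roles, "_end")])
  has <- rowSums(!is.na(smat)) > 0
  el$env_start[has] <- as.integer(apply(smat[has, , drop = FALSE], 1, min,
                                        na.rm = TRUE))
  el$env_end[has] <- as.integer(apply(emat[has, , drop = FALSE], 1, max,
                                      na.rm = TRUE))
  el$start <- pmin(el$start, el$env_start)
  el$end <- pmax(el$end, el$env_end)
  ann$elements <- el
  ann
}

#' Prevalence of premature stops and frameshifts per family and role
#'
#' @param calls Output of [integrity_scan()] (families assigned).
#' @return Data frame: family, role, n, pct_stop, pct_frameshift.
#' @export
integrity_table <- function(calls) {
  if (!nrow(calls)) {
    return(data.frame(family = character(0), role = character(0),
                      n = integer(0), pct_stop = numeric(0),
                      pct_frameshift = numeric(0)))
  }
  fam <- ifelse(is.na(calls$family), "unclassified", calls$family)
  rows <- list()
  for (f in sort(unique(fam))) {
    for (role in tbe_roles) {
      w <- fam == f & calls$role == role
      if (!any(w)) next
      rows[[length(rows) + 1L]] <- data.frame(
        family = f, role = role, n = sum(w),
        pct_stop = 100 * mean(calls$has_premature_stop[w]),
        pct_frameshift = 100 * mean(calls$has_frameshift[w]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Positional stop-codon profile and hotspots
#'
#' Per-residue fraction of copies carrying an in-frame stop, computed over
#' the copies whose alignment covers that residue; hotspots are residues
#' with fraction at or above the threshold, sorted by fraction.
#'
#' @param calls Output of [integrity_scan()], typically filtered to one
#'   family and role.
#' @param query_len Query length in residues.
#' @param hotspot_threshold Minimum fraction for a hotspot (default 0.10).
#' @return List: `fraction` (numeric vector over residues), `n_covering`,
#'   `hotspots` (data frame residue/fraction).
#' @export
stop_profile <- function(calls, query_len, hotspot_threshold = 0.10) {
  stopifnot(nrow(calls) >= 1)
  cover <- integer(query_len)
  stopped <- integer(query_len)
  for (i in seq_len(nrow(calls))) {
    qs <- calls$q_start[i]
    qe <- calls$q_end[i]
    cover[qs:qe] <- cover[qs:qe] + 1L
    if (nzchar(calls$stop_positions[i])) {
      pos <- as.integer(strsplit(calls$stop_positions[i], ";")[[1]])
      pos <- pos[pos >= 1 & pos <= query_len]
      stopped[pos] <- stopped[pos] + 1L
    }
  }
  frac <- ifelse(cover > 0, stopped / cover, NA_real_)
  hot <- which(!is.na(frac) & frac >= hotspot_threshold)
  hot <- hot[order(-frac[hot])]
  list(fraction = frac, n_covering = cover,
       hotspots = data.frame(residue = hot, fraction = frac[hot]))
}
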