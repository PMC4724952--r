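#' Configuration for the synthetic germline-genome generator
#'
#' The generator emulates a transposon-rich ciliate germline (micronuclear)
#' assembly: multi-contig background with implanted TBE elements of four
#' families (TBE1, TBE2.1, TBE2.2, TBE3), each bounded by terminal inverted
#' repeats that begin with telomeric repeat sequence, carrying three ORFs
#' (42kD and 57kD on the element strand, 22kD inverted) separated by a
#' ~200 bp tandem-repeat spacer, flanked by duplicated target sites, plus
#' macronuclear-destined-sequence (MDS) and satellite-repeat annotation
#' tracks.
#'
#' Divergences are expected *pairwise* substitutions per site between two
#' copies of the same family (each copy is drawn at half that distance from
#' the family template).
#'
#' @param seed Master seed; all stage streams derive from it.
#' @param n_contigs,contig_length Background contig count and length (bp).
#' @param copies_per_family Implanted copies per family.
#' @param within_family_divergence Expected pairwise subs/site within family.
#' @param between_family_divergence Template divergence between TBE1 and
#'   TBE2; must be >= the within-family divergence when positive.
#' @param tbe3_divergence Template divergence of TBE3 from TBE1/TBE2
#'   (default twice `between_family_divergence`).
#' @param subfamily_divergence 42kD/22kD template divergence between TBE2.1
#'   and TBE2.2 (default `between_family_divergence / 10`).
#' @param subfamily_57k_divergence 57kD template divergence between TBE2.1
#'   and TBE2.2 (default `1.75 * between_family_divergence`).
#' @param omega Named numeric, target dN/dS of the copy mutation process per
#'   ORF.
#' @param frameshift_prob Named numeric, probability a copy's ORF receives
#'   one 1-bp indel.
#' @param stop_hotspots Data frame (family, role, residue, fraction): the
#'   fraction of that family's copies whose ORF carries TGA at the residue.
#' @param partial_copy_fraction Fraction of copies degraded to partial
#'   (one or two ORFs deleted).
#' @param mds_genome_fraction Fraction of background bp covered by MDSs.
#' @param mds_interval_len Mean MDS interval length (bp).
#' @param mds_bias Relative weight of insertion points within `mds_window`
#'   of an MDS (1 = uniform placement).
#' @param mds_window Window (bp) defining "near MDS".
#' @param satellite_units List of `list(unit_len, n_loci, n_units)` tandem
#'   satellite arrays written into the background.
#' @param fragmentation Probability a contig boundary bisects an element.
#' @param tsd Target-site duplication motif (2-10 bp).
#' @param gc Background GC content.
#' @param orf_lens Named integer, ORF lengths in codons.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_contigs = 30L, contig_length = 1e5,
                         copies_per_family = 15L,
                         within_family_divergence = 0.08,
                         between_family_divergence = 0.20,
                         tbe3_divergence = NULL,
                         subfamily_divergence = NULL,
                         subfamily_57k_divergence = NULL,
                         omega = c(orf42 = 0.2, orf22 = 0.2, orf57 = 0.2),
                         frameshift_prob = c(orf42 = 0.3, orf22 = 0.3,
                                             orf57 = 0.3),
                         stop_hotspots = data.frame(
                           family = "TBE3", role = "orf42",
                           residue = 70, fraction = 0.8),
                         partial_copy_fraction = 0.10,
                         mds_genome_fraction = 0.111,
                         mds_interval_len = 25000,
                         mds_bias = 1, mds_window = 500,
                         satellite_units = list(
                           list(unit_len = 380, n_loci = 3, n_units = 6),
                           list(unit_len = 170, n_loci = 3, n_units = 8)),
                         fragmentation = 0, tsd = "TA", gc = 0.5,
                         orf_lens = c(orf42 = 352L, orf22 = 192L,
                                      orf57 = 471L)) {
  if (is.null(tbe3_divergence)) tbe3_divergence <- 2 * between_family_divergence
  if (is.null(subfamily_divergence)) {
    subfamily_divergence <- between_family_divergence / 10
  }
  if (is.null(subfamily_57k_divergence)) {
    subfamily_57k_divergence <- 1.75 * between_family_divergence
  }
  probs <- c(frameshift_prob, partial_copy_fraction, mds_genome_fraction,
             fragmentation, stop_hotspots$fraction)
  stopifnot(all(probs >= 0 & probs <= 1), all(omega >= 0),
            nchar(tsd) >= 2, nchar(tsd) <= 10)
  if (between_family_divergence > 0 &&
      within_family_divergence > between_family_divergence) {
    stop("divergence targets incompatible: within-family (",
         within_family_divergence, ") exceeds between-family (",
         between_family_divergence, ")")
  }
  structure(as.list(environment()), class = "synth_config")
}

tbe_families <- c("TBE1", "TBE2.1", "TBE2.2", "TBE3")
tbe_roles <- c("orf42", "orf22", "orf57")

# TIR-to-42kD and 57kD-to-TIR spacings (bp) per family; the TBE2.1 TIR ends
# right before the 42kD start codon, and TIR length + 5' spacing is the
# constant 138 bp across the TBE2 subfamilies.
fam_spacing <- data.frame(
  family = tbe_families,
  d5 = c(34L, 0L, 21L, 17L),
  d3 = c(1L, 23L, 44L, 54L))

#' Published TIR consensus sequences
#'
#' Reads the TIR consensus sequences shipped with the package (one per
#' family; TBE2.2 has two types, of which type 1 is a 21 bp shorter version
#' of the TBE2.1 TIR).
#'
#' @return Named character vector of TIR sequences.
#' @export
tir_consensus_seqs <- function() {
  path <- system.file("extdata", "tbe_tir_consensus.fa", package = "tbescan")
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

rand_nt <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

rand_cds <- function(n_codons, code = genetic_code(6)) {
  ok <- setdiff(all_codons(), code$stop_codons)
  paste(sample(ok, n_codons, replace = TRUE), collapse = "")
}

# independent per-site substitutions at the given rate
mutate_sites <- function(seq, rate) {
  n <- nchar(seq)
  if (n == 0 || rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(n) < rate)
  for (i in hit) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  paste(v, collapse = "")
}

#' Mutate a coding sequence under a target dN/dS
#'
#' Proposes uniform single-nucleotide changes; synonymous proposals are
#' accepted with probability 1 and nonsynonymous with probability `omega`.
#' Proposals creating a stop codon are re-proposed, so the output is
#' stop-free. The process runs until `Poisson(d * n_codons)` substitutions
#' have been accepted, so `d` is the expected number of accepted
#' substitutions per codon.
#'
#' @param cds Stop-free coding sequence (table 6), length divisible by 3.
#' @param omega Acceptance probability for nonsynonymous proposals (>= 0).
#' @param d Expected accepted substitutions per codon.
#' @param code Genetic code.
#' @return The mutated coding sequence.
#' @export
mutate_codon_sequence <- function(cds, omega, d, code = genetic_code(6)) {
  stopifnot(omega >= 0, d >= 0, nchar(cds) %% 3 == 0)
  n <- nchar(cds)
  if (n == 0 || d == 0) return(cds)
  v <- strsplit(clean_nuc(cds), "")[[1]]
  n_codons <- n %/% 3
  target <- stats::rpois(1L, d * n_codons)
  accepted <- 0L
  tries <- 0L
  max_tries <- 1000L * (target + 10L)
  while (accepted < target && tries < max_tries) {
    tries <- tries + 1L
    pos <- sample.int(n, 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), v[pos]), 1L)
    ci <- (pos - 1L) %/% 3L
    old_codon <- paste(v[(3L * ci + 1L):(3L * ci + 3L)], collapse = "")
    new <- v
    new[pos] <- alt
    new_codon <- paste(new[(3L * ci + 1L):(3L * ci + 3L)], collapse = "")
    if (code$map[[new_codon]] == "*") next
    syn <- code$map[[new_codon]] == code$map[[old_codon]]
    if (syn || stats::runif(1L) < omega) {
      v <- new
      accepted <- accepted + 1L
    }
  }
  if (accepted < target) {
    warning("mutation process stopped after ", tries, " proposals")
  }
  paste(v, collapse = "")
}

#' Build the four family templates
#'
#' Generates an ancestral element and evolves family templates along a fixed
#' tree (TBE1 and TBE2 sister, TBE3 outgroup; the TBE2 subfamilies nearly
#' identical in 42kD/22kD but divergent in 57kD), mirroring the observed
#' between-family similarity structure. TIRs are the published family
#' consensus sequences; the right TIR is the reverse complement of the left.
#'
#' @param cfg A [synth_config()].
#' @return A named list of templates (one per family), each with TIR, spacer
#'   and filler sequences, the three ancestral ORF coding sequences and the
#'   family spacings; the ancestral ORFs are attached as
#'   `attr(, "ancestor")` and their translations as `attr(, "queries")`.
#' @export
build_templates <- function(cfg = synth_config()) {
  code <- genetic_code(6)
  tirs <- tir_consensus_seqs()
  fam_tir <- c(TBE1 = unname(tirs["TBE1"]), `TBE2.1` = unname(tirs["TBE2.1"]),
               `TBE2.2` = unname(tirs["TBE2.2a"]), TBE3 = unname(tirs["TBE3"]))
  anc <- lapply(stats::setNames(cfg$orf_lens, tbe_roles), rand_cds,
                code = code)
  b2 <- cfg$between_family_divergence / 2
  b3 <- max(cfg$tbe3_divergence - b2, 0)
  evolve <- function(orfs, d_codon) {
    lapply(orfs, mutate_codon_sequence, omega = 1, d = d_codon, code = code)
  }
  t1 <- evolve(anc, 3 * b2)
  t2anc <- evolve(anc, 3 * b2)
  t3 <- evolve(anc, 3 * b3)
  sub_small <- 3 * cfg$subfamily_divergence / 2
  sub_57 <- 3 * cfg$subfamily_57k_divergence / 2
  t21 <- list(orf42 = mutate_codon_sequence(t2anc$orf42, 1, sub_small, code),
              orf22 = mutate_codon_sequence(t2anc$orf22, 1, sub_small, code),
              orf57 = mutate_codon_sequence(t2anc$orf57, 1, sub_57, code))
  t22 <- list(orf42 = mutate_codon_sequence(t2anc$orf42, 1, sub_small, code),
              orf22 = mutate_codon_sequence(t2anc$orf22, 1, sub_small, code),
              orf57 = mutate_codon_sequence(t2anc$orf57, 1, sub_57, code))
  unit <- rand_nt(12, cfg$gc)
  spacer0 <- paste(rep(unit, 17), collapse = "")
  gap0 <- rand_nt(60, cfg$gc)
  orfs_by_fam <- list(TBE1 = t1, `TBE2.1` = t21, `TBE2.2` = t22, TBE3 = t3)
  out <- lapply(tbe_families, function(fam) {
    sp <- fam_spacing[fam_spacing$family == fam, ]
    tl <- fam_tir[[fam]]
    list(family = fam, tir_left = tl, tir_right = revcomp(tl),
         d5_seq = rand_nt(sp$d5, cfg$gc), d3_seq = rand_nt(sp$d3, cfg$gc),
         gap_seq = mutate_sites(gap0, b2), spacer = mutate_sites(spacer0, b2),
         orf42 = orfs_by_fam[[fam]]$orf42, orf22 = orfs_by_fam[[fam]]$orf22,
         orf57 = orfs_by_fam[[fam]]$orf57)
  })
  names(out) <- tbe_families
  attr(out, "ancestor") <- anc
  attr(out, "queries") <- vapply(anc, translate_cds, character(1),
                                 code = code)
  out
}

# one element copy with element-relative truth
make_copy <- function(tpl, cfg, code = genetic_code(6)) {
  half <- cfg$within_family_divergence / 2
  orfs <- list()
  stops <- list(orf42 = integer(0), orf22 = integer(0), orf57 = integer(0))
  shifts <- list(orf42 = NULL, orf22 = NULL, orf57 = NULL)
  for (role in tbe_roles) {
    cds <- mutate_codon_sequence(tpl[[role]], cfg$omega[[role]], 3 * half,
                                 code)
    hs <- cfg$stop_hotspots
    hs <- hs[hs$family == tpl$family & hs$role == role, , drop = FALSE]
    for (r in seq_len(nrow(hs))) {
      if (stats::runif(1L) < hs$fraction[r]) {
        res <- hs$residue[r]
        substr(cds, 3L * (res - 1L) + 1L, 3L * res) <- "TGA"
        stops[[role]] <- sort(c(stops[[role]], res))
      }
    }
    if (stats::runif(1L) < cfg$frameshift_prob[[role]]) {
      pos <- sample.int(nchar(cds) - 3L, 1L) + 1L
      if (stats::runif(1L) < 0.5) {
        cds <- paste0(substr(cds, 1L, pos), rand_nt(1L, cfg$gc),
                      substr(cds, pos + 1L, nchar(cds)))
        shifts[[role]] <- c(codon = (pos - 1L) %/% 3L + 1L, shift = 1L)
      } else {
        cds <- paste0(substr(cds, 1L, pos - 1L),
                      substr(cds, pos + 1L, nchar(cds)))
        shifts[[role]] <- c(codon = (pos - 1L) %/% 3L + 1L, shift = -1L)
      }
    }
    orfs[[role]] <- cds
  }
  segs <- list(
    tirL = mutate_sites(tpl$tir_left, half),
    d5 = mutate_sites(tpl$d5_seq, half),
    orf42 = orfs$orf42,
    gap = mutate_sites(tpl$gap_seq, half),
    orf22 = revcomp(orfs$orf22),
    spacer = mutate_sites(tpl$spacer, half),
    orf57 = orfs$orf57,
    d3 = mutate_sites(tpl$d3_seq, half),
    tirR = mutate_sites(tpl$tir_right, half))
  drop_roles <- character(0)
  if (stats::runif(1L) < cfg$partial_copy_fraction) {
    drop_roles <- sample(tbe_roles, sample(1:2, 1L))
    for (role in drop_roles) segs[[role]] <- ""
  }
  lens <- vapply(segs, nchar, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  elem <- paste(unlist(segs), collapse = "")
  L <- nchar(elem)
  seg_iv <- data.frame(seg = names(segs), start = starts, end = ends,
                       row.names = NULL)
  orf_strand <- c(orf42 = "+", orf22 = "-", orf57 = "+")
  strand <- if (stats::runif(1L) < 0.5) "+" else "-"
  if (strand == "-") {
    elem <- revcomp(elem)
    tmp <- seg_iv$start
    seg_iv$start <- L - seg_iv$end + 1L
    seg_iv$end <- L - tmp + 1L
    orf_strand <- c(orf42 = "-", orf22 = "+", orf57 = "-")
  }
  list(family = tpl$family, seq = elem, len = L, strand = strand,
       segments = seg_iv, orf_strand = orf_strand,
       present = setdiff(tbe_roles, drop_roles),
       completeness = if (length(drop_roles)) "partial" else "complete",
       stops = stops, shifts = shifts)
}

#' Sample element insertion points, optionally biased toward a track
#'
#' Rejection sampler used by [simulate_genome()] and by enrichment
#' calibration: points within `window` of a track interval are accepted with
#' relative weight `bias`. Accepted points keep a minimum separation.
#'
#' @param n Number of points.
#' @param contig_len Background contig length.
#' @param track_starts,track_ends Track intervals (1-based, sorted or not).
#' @param bias Relative weight near the track (1 = uniform).
#' @param window Distance (bp) defining "near".
#' @param min_sep Minimum separation between accepted points.
#' @param edge_margin Keep points at least this far from contig ends.
#' @param max_tries Bounded retries before failing.
#' @return Sorted integer vector of insertion points.
#' @export
sample_insertion_points <- function(n, contig_len, track_starts = integer(0),
                                    track_ends = integer(0), bias = 1,
                                    window = 500, min_sep = 2500,
                                    edge_margin = 1000,
                                    max_tries = 2000L * n) {
  pts <- integer(0)
  wmax <- max(bias, 1)
  tries <- 0L
  lo <- edge_margin
  hi <- contig_len - edge_margin
  if (hi <= lo) stop("contig too short for placement")
  while (length(pts) < n && tries < max_tries) {
    tries <- tries + 1L
    p <- sample.int(hi - lo, 1L) + lo
    near <- length(track_starts) &&
      any(p >= track_starts - window & p <= track_ends + window)
    w <- if (near) bias else 1
    if (stats::runif(1L) >= w / wmax) next
    if (length(pts) && min(abs(pts - p)) < min_sep) next
    pts <- c(pts, p)
  }
  if (length(pts) < n) {
    stop("could not place ", n, " elements at density ",
         signif(n * min_sep / contig_len, 3), "; increase contig length")
  }
  sort(pts)
}

mds_intervals <- function(contig_len, fraction, mean_len) {
  if (fraction <= 0) return(data.frame(start = integer(0), end = integer(0)))
  target <- fraction * contig_len
  starts <- integer(0)
  ends <- integer(0)
  covered <- 0
  tries <- 0L
  while (covered < target && tries < 1000L) {
    tries <- tries + 1L
    len <- max(500L, round(stats::rnorm(1L, mean_len, mean_len / 4)))
    len <- min(len, round(target - covered) + 500L)
    s <- sample.int(max(contig_len - len, 1L), 1L)
    e <- s + len - 1L
    if (length(starts) && any(pmax(s - 1000L, starts) <=
                                pmin(e + 1000L, ends))) next
    starts <- c(starts, s)
    ends <- c(ends, e)
    covered <- covered + len
  }
  o <- order(starts)
  data.frame(start = starts[o], end = ends[o])
}

#' Simulate a germline-like genome with implanted TBE elements
#'
#' Implants element copies (with duplicated target sites) into background
#' contigs, writes MDS and satellite annotation tracks, optionally degrades
#' copies to partials or bisects them with contig boundaries, and returns
#' full ground truth for every copy.
#'
#' @param cfg A [synth_config()].
#' @return A list with `genome` (`DNAStringSet`), `truth` (per-copy data
#'   frame: copy_id, family, contig, start, end, strand, completeness, tsd),
#'   `truth_orfs` (per-ORF genomic intervals, strands, introduced stop
#'   residues and frameshifts), `mds` and `satellite` (`GRanges`),
#'   `templates`, `queries` (the three ancestral ORF proteins) and `config`.
#' @export
simulate_genome <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 5L)
  code <- genetic_code(6)

  set.seed(stage_seeds[1L])
  templates <- build_templates(cfg)

  set.seed(stage_seeds[2L])
  copies <- list()
  for (fam in tbe_families) {
    for (i in seq_len(cfg$copies_per_family)) {
      cp <- make_copy(templates[[fam]], cfg, code)
      cp$copy_id <- sprintf("%s_c%02d", fam, i)
      copies[[length(copies) + 1L]] <- cp
    }
  }
  total_implant <- sum(vapply(copies, function(x) x$len, numeric(1)))
  genome_len <- cfg$n_contigs * cfg$contig_length
  if (total_implant >= 0.5 * genome_len) {
    stop("implants (", total_implant, " bp) exceed half the genome (",
         genome_len, " bp)")
  }

  set.seed(stage_seeds[3L])
  assign_ctg <- sort(sample(rep_len(seq_len(cfg$n_contigs), length(copies))))
  k <- nchar(cfg$tsd)
  contigs <- character(cfg$n_contigs)
  names(contigs) <- sprintf("ctg%03d", seq_len(cfg$n_contigs))
  truth <- list()
  orf_truth <- list()
  mds_all <- list()
  sat_all <- list()
  for (ci in seq_len(cfg$n_contigs)) {
    ctg <- names(contigs)[ci]
    bg <- rand_nt(cfg$contig_length, cfg$gc)
    # satellite arrays overwrite background slices (length-preserving)
    sat_iv <- data.frame(start = integer(0), end = integer(0),
                         label = character(0))
    # each satellite locus lands on a random contig, decided by lottery
    for (su in cfg$satellite_units) {
      for (locus in seq_len(su$n_loci)) {
        if (sample.int(cfg$n_contigs, 1L) != ci) next
        unit <- rand_nt(su$unit_len, cfg$gc)
        arr <- paste(rep(unit, su$n_units), collapse = "")
        alen <- nchar(arr)
        if (alen >= cfg$contig_length - 2000L) next
        s <- sample.int(cfg$contig_length - alen - 1000L, 1L) + 500L
        substr(bg, s, s + alen - 1L) <- arr
        sat_iv <- rbind(sat_iv, data.frame(
          start = s, end = s + alen - 1L,
          label = paste0("satellite-", su$unit_len)))
      }
    }
    mds_iv <- mds_intervals(cfg$contig_length, cfg$mds_genome_fraction,
                            cfg$mds_interval_len)
    idx <- which(assign_ctg == ci)
    cps <- copies[idx]
    pts <- if (length(cps)) {
      sample_insertion_points(length(cps), cfg$contig_length,
                              mds_iv$start, mds_iv$end, cfg$mds_bias,
                              cfg$mds_window)
    } else integer(0)
    # assemble contig left to right, tracking the coordinate shift
    pieces <- character(0)
    prev <- 1L
    offset <- 0L
    ins_tbl <- data.frame(p = pts, shift = integer(length(pts)))
    for (q in seq_along(pts)) {
      p <- pts[q]
      cp <- cps[[q]]
      pieces <- c(pieces, substr(bg, prev, p), cfg$tsd, cp$seq, cfg$tsd)
      el_start <- p + offset + k + 1L
      el_end <- el_start + cp$len - 1L
      truth[[length(truth) + 1L]] <- data.frame(
        copy_id = cp$copy_id, family = cp$family, contig = ctg,
        start = el_start, end = el_end, strand = cp$strand,
        completeness = cp$completeness, tsd = cfg$tsd,
        stringsAsFactors = FALSE)
      seg <- cp$segments
      for (role in cp$present) {
        sr <- seg[seg$seg == role, ]
        st <- cp$stops[[role]]
        sh <- cp$shifts[[role]]
        orf_truth[[length(orf_truth) + 1L]] <- data.frame(
          copy_id = cp$copy_id, family = cp$family, role = role,
          contig = ctg, start = el_start + sr$start - 1L,
          end = el_start + sr$end - 1L,
          strand = cp$orf_strand[[role]],
          elem_strand = cp$strand,
          stops = paste(st, collapse = ";"),
          frameshifts = if (is.null(sh)) "" else
            paste0(sh[["codon"]], ":", ifelse(sh[["shift"]] > 0, "+1", "-1")),
          stringsAsFactors = FALSE)
      }
      # TIR truth rides along in the element record via segments
      tl <- seg[seg$seg == "tirL", ]
      tr <- seg[seg$seg == "tirR", ]
      truth[[length(truth)]]$tir_lstart <- el_start + tl$start - 1L
      truth[[length(truth)]]$tir_lend <- el_start + tl$end - 1L
      truth[[length(truth)]]$tir_rstart <- el_start + tr$start - 1L
      truth[[length(truth)]]$tir_rend <- el_start + tr$end - 1L
      prev <- p + 1L
      offset <- offset + cp$len + 2L * k
      ins_tbl$shift[q] <- offset
    }
    pieces <- c(pieces, substr(bg, prev, cfg$contig_length))
    contigs[ci] <- paste(pieces, collapse = "")
    shift_of <- function(x) {
      vapply(x, function(z) {
        s <- 0L
        if (nrow(ins_tbl)) {
          w <- ins_tbl$p < z
          if (any(w)) s <- ins_tbl$shift[max(which(w))]
        }
        s
      }, integer(1))
    }
    if (nrow(mds_iv)) {
      mds_all[[ctg]] <- data.frame(
        contig = ctg, start = mds_iv$start + shift_of(mds_iv$start),
        end = mds_iv$end + shift_of(mds_iv$end))
    }
    if (nrow(sat_iv)) {
      sat_all[[ctg]] <- data.frame(
        contig = ctg, start = sat_iv$start + shift_of(sat_iv$start),
        end = sat_iv$end + shift_of(sat_iv$end), label = sat_iv$label)
    }
  }
  truth <- do.call(rbind, truth)
  orf_truth <- do.call(rbind, orf_truth)

  # contig fragmentation: a boundary bisects some elements
  set.seed(stage_seeds[4L])
  if (cfg$fragmentation > 0 && nrow(truth)) {
    cut_ids <- truth$copy_id[stats::runif(nrow(truth)) < cfg$fragmentation]
    for (id in cut_ids) {
      r <- truth[truth$copy_id == id, ]
      ctg <- r$contig
      cut <- r$start + (r$end - r$start) %/% 2L
      seqc <- contigs[[ctg]]
      new1 <- paste0(ctg, "a")
      new2 <- paste0(ctg, "b")
      contigs <- contigs[names(contigs) != ctg]
      contigs[new1] <- substr(seqc, 1L, cut)
      contigs[new2] <- substr(seqc, cut + 1L, nchar(seqc))
      remap <- function(df) {
        if (is.null(df) || !nrow(df)) return(df)
        w <- df$contig == ctg
        if (!any(w)) return(df)
        d <- df[w, ]
        keep_l <- d$end <= cut
        keep_r <- d$start > cut
        span <- !keep_l & !keep_r
        d$contig[keep_l] <- new1
        d$contig[keep_r] <- new2
        d$start[keep_r] <- d$start[keep_r] - cut
        d$end[keep_r] <- d$end[keep_r] - cut
        # spanning records are clipped to the left fragment
        d$end[span] <- pmin(d$end[span], cut)
        d$contig[span] <- new1
        rbind(df[!w, ], d)
      }
      truth$completeness[truth$copy_id == id] <- "bisected"
      truth <- remap(truth)
      orf_truth <- remap(orf_truth)
      mds_all <- lapply(mds_all, remap)
      sat_all <- lapply(sat_all, remap)
    }
  }

  genome <- Biostrings::DNAStringSet(contigs)
  to_gr <- function(lst, extra = NULL) {
    df <- do.call(rbind, lst)
    if (is.null(df) || !nrow(df)) {
      return(GenomicRanges::GRanges(seqnames = NULL))
    }
    gr <- GenomicRanges::GRanges(df$contig,
                                 IRanges::IRanges(df$start, df$end))
    if (!is.null(df$label)) S4Vectors::mcols(gr)$label <- df$label
    gr
  }
  list(genome = genome, truth = truth, truth_orfs = orf_truth,
       mds = to_gr(mds_all), satellite = to_gr(sat_all),
       templates = templates, queries = attr(templates, "queries"),
       config = cfg)
}
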