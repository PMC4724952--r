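#' Nucleotide substitution matrix with strict N handling
#'
#' Match/mismatch matrix over the IUPAC alphabet in which only A/C/G/T match
#' themselves; N (and every ambiguity code) scores as a mismatch against
#' everything, including itself.
#'
#' @param match,mismatch Match and mismatch scores (BLASTN defaults 2/-3).
#' @return A square numeric matrix.
#' @export
nuc_submat <- function(match = 2, mismatch = -3) {
  letters <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K", "V", "H",
               "D", "B", "N")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m)[1:4] <- match
  m
}

# pairwise nt alignment with explicit column statistics
nt_align <- function(a, b, type = "local", match = 2, mismatch = -3,
                     gap_open = 5, gap_ext = 2) {
  al <- Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = nuc_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext, type = type)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- !(p == "-" & s == "-")
  p <- p[keep]
  s <- s[keep]
  pr <- al@pattern@range
  sr <- al@subject@range
  list(score = Biostrings::score(al), columns = length(p),
       matches = sum(p == s & p != "-" & p != "N"),
       p_start = BiocGenerics::start(pr), p_end = BiocGenerics::end(pr),
       s_start = BiocGenerics::start(sr), s_end = BiocGenerics::end(sr))
}

#' Percent similarity of two sequences
#'
#' Local alignment with BLASTN default scoring (match 2, mismatch -3, gap
#' open 5, extend 2); similarity is matches over alignment columns (gap
#' columns included) times 100. Applied to the two TBE2.2 TIR consensus
#' types this reproduces their published 92.5 % similarity.
#'
#' @param a,b Nucleotide sequences (character).
#' @param type Alignment type, `"local"` (default) or `"global"`.
#' @return Percent similarity in `[0, 100]`.
#' @examples
#' tir_similarity("AAAA", "AAAT", type = "global")  # 75
#' @export
tir_similarity <- function(a, b, type = "local") {
  stopifnot(nzchar(a), nzchar(b))
  al <- nt_align(clean_nuc(a), clean_nuc(b), type = type)
  100 * al$matches / al$columns
}

#' Reference TIR features of the Oxytricha TBE families
#'
#' Modal distances (bp) between each TIR type and the nearest ORF: the 5'
#' TIR inner end to the 42kD start codon (`d5_mode`) and the 57kD ORF end
#' to the 3' TIR (`d3_mode`). The TBE2.1 TIR ends right before the 42kD
#' start codon; across the TBE2 subfamilies, TIR length plus `d5_mode` is
#' the constant 138 bp. Used as the synthetic generator's template
#' spacings and as reference values for checks.
#'
#' @return Data frame: tir (consensus name, see [tir_consensus_seqs()]),
#'   family, d5_mode, d3_mode.
#' @export
tbe_reference_features <- function() {
  data.frame(
    tir = c("TBE1", "TBE2.1", "TBE2.2a", "TBE2.2b", "TBE3"),
    family = c("TBE1", "TBE2.1", "TBE2.2", "TBE2.2", "TBE3"),
    d5_mode = c(34L, 0L, 21L, 26L, 17L),
    d3_mode = c(1L, 23L, 44L, 49L, 54L),
    stringsAsFactors = FALSE)
}

#' The telomeric motif bounding TBE terminal inverted repeats
#'
#' @return List with `canonical` (CA4C4A4C4, 17 nt) and `variant`
#'   (CA4C4A4C3, 16 nt).
#' @export
telomeric_motif <- function() {
  list(canonical = "CAAAACCCCAAAACCCC", variant = "CAAAACCCCAAAACCC")
}

#' Classify a TIR by its telomeric repeat
#'
#' Exact substring search; the canonical 17-nt motif is checked before the
#' 16-nt variant.
#'
#' @param tir TIR sequence.
#' @param motif Motif set, see [telomeric_motif()].
#' @return List with `status` (`"canonical"`, `"variant"` or `"absent"`)
#'   and `offset` (1-based position, NA if absent).
#' @export
scan_telomeric <- function(tir, motif = telomeric_motif()) {
  tir <- clean_nuc(tir)
  for (st in c("canonical", "variant")) {
    off <- regexpr(motif[[st]], tir, fixed = TRUE)
    if (off > 0) return(list(status = st, offset = as.integer(off)))
  }
  list(status = "absent", offset = NA_integer_)
}

#' Detect terminal inverted repeats by end self-alignment
#'
#' For each element, a window around the 5' end of the ORF envelope is
#' locally aligned against the reverse complement of a window around the 3'
#' end. An accepted pair (length >= `min_len`, similarity >= `min_sim`)
#' extends the element span to the TIR termini and sets `n_tirs = 2`. When
#' no pair is found, each window is scanned for the telomeric motif and
#' `n_tirs` counts the sides that carry it.
#'
#' @param ann A `tbe_annotation`.
#' @param genome The genome searched.
#' @param window_out,window_in Window extent (bp) outside and inside the ORF
#'   envelope.
#' @param min_len Minimum accepted alignment length (columns).
#' @param min_sim Minimum accepted percent similarity.
#' @return The annotation with TIR columns (`tir_lstart` .. `tir_rend`,
#'   `tir_similarity`, `n_tirs`) filled and spans extended.
#' @export
detect_tir <- function(ann, genome, window_out = 400, window_in = 100,
                       min_len = 20, min_sim = 70) {
  el <- ann$elements
  if (!nrow(el)) return(ann)
  if (!is(genome, "DNAStringSet")) genome <- as_genome(genome)
  for (cn in c("tir_lstart", "tir_lend", "tir_rstart", "tir_rend")) {
    el[[cn]] <- NA_integer_
  }
  el$tir_similarity <- NA_real_
  el$n_tirs <- 0L
  for (i in seq_len(nrow(el))) {
    ctg <- as.character(genome[[el$contig[i]]])
    clen <- nchar(ctg)
    es <- el$env_start[i]
    ee <- el$env_end[i]
    ls <- max(1L, es - window_out)
    le <- min(clen, es + window_in - 1L)
    rs <- max(1L, ee - window_in + 1L)
    re <- min(clen, ee + window_out)
    lw <- if (le >= ls) substr(ctg, ls, le) else ""
    rw <- if (re >= rs) substr(ctg, rs, re) else ""
    found <- FALSE
    if (nchar(lw) >= min_len && nchar(rw) >= min_len) {
      al <- nt_align(lw, revcomp(rw), type = "local")
      sim <- 100 * al$matches / al$columns
      if (al$columns >= min_len && sim >= min_sim) {
        tls <- ls + al$p_start - 1L
        tle <- ls + al$p_end - 1L
        trs <- re - al$s_end + 1L
        tre <- re - al$s_start + 1L
        # local alignment trims mutated TIR tips; the telomeric motif at
        # the element terminus is a mismatch-tolerant anchor for the true
        # outer ends (the junction where the target-site duplication sits)
        snapl <- snap_to_motif(lw, al$p_start)
        if (!is.na(snapl)) tls <- ls + snapl - 1L
        snapr <- snap_to_motif(revcomp(rw), al$s_start)
        if (!is.na(snapr)) tre <- re - snapr + 1L
        if (tls < trs) {
          el$tir_lstart[i] <- tls
          el$tir_lend[i] <- tle
          el$tir_rstart[i] <- trs
          el$tir_rend[i] <- tre
          el$tir_similarity[i] <- sim
          el$n_tirs[i] <- 2L
          el$start[i] <- min(el$start[i], tls)
          el$end[i] <- max(el$end[i], tre)
          found <- TRUE
        }
      }
    }
    if (!found) {
      n <- 0L
      if (nzchar(lw) && scan_telomeric(lw)$status != "absent") n <- n + 1L
      if (nzchar(rw) &&
          scan_telomeric(revcomp(rw))$status != "absent") n <- n + 1L
      el$n_tirs[i] <- n
    }
  }
  ann$elements <- el
  ann
}

#' Call target-site duplications from element flanks
#'
#' Reports the largest k in `k_range` for which the k-mer immediately 5' of
#' the element equals the k-mer immediately 3' of it (exact identity; a
#' target-site duplication is a duplication, so mismatched flanks yield no
#' call).
#'
#' @param ann A `tbe_annotation` (spans TIR-extended where available).
#' @param genome The genome.
#' @param k_range Integer range of duplication lengths searched.
#' @return The annotation with a `tsd` column (NA when no call).
#' @export
call_tsd <- function(ann, genome, k_range = 2:10) {
  el <- ann$elements
  if (!nrow(el)) return(ann)
  if (!is(genome, "DNAStringSet")) genome <- as_genome(genome)
  el$tsd <- NA_character_
  kmax <- max(k_range)
  for (i in seq_len(nrow(el))) {
    ctg <- as.character(genome[[el$contig[i]]])
    s <- el$start[i]
    e <- el$end[i]
    if (s - kmax < 1L || e + kmax > nchar(ctg)) next
    for (k in sort(k_range, decreasing = TRUE)) {
      left <- substr(ctg, s - k, s - 1L)
      right <- substr(ctg, e + 1L, e + k)
      if (left == right && !grepl("N", left, fixed = TRUE)) {
        el$tsd[i] <- left
        break
      }
    }
  }
  ann$elements <- el
  ann
}

# Anchor a TIR outer end on the telomeric motif near an approximate
# position. Returns the implied motif start in window coordinates (the
# local alignment of the motif may itself trim a mutated first base, so the
# start is back-projected from the aligned offset), or NA when no
# convincing motif (score allows ~4 mismatches in 17 nt) lies within
# max_shift of the approximate position.
snap_to_motif <- function(window, approx_pos, max_shift = 25,
                          min_score = 14) {
  lo <- max(1L, approx_pos - max_shift - 17L)
  hi <- min(nchar(window), approx_pos + max_shift + 17L)
  if (hi - lo + 1L < 10L) return(NA_integer_)
  sub <- substr(window, lo, hi)
  al <- nt_align(telomeric_motif()$canonical, sub, type = "local")
  if (al$score < min_score) return(NA_integer_)
  implied <- lo + (al$s_start - 1L) - (al$p_start - 1L)
  if (abs(implied - approx_pos) > max_shift) return(NA_integer_)
  implied
}

stat_mode <- function(x) {
  if (!length(x)) return(list(mode = NA_integer_, fraction = NA_real_))
  tab <- table(x)
  cands <- as.integer(names(tab)[tab == max(tab)])
  list(mode = min(cands), fraction = max(tab) / length(x))
}

#' TIR-to-ORF distance statistics
#'
#' Distances in bp between the inner end of the 5' TIR and the 42kD start
#' codon, and between the 57kD ORF end and the inner end of the 3' TIR, per
#' family. The mode is the most frequent distance (ties broken by the
#' smaller distance).
#'
#' @param ann A `tbe_annotation` with TIRs detected and families assigned.
#' @return Data frame: family, side (`tir_42` or `57_tir`), n, mode,
#'   fraction_at_mode. Distances per family are attached as
#'   `attr(, "distances")`.
#' @export
distance_stats <- function(ann) {
  el <- ann$elements
  el <- el[el$completeness == "complete" & el$n_tirs == 2L &
             !is.na(el$orf42_start) & !is.na(el$orf57_start), , drop = FALSE]
  fams <- unique(ifelse(is.na(el$family), "unclassified", el$family))
  out <- list()
  dists <- list()
  for (fam in sort(fams)) {
    w <- el[ifelse(is.na(el$family), "unclassified", el$family) == fam, ,
            drop = FALSE]
    plus <- w$strand == "+"
    d5 <- ifelse(plus, w$orf42_start - w$tir_lend - 1L,
                 w$tir_rstart - w$orf42_end - 1L)
    d3 <- ifelse(plus, w$tir_rstart - w$orf57_end - 1L,
                 w$orf57_start - w$tir_lend - 1L)
    for (side in c("tir_42", "57_tir")) {
      d <- if (side == "tir_42") d5 else d3
      m <- stat_mode(d)
      out[[length(out) + 1L]] <- data.frame(
        family = fam, side = side, n = length(d), mode = m$mode,
        fraction_at_mode = m$fraction, stringsAsFactors = FALSE)
    }
    dists[[fam]] <- list(tir_42 = d5, `57_tir` = d3)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(family = character(0), side = character(0), n = integer(0),
               mode = integer(0), fraction_at_mode = numeric(0))
  attr(res, "distances") <- dists
  res
}

#' Greedy centroid clustering and consensus of TIR sequences
#'
#' UCLUST-style: sequences are sorted longest-first; each joins the first
#' centroid with global-alignment identity at or above the threshold, else
#' founds a new centroid. The cluster consensus is the per-position majority
#' over a centroid-anchored alignment of the members.
#'
#' @param seqs Character vector of TIR sequences.
#' @param identity_threshold Identity (0-1) required to join a centroid.
#' @return Data frame with columns `consensus` and `n_members`; member
#'   indices are attached as `attr(, "members")`.
#' @export
tir_consensus <- function(seqs, identity_threshold = 0.9) {
  stopifnot(length(seqs) >= 1)
  seqs <- vapply(seqs, clean_nuc, character(1), USE.NAMES = FALSE)
  ord <- order(nchar(seqs), decreasing = TRUE)
  centroids <- integer(0)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      al <- nt_align(seqs[centroids[ci]], seqs[i], type = "global")
      if (al$matches / al$columns >= identity_threshold) {
        members[[ci]] <- c(members[[ci]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      members[[length(centroids)]] <- i
    }
  }
  cons <- vapply(seq_along(centroids), function(ci) {
    cen <- seqs[centroids[ci]]
    cchars <- strsplit(cen, "")[[1]]
    votes <- lapply(cchars, function(ch) c(ch))
    for (mi in setdiff(members[[ci]], centroids[ci])) {
      al <- Biostrings::pairwiseAlignment(
        cen, seqs[mi], substitutionMatrix = nuc_submat(),
        gapOpening = 5, gapExtension = 2, type = "global")
      p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
      s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
      cpos <- 0L
      for (k in seq_along(p)) {
        if (p[k] != "-") {
          cpos <- cpos + 1L
          votes[[cpos]] <- c(votes[[cpos]], s[k])
        }
      }
    }
    res <- vapply(seq_along(votes), function(k) {
      tab <- sort(table(votes[[k]]), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      if (cchars[k] %in% top) cchars[k] else top[1L]
    }, character(1))
    paste(res[res != "-"], collapse = "")
  }, character(1))
  out <- data.frame(consensus = cons,
                    n_members = lengths(members),
                    stringsAsFactors = FALSE)
  attr(out, "members") <- members
  out
}

#' Extract detected TIR sequences from an annotation
#'
#' @param ann A `tbe_annotation` after [detect_tir()].
#' @param genome The genome.
#' @param family Optional family filter.
#' @return Character vector of TIR sequences (both TIRs of each element;
#'   the right TIR is reverse complemented onto the element 5' orientation).
#' @export
tir_sequences <- function(ann, genome, family = NULL) {
  el <- ann$elements
  el <- el[el$n_tirs == 2L, , drop = FALSE]
  if (!is.null(family)) el <- el[!is.na(el$family) & el$family == family, ]
  if (!nrow(el)) return(character(0))
  if (!is(genome, "DNAStringSet")) genome <- as_genome(genome)
  out <- character(0)
  for (i in seq_len(nrow(el))) {
    ctg <- as.character(genome[[el$contig[i]]])
    l <- substr(ctg, el$tir_lstart[i], el$tir_lend[i])
    r <- revcomp(substr(ctg, el$tir_rstart[i], el$tir_rend[i]))
    # both TIRs reported in the 5'-TIR orientation; on a minus-strand
    # element the genome-right TIR is the element's 5' TIR
    if (el$strand[i] == "-") {
      tmp <- l
      l <- r
      r <- tmp
    }
    out <- c(out, l, r)
  }
  out
}
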