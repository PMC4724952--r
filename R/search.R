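#' Scoring scheme for the translated search
#'
#' Houses the substitution matrix, affine gap penalties and the
#' Karlin-Altschul constants used for the approximate E-value. The constants
#' (lambda = 0.267, K = 0.041) are the published gapped BLOSUM62 values for
#' gap costs 11/1; E-values are therefore approximate and the threshold
#' semantics differ slightly from NCBI BLAST.
#'
#' @param matrix Name of the substitution matrix (a Biostrings data set).
#' @param gap_open,gap_ext Affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_ext`.
#' @param lambda,K Karlin-Altschul constants for `E = K m n exp(-lambda S)`.
#' @param evalue E-value acceptance threshold for reported hits.
#' @return A list of class `tbe_scoring`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_ext = 1,
                           lambda = 0.267, K = 0.041, evalue = 1e-7) {
  stopifnot(gap_open > 0, gap_ext > 0, evalue > 0)
  submat <- get_submat(matrix)
  structure(list(matrix = matrix, submat = submat, gap_open = gap_open,
                 gap_ext = gap_ext, lambda = lambda, K = K, evalue = evalue),
            class = "tbe_scoring")
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  as.matrix(get(name, envir = e))
}

aa_encode <- function(prot, submat) {
  lut <- rep.int(match("X", rownames(submat)), 127L)
  lut[utf8ToInt(paste(rownames(submat), collapse = ""))] <-
    seq_len(nrow(submat))
  codes <- utf8ToInt(prot)
  codes[codes > 127L] <- utf8ToInt("X")
  lut[codes] - 1L
}

#' Six-frame translation with coordinate maps
#'
#' Translates a contig in all six reading frames under the ciliate code.
#' Frames -1..-3 derive from the reverse complement. Protein positions map
#' back to unique codon intervals via [frame_to_genomic()].
#'
#' @param seq Contig nucleotide sequence (character or `DNAString`).
#' @param code Genetic code, see [genetic_code()].
#' @return A data frame with columns `frame` (-3..-1, 1..3) and `protein`.
#' @export
six_frame_translate <- function(seq, code = genetic_code(6)) {
  seq <- clean_nuc(seq)
  n <- nchar(seq)
  gc <- Biostrings::getGeneticCode(as.character(code$table_id))
  d <- if (n) Biostrings::DNAString(seq) else NULL
  rc <- if (n) Biostrings::reverseComplement(d) else NULL
  frames <- integer(0)
  prots <- character(0)
  for (f in 1:3) {
    for (sgn in c(1L, -1L)) {
      p <- ""
      if (n >= f + 2) {
        s <- if (sgn > 0) d else rc
        last <- f + 3L * ((n - f + 1L) %/% 3L) - 1L
        p <- as.character(Biostrings::translate(
          Biostrings::subseq(s, f, last), genetic.code = gc,
          if.fuzzy.codon = "X"))
      }
      frames <- c(frames, sgn * f)
      prots <- c(prots, p)
    }
  }
  data.frame(frame = frames, protein = prots, stringsAsFactors = FALSE)
}

#' Map protein-frame positions to genomic nucleotide coordinates
#'
#' @param frame Frame (-3..-1, 1..3).
#' @param p1,p2 First and last protein positions (1-based) of the span.
#' @param contig_len Contig length in bp.
#' @return `c(start, end)`, 1-based inclusive forward-strand coordinates.
#' @export
frame_to_genomic <- function(frame, p1, p2, contig_len) {
  f <- abs(frame)
  a <- f + 3L * (p1 - 1L)
  b <- f + 3L * p2 - 1L
  if (frame > 0) c(a, b) else c(contig_len - b + 1L, contig_len - a + 1L)
}

#' Map a genomic codon span back to protein-frame positions
#'
#' Inverse of [frame_to_genomic()] for codon-aligned spans.
#' @inheritParams frame_to_genomic
#' @param start,end Forward-strand nucleotide coordinates (1-based inclusive).
#' @return `c(p1, p2)` protein positions.
#' @export
genomic_to_frame <- function(frame, start, end, contig_len) {
  f <- abs(frame)
  if (frame > 0) {
    c((start - f) %/% 3L + 1L, (end + 1L - f) %/% 3L)
  } else {
    a <- contig_len - end + 1L
    b <- contig_len - start + 1L
    c((a - f) %/% 3L + 1L, (b + 1L - f) %/% 3L)
  }
}

empty_hits <- function() {
  data.frame(query = character(0), role = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             frame = integer(0), score = numeric(0), bitscore = numeric(0),
             evalue = numeric(0), pident = numeric(0), psim = numeric(0),
             qcov = numeric(0), stringsAsFactors = FALSE)
}

#' Translated local-alignment search of protein queries against a genome
#'
#' A six-frame Smith-Waterman search with affine gaps: every frame of every
#' contig is translated under the ciliate code and scanned with full dynamic
#' programming (no word seeding), so reported scores are exact local optima.
#' Non-overlapping hits per frame are extracted greedily by descending score;
#' hits with approximate E-value at or below the scheme threshold are
#' returned, trimmed to codon boundaries.
#'
#' @param queries Named character vector (or `AAStringSet`) of stop-free
#'   protein queries, length >= 10 aa each.
#' @param genome A `DNAStringSet` (or named character vector).
#' @param scheme A [scoring_scheme()].
#' @param roles Optional named character vector mapping query names to roles
#'   (`orf42`, `orf22`, `orf57`); defaults to the query names themselves.
#' @param min_raw_score Optional raw-score cutoff overriding the E-value
#'   threshold (used for oracle checks on tiny instances).
#' @param code Genetic code.
#' @return A data frame of hits, sorted by contig then start, with columns
#'   query, role, contig, start, end, strand, frame, score, bitscore,
#'   evalue, pident, psim (percent positives) and qcov (query coverage).
#' @export
search_protein <- function(queries, genome, scheme = scoring_scheme(),
                           roles = NULL, min_raw_score = NULL,
                           code = genetic_code(6)) {
  if (is(queries, "AAStringSet")) {
    queries <- stats::setNames(as.character(queries), names(queries))
  }
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    stop("queries must be named")
  }
  if (any(grepl("\\*", queries))) stop("queries must be stop-free proteins")
  if (any(nchar(queries) < 10)) stop("query length must be >= 10 aa")
  if (!is(genome, "DNAStringSet")) genome <- as_genome(genome)
  if (is.null(roles)) roles <- stats::setNames(names(queries), names(queries))
  n_total <- sum(Biostrings::width(genome))
  sm <- scheme$submat
  out <- list()
  for (ctg in names(genome)) {
    cseq <- as.character(genome[[ctg]])
    clen <- nchar(cseq)
    if (clen < 3) next
    frames <- six_frame_translate(cseq, code)
    enc <- lapply(frames$protein, function(p) {
      if (nchar(p) < 1) integer(0) else aa_encode(p, sm)
    })
    for (qn in names(queries)) {
      qstr <- queries[[qn]]
      qlen <- nchar(qstr)
      qv <- aa_encode(qstr, sm)
      smin <- if (!is.null(min_raw_score)) min_raw_score else {
        max(1, ceiling(log(scheme$K * qlen * n_total / scheme$evalue) /
                         scheme$lambda))
      }
      for (k in seq_len(nrow(frames))) {
        if (!length(enc[[k]])) next
        fr <- frames$frame[k]
        sv <- enc[[k]]
        # greedy non-overlapping extraction by divide and conquer: take
        # the best alignment of the segment, then recurse on the two
        # flanking subsegments (equivalent to greedy descending score over
        # the whole frame, since remaining candidates live in disjoint
        # segments)
        found <- list()
        segs <- list(c(1L, length(sv)))
        while (length(segs)) {
          seg <- segs[[length(segs)]]
          segs[[length(segs)]] <- NULL
          a <- seg[1]
          b <- seg[2]
          if (b - a + 1L < 3L) next
          E <- .sw_best_ends(qv, sv[a:b], sm, scheme$gap_open,
                             scheme$gap_ext)
          if (attr(E, "best") < smin) next
          j <- a + which.max(E) - 1L
          ws <- max(a, j - 2L * qlen)
          tb <- .sw_traceback(qv, sv[ws:j], sm, scheme$gap_open,
                              scheme$gap_ext)
          if (tb$score < smin) next
          ss <- ws + tb$s_start - 1L
          se <- ws + tb$s_end - 1L
          found[[length(found) + 1L]] <- list(ss = ss, se = se, tb = tb)
          segs[[length(segs) + 1L]] <- c(a, ss - 1L)
          segs[[length(segs) + 1L]] <- c(se + 1L, b)
        }
        for (hcand in found) {
          tb <- hcand$tb
          gcoord <- frame_to_genomic(fr, hcand$ss, hcand$se, clen)
          S <- tb$score
          out[[length(out) + 1L]] <- data.frame(
            query = qn, role = unname(roles[qn]), contig = ctg,
            start = gcoord[1], end = gcoord[2],
            strand = if (fr > 0) "+" else "-", frame = fr, score = S,
            bitscore = (scheme$lambda * S - log(scheme$K)) / log(2),
            evalue = scheme$K * qlen * n_total * exp(-scheme$lambda * S),
            pident = 100 * tb$matches / tb$columns,
            psim = 100 * tb$positives / tb$columns,
            qcov = tb$q_aligned / qlen, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty_hits())
  hits <- do.call(rbind, out)
  if (is.null(min_raw_score)) hits <- hits[hits$evalue <= scheme$evalue, ]
  hits <- hits[order(hits$contig, hits$start), ]
  rownames(hits) <- NULL
  hits
}
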