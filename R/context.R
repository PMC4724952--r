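elements_granges <- function(ann) {
  el <- ann$elements
  GenomicRanges::GRanges(el$contig, IRanges::IRanges(el$start, el$end),
                         strand = el$strand,
                         element_id = el$element_id)
}

#' Distance from each element to the nearest track interval
#'
#' Zero if the element overlaps an interval; `Inf` when the element's
#' contig carries no track interval (such elements count as "not near").
#' Tracks are strandless; distances are measured from the element span
#' boundary (TIR-extended where available).
#'
#' @param ann A `tbe_annotation` (or a `GRanges`).
#' @param track A `GRanges` annotation track.
#' @return Numeric vector of bp distances, one per element.
#' @export
nearest_track_distance <- function(ann, track) {
  gr <- if (is(ann, "GRanges")) ann else elements_granges(ann)
  if (!length(gr)) return(numeric(0))
  out <- rep(Inf, length(gr))
  if (!length(track)) return(out)
  hits <- GenomicRanges::distanceToNearest(gr, track, ignore.strand = TRUE)
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

#' Fraction of genome covered by a track
#'
#' Intervals are merged before summation, so the result is invariant to
#' interval order and splitting.
#'
#' @param track A `GRanges`.
#' @param genome The genome (`DNAStringSet`) or total length in bp.
#' @return Covered fraction in `[0, 1]`.
#' @export
genome_fraction <- function(track, genome) {
  total <- if (is(genome, "DNAStringSet")) {
    sum(as.numeric(Biostrings::width(genome)))
  } else as.numeric(genome)
  if (!length(track)) return(0)
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(
    track, ignore.strand = TRUE)))) / total
}

#' Chi-squared enrichment of elements near a track
#'
#' Compares the observed fraction of elements within `window_bp` of the
#' track against an expected fraction (typically the track's genome-space
#' fraction, a deliberately conservative null: the probability that a
#' uniformly placed element falls within the window is somewhat larger
#' than the covered fraction). One degree of freedom, two-sided p from the
#' upper chi-squared tail.
#'
#' @param n_near Number of elements within the window.
#' @param n_total Total elements (>= 1).
#' @param expected Expected near fraction, strictly between 0 and 1.
#' @param window_bp Window used to compute `n_near` (recorded).
#' @param correct Apply the Yates continuity correction (default off).
#' @return List of class `enrichment_result`: n_elements, n_near,
#'   observed_fraction, expected_fraction, window_bp, chi2, dof, p_value.
#' @export
enrichment_test <- function(n_near, n_total, expected, window_bp = 500,
                            correct = FALSE) {
  stopifnot(n_total >= 1, n_near >= 0, n_near <= n_total)
  if (expected <= 0 || expected >= 1) {
    stop("expected fraction must be strictly between 0 and 1")
  }
  obs <- c(n_near, n_total - n_near)
  exp <- c(expected, 1 - expected) * n_total
  dev <- abs(obs - exp)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / exp)
  structure(list(n_elements = n_total, n_near = n_near,
                 observed_fraction = n_near / n_total,
                 expected_fraction = expected, window_bp = window_bp,
                 chi2 = chi2, dof = 1L,
                 p_value = stats::pchisq(chi2, 1, lower.tail = FALSE)),
            class = "enrichment_result")
}

#' Enrichment of annotated elements near a track
#'
#' Convenience wrapper: computes near counts via
#' [nearest_track_distance()] and the expected fraction via
#' [genome_fraction()], then runs [enrichment_test()].
#'
#' @param ann A `tbe_annotation` (or `GRanges` of elements).
#' @param track A `GRanges` track.
#' @param genome The genome.
#' @param window_bp "Near" window in bp.
#' @param expected Expected fraction; defaults to the track's genome
#'   fraction.
#' @param correct Continuity correction flag.
#' @return An `enrichment_result`.
#' @export
enrichment_near_track <- function(ann, track, genome, window_bp = 500,
                                  expected = NULL, correct = FALSE) {
  d <- nearest_track_distance(ann, track)
  if (is.null(expected)) expected <- genome_fraction(track, genome)
  enrichment_test(sum(d <= window_bp), length(d), expected, window_bp,
                  correct)
}
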