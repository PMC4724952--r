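# cache for the codon site/difference lookup tables
.tbe_cache <- new.env(parent = emptyenv())

#' Nei-Gojobori synonymous/nonsynonymous site counts per codon
#'
#' For each sense codon, each position contributes the fraction of its
#' viable single-nucleotide changes (changes to stop codons excluded from
#' numerator and denominator) that are synonymous; the three positions sum
#' to the codon's synonymous site count s, with n = 3 - s.
#'
#' @param code Genetic code.
#' @return Data frame with codon, s and n (NA for stop codons).
#' @export
ng86_site_counts <- function(code = genetic_code(6)) {
  key <- paste0("sites", code$table_id)
  if (!is.null(.tbe_cache[[key]])) return(.tbe_cache[[key]])
  codons <- all_codons()
  b <- c("A", "C", "G", "T")
  s <- rep(NA_real_, 64)
  for (k in seq_along(codons)) {
    cd <- codons[k]
    if (code$map[[cd]] == "*") next
    tot <- 0
    for (pos in 1:3) {
      syn <- 0L
      viable <- 0L
      for (alt in setdiff(b, substr(cd, pos, pos))) {
        nc <- cd
        substr(nc, pos, pos) <- alt
        if (code$map[[nc]] == "*") next
        viable <- viable + 1L
        if (code$map[[nc]] == code$map[[cd]]) syn <- syn + 1L
      }
      if (viable > 0) tot <- tot + syn / viable
    }
    s[k] <- tot
  }
  out <- data.frame(codon = codons, s = s, n = ifelse(is.na(s), NA, 3 - s))
  .tbe_cache[[key]] <- out
  out
}

# pathway-averaged synonymous/nonsynonymous differences between two codons;
# minimal mutational pathways through stop codons are excluded, and a pair
# whose every pathway crosses a stop contributes its differences as
# nonsynonymous
ng86_diff_counts <- function(c1, c2, code = genetic_code(6)) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0("diff", code$table_id, c1, c2)
  if (!is.null(.tbe_cache[[key]])) return(.tbe_cache[[key]])
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- switch(as.character(length(pos)),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                      c(3, 1, 2), c(3, 2, 1)), function(o) pos[o]))
  sd_tot <- 0
  nd_tot <- 0
  n_valid <- 0L
  for (perm in perms) {
    cur <- c1
    sdp <- 0L
    ndp <- 0L
    ok <- TRUE
    for (p in perm) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code$map[[nxt]] == "*") {
        ok <- FALSE
        break
      }
      if (code$map[[nxt]] == code$map[[cur]]) sdp <- sdp + 1L else
        ndp <- ndp + 1L
      cur <- nxt
    }
    if (ok) {
      sd_tot <- sd_tot + sdp
      nd_tot <- nd_tot + ndp
      n_valid <- n_valid + 1L
    }
  }
  out <- if (n_valid > 0) {
    c(sd = sd_tot / n_valid, nd = nd_tot / n_valid)
  } else {
    c(sd = 0, nd = length(pos))
  }
  .tbe_cache[[key]] <- out
  out
}

split_codons <- function(cds) {
  cds <- clean_nuc(cds)
  stopifnot(nchar(cds) %% 3 == 0)
  if (nchar(cds) == 0) return(character(0))
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Pairwise codon alignment of two repaired coding sequences
#'
#' Globally aligns the table-6 translations, threads the alignment back
#' onto codons, and drops columns containing a gap or an N-containing
#' codon in either row.
#'
#' @param cds_a,cds_b Repaired coding sequences (no internal stops; N
#'   allowed, masked columns are dropped).
#' @param min_codons Minimum retained columns; shorter alignments are
#'   excluded (`n_codons = 0` with the exclusion `reason` filled).
#' @param code Genetic code.
#' @return List of class `codon_alignment`: `codons_a`, `codons_b`,
#'   `n_codons`, `reason` (NULL unless excluded).
#' @export
pairwise_codon_align <- function(cds_a, cds_b, min_codons = 30,
                                 code = genetic_code(6)) {
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  tr <- function(cod) {
    aa <- unname(code$map[cod])
    aa[is.na(aa) | grepl("N", cod)] <- "X"
    aa
  }
  aa_a <- tr(ca)
  aa_b <- tr(cb)
  if (any(aa_a == "*") || any(aa_b == "*")) {
    stop("coding sequences must be stop-free after repair")
  }
  submat <- get_submat("BLOSUM62")
  al <- Biostrings::pairwiseAlignment(
    paste(aa_a, collapse = ""), paste(aa_b, collapse = ""),
    substitutionMatrix = submat, gapOpening = 11, gapExtension = 1,
    type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- 0L
  ib <- 0L
  keep_a <- integer(0)
  keep_b <- integer(0)
  for (k in seq_along(p)) {
    if (p[k] != "-") ia <- ia + 1L
    if (s[k] != "-") ib <- ib + 1L
    if (p[k] != "-" && s[k] != "-" && p[k] != "X" && s[k] != "X") {
      keep_a <- c(keep_a, ia)
      keep_b <- c(keep_b, ib)
    }
  }
  if (length(keep_a) < min_codons) {
    return(structure(list(codons_a = character(0), codons_b = character(0),
                          n_codons = 0L,
                          reason = paste0("fewer than ", min_codons,
                                          " retained codons")),
                     class = "codon_alignment"))
  }
  structure(list(codons_a = ca[keep_a], codons_b = cb[keep_b],
                 n_codons = length(keep_a), reason = NULL),
            class = "codon_alignment")
}

#' Nei-Gojobori (1986) pairwise dN/dS under the ciliate code
#'
#' Counts synonymous/nonsynonymous sites and pathway-averaged differences,
#' applies the Jukes-Cantor correction `d = -3/4 log(1 - 4p/3)`, and flags
#' estimates by the synonymous-rate validity filter: estimates with dS
#' below 0.01 or above 5, or with an undefined correction (p >= 3/4), are
#' marked invalid.
#'
#' @param aln A `codon_alignment`.
#' @param code Genetic code.
#' @return List of class `rate_estimate`: S, N, Sd, Nd, pS, pN, dS, dN,
#'   omega, valid, invalid_reason.
#' @export
ng86 <- function(aln, code = genetic_code(6)) {
  sites <- ng86_site_counts(code)
  rownames(sites) <- sites$codon
  sa <- sites[aln$codons_a, ]
  sb <- sites[aln$codons_b, ]
  S <- (sum(sa$s) + sum(sb$s)) / 2
  N <- (sum(sa$n) + sum(sb$n)) / 2
  Sd <- 0
  Nd <- 0
  for (k in seq_len(aln$n_codons)) {
    d <- ng86_diff_counts(aln$codons_a[k], aln$codons_b[k], code)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  reason <- NULL
  if (is.na(dS) || is.na(dN)) {
    reason <- "correction undefined (p >= 3/4)"
  } else if (dS < 0.01) {
    reason <- "dS below 0.01"
  } else if (dS > 5) {
    reason <- "dS above 5"
  }
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 valid = is.null(reason),
                 invalid_reason = if (is.null(reason)) NA_character_ else
                   reason),
            class = "rate_estimate")
}

#' Pairwise dN/dS estimates over a set of coding sequences
#'
#' @param cds Named character vector of repaired coding sequences.
#' @param pairs Optional 2-column matrix of name pairs; defaults to all
#'   distinct unordered pairs.
#' @param code Genetic code.
#' @return Data frame: id_a, id_b, n_codons, S, N, Sd, Nd, dS, dN, omega,
#'   valid, reason.
#' @export
ng86_pairs <- function(cds, pairs = NULL, code = genetic_code(6)) {
  if (is.null(pairs)) {
    stopifnot(length(cds) >= 2)
    pairs <- t(utils::combn(names(cds), 2))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1]
    b <- pairs[k, 2]
    aln <- pairwise_codon_align(cds[[a]], cds[[b]], code = code)
    if (aln$n_codons == 0L) {
      return(data.frame(id_a = a, id_b = b, n_codons = 0L, S = NA, N = NA,
                        Sd = NA, Nd = NA, dS = NA, dN = NA, omega = NA,
                        valid = FALSE, reason = aln$reason,
                        stringsAsFactors = FALSE))
    }
    e <- ng86(aln, code)
    data.frame(id_a = a, id_b = b, n_codons = aln$n_codons, S = e$S,
               N = e$N, Sd = e$Sd, Nd = e$Nd, dS = e$dS, dN = e$dN,
               omega = e$omega, valid = e$valid,
               reason = ifelse(e$valid, "", e$invalid_reason),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summary of dN/dS distributions by group
#'
#' Only valid estimates enter the box-plot summary; excluded pairs are
#' tallied by reason.
#'
#' @param est Data frame from [ng86_pairs()] with an added `group` column.
#' @return Data frame per group: n (valid pairs), median, q1, q3 of omega,
#'   and `excluded` ("reason:count" tallies).
#' @export
omega_distribution <- function(est) {
  stopifnot("group" %in% names(est))
  rows <- lapply(split(est, est$group), function(g) {
    v <- g$omega[g$valid]
    v <- v[!is.na(v)]
    exc <- table(g$reason[!g$valid])
    data.frame(
      group = g$group[1], n = length(v),
      median = if (length(v)) stats::median(v) else NA_real_,
      q1 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
      q3 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
      excluded = if (length(exc)) {
        paste(paste0(names(exc), ":", exc), collapse = "; ")
      } else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact counting test of purifying selection (dN/dS < 1)
#'
#' Under neutrality the probability that a difference is nonsynonymous
#' equals the nonsynonymous site fraction N/(N+S). The test is an exact
#' binomial tail: the one-sided (purifying) p-value is the probability of
#' observing at most the rounded Nd nonsynonymous differences among the
#' rounded Nd+Sd total. When counts are pooled across pairs the pairs are
#' not independent; the result carries that caveat.
#'
#' @param S,N,Sd,Nd Site and difference counts (possibly summed over
#'   pairs; fractional counts are rounded for the exact test).
#' @return List of class `neutrality_test`: statistic (observed
#'   nonsynonymous fraction of differences), expected (N/(N+S)), p_value,
#'   direction, note.
#' @export
neutrality_test <- function(S, N, Sd, Nd) {
  stopifnot(Nd + Sd >= 1, S > 0 || N > 0)
  p0 <- N / (N + S)
  x <- round(Nd)
  n <- round(Nd + Sd)
  p <- stats::pbinom(x, n, p0)
  structure(list(statistic = x / n, expected = p0, p_value = p,
                 direction = "purifying (Nd below expectation)",
                 note = "pooled counts: pairs are not independent"),
            class = "neutrality_test")
}
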