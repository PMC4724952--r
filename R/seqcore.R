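#' @useDynLib tbescan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Ciliate nuclear genetic code (translation table 6)
#'
#' Returns the codon table used throughout the package. Under the ciliate
#' nuclear code, TAA and TAG encode glutamine and TGA is the sole stop codon.
#'
#' @param table_id Genetic code table identifier; only `6` (ciliate nuclear)
#'   and `1` (standard) are supported.
#' @return A list with elements `table_id`, `map` (named character vector of
#'   length 64, codon to one-letter amino acid, stops as `"*"`) and
#'   `stop_codons`.
#' @examples
#' code <- genetic_code(6)
#' code$map[c("TAA", "TAG", "TGA")]
#' @export
genetic_code <- function(table_id = 6) {
  stopifnot(table_id %in% c(1, 6))
  map <- Biostrings::getGeneticCode(as.character(table_id))
  list(table_id = table_id, map = map,
       stop_codons = names(map)[map == "*"])
}

#' Translate a nucleotide sequence
#'
#' Translates codon by codon under the given genetic code. A trailing partial
#' codon is dropped with a warning. Codons containing any character other
#' than A/C/G/T translate to `"X"`; stop codons render as `"*"`.
#'
#' @param nuc Nucleotide sequence (character scalar or `DNAString`).
#' @param code A genetic code as returned by [genetic_code()].
#' @return Protein sequence as a character scalar (`""` for empty input).
#' @examples
#' translate_cds("TAATAG")     # "QQ" under the ciliate code
#' translate_cds("TGA")        # "*"
#' @export
translate_cds <- function(nuc, code = genetic_code(6)) {
  nuc <- clean_nuc(nuc)
  n <- nchar(nuc)
  if (n == 0L) return("")
  if (n %% 3L != 0L) {
    warning("sequence length not divisible by 3; dropping trailing ",
            n %% 3L, " nt")
    nuc <- substr(nuc, 1L, n - n %% 3L)
    if (nchar(nuc) == 0L) return("")
  }
  codons <- substring(nuc, seq(1L, nchar(nuc), 3L), seq(3L, nchar(nuc), 3L))
  aa <- unname(code$map[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# uppercase, U -> T; accepts DNAString or character
clean_nuc <- function(nuc) {
  if (is(nuc, "XString") || is(nuc, "XStringSet")) nuc <- as.character(nuc)
  chartr("u", "T", chartr("U", "T", toupper(nuc)))
}

#' Reverse complement
#'
#' @param nuc Nucleotide sequence over the alphabet A/C/G/T/N (case
#'   insensitive, U tolerated). Any other character is rejected with its
#'   position.
#' @return The reverse complement, a character scalar.
#' @examples
#' revcomp("CAAAAC")  # "GTTTTG"
#' @export
revcomp <- function(nuc) {
  nuc <- clean_nuc(nuc)
  bad <- regexpr("[^ACGTN]", nuc)
  if (bad > 0L) {
    stop("non-IUPAC character '", substr(nuc, bad, bad),
         "' at position ", bad)
  }
  if (nchar(nuc) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nuc)))
}

#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased and U is mapped to T on read. Duplicate contig
#' names are an error.
#'
#' @param path Path to a FASTA file (arbitrary line wrapping).
#' @return A named [Biostrings::DNAStringSet] of contigs.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    stop("duplicate contig name: ",
         names(x)[duplicated(names(x))][1L])
  }
  if (any(!nzchar(names(x)))) stop("empty contig name in ", path)
  as_genome(as.character(x))
}

#' Coerce named sequences to a genome assembly
#'
#' @param x Named character vector of contig sequences (or `DNAStringSet`).
#' @return A named `DNAStringSet`, uppercased with U mapped to T.
#' @export
as_genome <- function(x) {
  if (is(x, "DNAStringSet")) x <- as.character(x)
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  if (anyDuplicated(names(x))) stop("duplicate contig name")
  Biostrings::DNAStringSet(vapply(x, clean_nuc, character(1)))
}

#' Write a genome assembly to FASTA
#'
#' @param genome A `DNAStringSet` (or named character vector).
#' @param path Output path; sequences are wrapped at 70 columns.
#' @export
write_genome <- function(genome, path) {
  if (!is(genome, "DNAStringSet")) genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read an annotation track (BED or GFF3)
#'
#' Coordinate conventions (0-based half-open BED, 1-based inclusive GFF3) are
#' handled by rtracklayer; intervals are returned as a `GRanges` in the
#' package's internal 1-based closed convention.
#'
#' @param path Path to a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @param genome Optional genome (`DNAStringSet`); if given, intervals
#'   exceeding their contig are an error.
#' @return A [GenomicRanges::GRanges].
#' @export
read_track <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path)
  if (!is.null(genome)) validate_track(gr, genome)
  gr
}

validate_track <- function(gr, genome) {
  len <- stats::setNames(Biostrings::width(genome), names(genome))
  ctg <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(ctg), names(len))
  if (length(unknown)) stop("track contig not in genome: ", unknown[1L])
  over <- GenomicRanges::end(gr) > len[ctg] | GenomicRanges::start(gr) < 1L
  if (any(over)) {
    stop("interval exceeds contig ", ctg[which(over)[1L]],
         " (", GenomicRanges::start(gr)[which(over)[1L]], "-",
         GenomicRanges::end(gr)[which(over)[1L]], ")")
  }
  invisible(gr)
}

#' Write an annotation track
#'
#' @param gr A `GRanges`.
#' @param path Output path; format chosen from the extension (`.bed`,
#'   `.gff3`/`.gff`).
#' @export
write_track <- function(gr, path) {
  rtracklayer::export(gr, path)
  invisible(path)
}

#' Element annotation as GFF3
#'
#' Writes one `mobile_genetic_element` feature per element with child `CDS`
#' rows for the ORF hits and `inverted_repeat` rows for detected TIRs.
#'
#' @param ann A `tbe_annotation` (see [assemble_elements()]).
#' @param path Output path.
#' @export
write_gff3 <- function(ann, path) {
  el <- ann$elements
  feats <- list()
  if (nrow(el)) {
    g <- GenomicRanges::GRanges(el$contig,
      IRanges::IRanges(el$start, el$end), strand = el$strand)
    S4Vectors::mcols(g)$type <- "mobile_genetic_element"
    S4Vectors::mcols(g)$ID <- el$element_id
    S4Vectors::mcols(g)$completeness <- el$completeness
    S4Vectors::mcols(g)$family <- el$family
    feats$elements <- g
  }
  h <- ann$hits
  if (!is.null(h) && nrow(h)) {
    g <- GenomicRanges::GRanges(h$contig,
      IRanges::IRanges(h$start, h$end), strand = h$strand)
    S4Vectors::mcols(g)$type <- "CDS"
    S4Vectors::mcols(g)$ID <- paste0(h$element_id, ".", h$role)
    S4Vectors::mcols(g)$Parent <- h$element_id
    S4Vectors::mcols(g)$phase <- 0L
    feats$cds <- g
  }
  if ("tir_lstart" %in% names(el)) {
    has <- !is.na(el$tir_lstart)
    if (any(has)) {
      g <- GenomicRanges::GRanges(
        rep(el$contig[has], 2L),
        IRanges::IRanges(c(el$tir_lstart[has], el$tir_rstart[has]),
                         c(el$tir_lend[has], el$tir_rend[has])))
      S4Vectors::mcols(g)$type <- "inverted_repeat"
      S4Vectors::mcols(g)$Parent <- rep(el$element_id[has], 2L)
      feats$tirs <- g
    }
  }
  all <- suppressWarnings(do.call(c, unname(feats)))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}
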