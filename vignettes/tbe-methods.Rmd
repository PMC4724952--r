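---
title: "Methods: annotating and analysing telomere-bearing element transposons"
author: "tbescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and analysing telomere-bearing element transposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The biological problem

Telomere-bearing elements (TBEs) are Tc1/*mariner* DNA transposons of
stichotrich ciliates such as *Oxytricha trifallax*. They live in the
germline (micronuclear) genome, are flanked by terminal inverted repeats
(TIRs) that begin with telomeric repeat sequence, and encode three ORFs: a
42kD DDE transposase, a 22kD ORF of unknown function, and a 57kD ORF with
zinc-finger and kinase domains. The 22kD ORF is inverted relative to the
other two, and a ~200 bp tandem-repeat spacer separates the 22kD and 57kD
ORFs. Insertion creates a short target-site duplication (TSD) on both
flanks. The elements fall into four families (TBE1, TBE2.1, TBE2.2, TBE3)
whose 42kD/22kD genes barely distinguish the TBE2 subfamilies while their
57kD genes are clearly distinct. Because the transposase participates in
the programmed genome rearrangements that build the somatic nucleus, the
question of whether the element-encoded genes evolve under purifying
selection (dN/dS well below 1) is of real biological interest.

`tbescan` implements the full annotation-and-evolution analysis for such
elements: protein-guided element discovery, completeness classification,
TIR/TSD characterisation, family clustering, ORF-integrity profiling under
the ciliate nuclear genetic code, pairwise dN/dS with a counting-based
test of purifying selection, and positional enrichment relative to
annotation tracks (macronuclear-destined sequences, satellite repeats).
A synthetic-genome generator with complete implant ground truth makes
every stage testable without any external data.

# Translation: the ciliate nuclear code

All translation uses NCBI genetic code 6, in which TAA and TAG encode
glutamine and TGA is the sole stop codon. This matters everywhere: a TAA
in an ORF is a sense codon, not degeneracy evidence, and premature-stop
detection reduces to in-frame TGA. Codons containing N translate to X.

# The translated search

Protein queries for the three ORFs are searched against all six reading
frames of every contig with full Smith-Waterman dynamic programming
(affine gaps; a gap of length $k$ costs $o + ke$ with BLOSUM62 and
$o = 11$, $e = 1$). There is no word seeding: reported scores are exact
local optima, which lets a brute-force oracle verify them cell for cell.
Non-overlapping hits per frame are extracted greedily by descending score
using divide and conquer: the segment's best alignment is located with a
linear-memory scan, recovered by a windowed traceback, and the flanking
subsegments are searched recursively. Because the remaining candidates
live in disjoint segments, this is equivalent to globally greedy
descending-score extraction.

E-values use the Karlin-Altschul form $E = K m n e^{-\lambda S}$ with the
published gapped BLOSUM62 constants $\lambda = 0.267$, $K = 0.041$. These
are approximate — the intent is a threshold of the same spirit as a
translated-BLAST cutoff of $10^{-7}$, not bit-identical BLAST statistics.
Hits are trimmed to codon boundaries so coding-sequence extraction is
unambiguous.

# Element assembly

Hits are chained per contig. Frameshifted ORFs produce two hits of one
query; hits of the same role and strand closer than 100 bp are merged
first (a frameshift fragment changes reading frame but not strand, so
strand is the stable key). Three roles within 1 kb of each other in the
order 42kD-22kD-57kD along the element strand, with the 22kD ORF
inverted, form a complete element; all other hits group into partial
elements by the same 1 kb proximity rule. When one role occurs twice in a
chain the higher-bitscore hit stays and the loser seeds its own partial
(ties to the leftmost). A role needs query coverage of at least 0.3 to
count toward completeness — weaker hits still join partials, keeping
degenerate copies visible without inflating the complete count.

# TIRs, target sites, and distances

TIR detection aligns a window around the 5' end of the ORF envelope
(400 bp outside, 100 bp inside) against the reverse complement of the
matching 3' window, using BLASTN-default local alignment scoring (match 2,
mismatch -3, gap 5/2). A pair is accepted at >= 20 aligned columns and
>= 70 % similarity.

Local alignment trims mutated TIR tips, which would blur the element
termini. The telomeric repeat at the outer TIR end is used as a
mismatch-tolerant anchor: the canonical motif is aligned near the
provisional outer end and the implied motif start, back-projected through
the motif alignment's own offset, snaps the terminus. This recovers the
exact junction where the TSD sits. TSD calling then simply takes the
largest $k \in [2, 10]$ with exact identity between the $k$-mer ending at
the element start and the $k$-mer starting at the element end — a
duplication is a duplication; fuzzy flank matches are reported as no
call.

Percent similarity between two TIRs is matches over alignment columns
(gap columns included) times 100, computed on a local alignment with the
BLASTN-default scoring above. Under this convention the two TBE2.2 TIR
consensus types shipped with the package align at 92.5 %; a global
alignment with end gaps penalised yields 87 % instead, so the local
convention is the committed one.

TIR-to-ORF distances (5' TIR inner end to the 42kD start; 57kD end to the
3' TIR) are reported per family as a mode with the fraction at the mode;
multimodal ties break toward the smaller distance. Distance modes are
only as sharp as the ORF coordinates, which motivates the two-pass CDS
extraction below.

# Family clustering

Whole elements are compared all-vs-all: an edge requires at least one
exact shared word of 50 nt (diverged families share none, so the graph
decomposes), and the edge weight is the percent identity of a global
alignment of 600 bp windows around the first shared word. Markov
clustering (MCL) runs on this graph: self loops at each node's maximum
incident weight, column normalisation, then alternating expansion (matrix
squaring) and inflation (entry-wise power 1.2, renormalisation, pruning)
to convergence; clusters are read from the attractor structure and every
node lands in exactly one cluster.

Because the TBE2 subfamilies are indistinguishable in their 42kD and 22kD
genes, the main pass merges them. A second MCL pass on the 57kD coding
regions of each main cluster (anchor word 30 nt — the gene is much
shorter than an element) splits a cluster whose 57kD genes form two or
more well-populated subclusters. Family labels are anonymous (`fam1`,
`fam1.1`, ...); mapping them onto named families is a post hoc step done
against ground truth in synthetic runs or by the user's exemplars in real
ones.

Neighbor joining (via `ape::nj`) with newick output is provided as the
lightweight tree-building substitute for full Bayesian phylogenetics,
which is out of scope.

# Protein-guided CDS extraction and integrity

For each annotated ORF the query protein is aligned to the hit region
(plus 30 bp margins) with a frameshift-aware local dynamic program over
(residue, nucleotide) cells: codon advances scored on the table-6
translation; in-frame stops absorbed at a fixed penalty of -10 and
recorded; 2-nt and 4-nt frameshift codons at -15 (so a single frameshift
is preferred over abandoning an alignment of eight or more residues);
affine residue/codon gaps at 11/1. Both strands are tried. A stop is
premature if it sits strictly before the last aligned residue.

Extraction runs twice. The first pass uses the global queries; from its
repaired sequences a per-family majority-rule consensus protein is built
(stop and masked residues do not vote). Residues trimmed in every copy by
a diverged family terminus are reconstructed from the flanking DNA of the
family's best-covered copy. The second pass re-aligns with these family
consensus queries and its spans replace the hit-based ORF coordinates.
This removes the systematic terminal trimming that a diverged global
query causes — without it, each family's TIR-to-ORF distance mode is
shifted by a family-constant few codons.

Repair undoes frameshifts (an inserted base dropped, a deleted base
restored as N), masks stops as NNN, and pads residue deletions with NNN;
the result has length divisible by three and re-aligns without
frameshifts. Hotspot profiling reports, per query residue, the fraction
of copies carrying a stop there among the copies whose alignment covers
that residue; hotspots are residues at fraction >= 0.10.

# dN/dS and the purifying-selection test

Pairs of repaired coding sequences are aligned at the protein level,
threaded back onto codons, and columns containing a gap or an N codon are
dropped (pairs retaining fewer than 30 codons are excluded with a
reason). Nei-Gojobori (1986) counting follows, under code 6: per-codon
synonymous sites are the per-position fraction of viable single-nucleotide
changes (changes to TGA excluded from numerator and denominator) that are
synonymous, so every sense codon contributes exactly 3 sites;
multi-nucleotide codon differences average over all minimal mutational
pathways with equal weights, pathways through stops excluded (a pair
whose every pathway crosses a stop contributes its differences as
nonsynonymous). Proportions are Jukes-Cantor corrected,
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$, and an estimate is valid only
when $0.01 \le dS \le 5$ and both corrections are defined. Identical
sequences are therefore invalid by construction, not an error.

The test of purifying selection is an exact binomial tail on the counts:
under neutrality a difference is nonsynonymous with probability
$N/(N+S)$; the one-sided p-value is $P(X \le \mathrm{Nd})$ with
$X \sim \mathrm{Bin}(\mathrm{Nd}+\mathrm{Sd},\, N/(N+S))$ (fractional
pathway-averaged counts are rounded). This replaces a maximum-likelihood
codon-model comparison: it is self-contained, exactly checkable, and
preserves the inference target (dN/dS below 1). Pooled counts across
pairs carry the explicit caveat that pairs sharing sequences are not
independent.

# Enrichment near annotation tracks

Element-to-track distances are measured from the (TIR-extended) span
boundary; an element on a contig without track intervals counts as "not
near". The enrichment test compares the observed fraction of elements
within 500 bp of the track against the track's genome-space fraction with
a 1-df chi-squared. Using the covered fraction as the expected value is
deliberately conservative for detecting enrichment in the "near" tail in
one specific sense: the probability that a uniformly placed element falls
within the window exceeds the covered fraction by a halo term of roughly
(number of intervals x 2 x window)/genome length. The calibration checks
therefore use tracks made of few long intervals, where the halo is
negligible; with many short intervals the test will over-reject slightly
under uniformity, which is documented behaviour, not a bug. The exact
finite-sample size of the chi-squared rule also oscillates with the
element count; the calibration uses 100 elements (analytic size 3.7 % at
an 11.1 % expected fraction) for the null check and 200 elements for the
power check at two-fold bias (analytic power 0.96), both computed from
the binomial null before any simulation was run.

# The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions. Defaults: 30 contigs of 100 kb (~3 Mb), 15 copies per family,
pairwise within-family divergence 0.08 substitutions/site (each copy is
drawn at half that distance from its family template, so copy pairs meet
the configured divergence — this is also what makes 50-nt shared words
abundant within families and absent between them), 10 % partial copies
(one or two ORFs deleted), dN/dS target 0.2 for all three ORFs, one 1-bp
frameshift per ORF with probability 0.3, a stop-codon hotspot at 42kD
residue 70 in 80 % of TBE3 copies, TSD "TA", MDSs covering 11.1 % of the
background, two satellite classes (380 bp and 170 bp units), and no
contig fragmentation. ORF lengths are 352/192/471 codons. Family
templates descend from one ancestral element along a fixed tree (TBE1 and
TBE2 sister at 0.20 between-family divergence, TBE3 at twice that, TBE2
subfamilies nearly identical in 42kD/22kD and split at 0.35 in 57kD),
which reproduces the observed similarity ordering: within family >
TBE1-TBE2 > anything-TBE3, with the 57kD gene least conserved. TIRs are
the published family consensus sequences; the right TIR is the exact
reverse complement of the left at implant time, so TIR-pair divergence in
mature copies comes from the copy mutation process.

The codon mutation process proposes uniform single-nucleotide changes and
accepts synonymous ones always, nonsynonymous ones with probability
omega, re-proposing anything that creates a stop; it runs until a
Poisson-drawn target of accepted substitutions is reached. NG86 recovers
the omega of this process to well within 10 % at the simulated depths,
which is the package's parameter-recovery surface.

What the generator deliberately does not emulate: insertion-site sequence
preference beyond a single MDS-bias knob, per-copy age structure (one
divergence scale per family rather than a birth process), nested or
overlapping insertions, assembly error, and base-composition structure in
the background (i.i.d. nucleotides at configurable GC). Passing the
recovery tests therefore demonstrates correctness of the pipeline's
inference machinery under these idealised conditions, not performance on
real assemblies with nested repeats and indel-rich divergence.

# Numerical and design choices

* Intervals are `GRanges` (1-based, closed) throughout; BED/GFF3
  conversion is delegated to `rtracklayer` at the format boundary.
* N never matches in nucleotide alignments (scored as a mismatch even
  against N) and N codons translate to X, which BLOSUM62 scores near
  zero; TSDs containing N are not called.
* Distance-mode ties break toward the smaller distance; duplicate-role
  ties in assembly break by bitscore, then leftmost start.
* All randomness flows from a single seed; the generator derives one
  stream per stage so adding draws in one stage does not shift another.
* The problem sizes used by the recovery checks (one ~3 Mb default run;
  50 pairs x 500 codons for rate recovery; 200 oracle instances up to
  30 aa x 200 nt; 100 placement replicates) were chosen as the smallest
  sets at which the binomial/analytic error bands above are decisive.
* Pipeline stage order: search, assembly, clustering, two-pass CDS
  extraction, TIR/TSD, rates, context. Clustering precedes extraction
  because the consensus queries are per family.
* Partial elements are not family-labelled (the whole-element clustering
  operates on complete elements); they are reported as unclassified in
  the distribution table.

# Known limitations

* E-values are approximate (fixed Karlin-Altschul constants), so the
  `1e-7` threshold is comparable in spirit, not in value, to BLAST's.
* TIR inner ends carry +/- a few bp of local-alignment noise; distance
  modes are robust at realistic copy numbers but single-copy distances
  are not exact.
* The 57kD second pass needs at least `2 * min_sub` members with 57kD
  coordinates in a cluster to attempt a split.
* The exact binomial neutrality test on pooled counts treats pairs as
  independent draws, which they are not; the output carries that caveat
  and per-pair tests are available.
* Very short frameshift fragments (under roughly 35 residues) can fall
  below the search score threshold; their ORF then enters as a partial
  envelope and the CDS pass recovers what the region contains.
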