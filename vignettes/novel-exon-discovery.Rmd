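---
title: "Discovering unannotated exons from spliced RNA-seq alignments"
author: "exonscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering unannotated exons from spliced RNA-seq alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonscout)
```

## The inference problem

A knockout allele can de-repress transcription inside the very gene it
disrupts: a cryptic promoter in an intron produces an unannotated exon that
splices into the known downstream exon structure, creating a novel isoform
absent from every annotation database. Finding such a region from RNA-seq
requires three pieces of evidence, and exonscout models them explicitly:

1. *The intron is transcribed*: a contiguous island of read coverage where
   the annotation says there should be none.
2. *The island is spliced into the gene*: junction reads (alignments with
   `N` CIGAR gaps) connect an island edge to an annotated exon boundary.
3. *The connectivity implies an isoform*: an island linked only downstream
   is a novel **first exon** (a promoter product), one linked only upstream
   is terminal, one linked on both sides is internal, and one linked on
   neither side stays an "unlinked" island — transcribed, but not
   demonstrably part of the gene's splicing.

The package takes spliced alignments (SAM), a gene annotation (GTF), and
optionally methylation tracks (BED), a multi-species alignment (aligned
FASTA) and qPCR Ct tables (TSV). It does not align reads, compute multiple
alignments, or fetch anything from genome browsers; those inputs are
consumed, not produced.

## Coordinate conventions

Internally everything is a `GRanges`: 1-based, inclusive — the native
convention of the Bioconductor containers the package is built on.
rtracklayer and Rsamtools do the 0-based/1-based conversions at the BED and
SAM boundaries, and every printed report uses 1-based inclusive coordinates
(`chr7:144238708-144239093` style), so internal and reported coordinates
coincide. Junctions are stored as `(donor_end, acceptor_start)`: the last
base of the upstream block and the first base of the downstream block.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_depth` | 2 | reads | island depth threshold; 2 suppresses single-read noise |
| `min_length` | 50 | bp | shortest reportable island; well below a ~400 bp exon, above spurious pileups |
| `merge_gap` | 10 | bp | bridges short sub-threshold dips inside one island |
| `min_support` | 2 | reads | junctions seen in one read only are ignored |
| `boundary_tolerance` | 5 | bp | slack when matching junction ends to island/exon boundaries |
| `min_mapq` | 30 | — | uniqueness criterion: MAPQ ≥ 30 and neither secondary nor supplementary flag |
| `pseudocount` | 0 | density | added to both group means in fold changes; 0 errors on an unexpressed control rather than silently rescuing it |

The uniqueness criterion deserves a note: "uniquely mapped" has no
universal SAM encoding, so the package defines it as a MAPQ cutoff plus
primary-alignment flags and makes the cutoff configurable.

Island boundary refinement: when a linking junction exists, the island edge
snaps to the junction coordinate. Splice sites are defined to the base by
the junction reads; coverage edges decay with library depth and fragment
ends. The unjunctioned 5′ edge of a novel first exon has only coverage
evidence, which is why two libraries of different depth can legitimately
report starts a few bp apart — the package reports per-sample boundaries
and does not reconcile them across samples.

Islands that are intronic in some isoforms but exonic in others are
discarded: novelty is judged against the union of all annotated exons,
matching what "not previously annotated in any database" has to mean.

## Guided reconstruction semantics

The splice graph has one node per annotated exon and per novel call; edges
are read-supported junctions (matched to node boundaries within
`boundary_tolerance`; a junction matching two node boundaries on the same
side is an ambiguity error, not a guess) plus guide edges between
consecutive exons of each known isoform. Variant enumeration returns every
guide isoform unchanged, and, per novel node, extends along each read edge
and then follows the guide isoform that contains the linked exon to its
end — one variant per compatible guide, deduplicated, sub-chains
suppressed. Read evidence typically covers only the novel junction itself,
so extension beyond the linked exon is deliberately annotation-guided
rather than read-exhaustive; when several guides share the linked exon but
diverge later, the method emits one variant per guide and leaves the choice
to the user. Minus-strand genes use the same genomic-coordinate graph with
upstream/downstream interpreted transcriptionally.

## Quantification

Region expression is whole-read RPKM-style density: reads with ≥ 1 bp of
block overlap, divided by region kilobases and library millions. Whole-read
counting (rather than per-base integration) keeps the estimator unbiased at
region edges where fragments straddle the boundary. The ΔΔCt implementation
follows the standard Livak formulation — technical replicates averaged per
biological sample, then mean-of-ΔCt per group, then `2^-ΔΔCt` — rather than
mean-of-folds, which is biased upward under Ct noise. Per-sample folds
relative to the control mean are reported as the dispersion summary.

## Evolutionary and epigenetic characterization

Conservation is a sliding window (20 alignment columns, step 10) of mean
pairwise identity under pairwise deletion: for each sequence pair, matches
over columns where both have an unambiguous base; the window score averages
over pairs; a window where any pair has zero comparable columns is flagged
undefined and excluded from blocks. Blocks are runs of windows at or above
a 0.8 identity threshold. These defaults are a pragmatic stand-in for
browser-style conservation tracks — the goal is to localize high-identity
blocks (a promoter-like block upstream, a coding-like block at the exon
3′ end), not to fit a phylogenetic conservation model; phastCons/phyloP
style scoring is explicitly out of scope.

Distances use pairwise deletion with either p-distance or its Jukes–Cantor
correction `-(3/4)·ln(1 − (4/3)p)` (default; saturation `p ≥ 0.75` is an
error naming the pair). The neighbor-joining implementation is the classic
Saitou–Nei agglomeration with two determinism conventions: ties on the
Q-criterion break toward the lowest taxon-index pair, and negative branch
lengths are clamped to zero with the deficit moved to the sibling branch
(the raw lengths are kept in an attribute). On additive matrices NJ is
exact — the test suite verifies topology and branch-length recovery on
random additive matrices and cross-checks topology against an independent
NJ implementation.

Methylation overlap reduces the hypomethylated intervals (score ≤ 0.3 by
default, on a [0,1] methylation level) to their union before intersecting
with the query, so the reported fraction is invariant to how the track
happens to be segmented. Records whose score column was absent are flagged
at parse time, and methylation analyses refuse tracks carrying such
silently-defaulted scores.

## What the simulator emulates — and what it does not

`simulate_locus()` builds a 7-exon gene with two known isoforms (long:
exons 1–7; short: exons 3–7) and plants a 386 bp novel exon in the intron
between exons 4 and 5, spliced to exon 5 only — a novel first exon. The
386 bp length mirrors the size of a real intronic first-exon discovery;
the annotation written to GTF contains only the known isoforms, and the
planted truth lives in a JSON sidecar. Four genotype presets plant
KO:WT novel-expression ratios of 8 (the "e67" pair) and 1.71 (the "e7"
pair) against equal-weight known isoforms.

`simulate_reads()` samples fragments along each transcript proportionally
to genotype weights, calibrated so a constitutive exon (present in every
known isoform) sees the nominal depth. Two modes:

* **stochastic** (default): fragment starts are a uniform Poisson process
  over the end-extended transcript, truncated at transcript boundaries, so
  expected coverage is flat all the way to the transcript ends;
* **noiseless**: deterministic tiling with end-truncated fragments giving
  every transcript base depth exactly *d*. This idealization makes exact
  boundary recovery a well-posed target for the unjunctioned 5′ edge of a
  first exon; with stochastic sampling that edge is exact only up to
  coverage noise (within ±2 bp in ≥95% of replicates at ≥20× in the test
  suite).

The emitted SAM is a single-locus extract of a notional whole-transcriptome
library: the header records a library size proportional to sequencing
effort (depth), equal across genotypes, the way a genome-wide
"total uniquely mapped reads" figure would be. Reads are emitted pre-aligned
with correct coordinates (the aligner is out of scope), so simulation noise
enters through sampling only — no sequencing errors, PCR duplicates,
multi-mappers or mis-mappings. Passing tests on these data therefore
demonstrate the inference logic, not robustness to alignment artifacts.

`simulate_evo_tracks()` writes an ungapped 8-species alignment (mouse plus
seven vertebrates) over the exon and 200 bp of upstream context, with two
planted high-identity blocks: identity targets are converted to a per-site
substitution rate via `(1-q)² + q²/3 = p` (two sequences independently
mutated from a common reference match if both kept the base, or mutated to
the same alternative). Defaults are 0.95 inside blocks and 0.35 background
— distant-vertebrate neutral divergence — which keeps windows straddling a
block boundary (≈ 0.65 expected identity) safely below the 0.8 threshold,
so block recovery is exact on the window grid; block coordinates are
grid-aligned by construction. Because the alignment is ungapped, alignment
columns map 1:1 to genomic positions; real alignments with indels would
blur the column-to-genome mapping and the block edges with it. Methylation
tracks are deterministic: brain tissues get a 0.1-scored interval covering
the exon (±50 bp) against a 0.8 background; other tissues are uniformly
0.8.

`simulate_qpcr()` draws a control ΔCt around a 6-cycle baseline, shifts the
case group by −log₂(fold), and adds Gaussian noise (sd 0.3 cycles by
default) independently to target and reference Ct of each of 3 technical
replicates × 5 biological samples per group. With zero noise the ΔΔCt
estimate recovers the planted fold exactly.

## Numerical and degenerate-input choices

* Zero-width alignment blocks (insertions sandwiched between two `N`
  skips) are dropped: a block must consume reference.
* A junction observed twice in one read (possible in pathological CIGARs)
  counts once for that read; support is the number of distinct reads.
* `call_islands` on an all-zero track, an empty annotation file, and an
  empty junction set all return empty results, not errors; a discovery run
  with no calls writes an empty report and says so.
* Islands extending beyond the gene span are flagged `outside_gene_span`
  but reported.
* Density fold changes refuse a zero-density control at pseudocount 0
  instead of returning `Inf`.
* The ΔΔCt shift-invariance (adding a constant to one sample's target and
  reference Ct together) is property-tested; it is the reason ΔCt is
  formed per sample before any averaging.

## Problem sizes used in tests

The test suite runs entirely on generated data: a ~7 kb locus at 20–50×
(hundreds to ~a thousand reads per sample), 30-replicate fold-change
calibrations for three planted ratios, 100-replicate ΔΔCt calibration,
100 random additive matrices for NJ recovery, and ≥1000 random instances
per brute-force oracle comparison (coverage, junctions, islands,
interval-union overlap, variant enumeration). These sizes make the
statistical acceptance bands (±20% on medians/means) comfortably tight
while keeping the full suite in the minutes range on a laptop.

## Known limitations

* Discovery is restricted to supplied gene loci; this is not a genome-wide
  de novo transcript assembler.
* Fold changes come without significance tests; with typical 1–3 samples
  per genotype a p-value would be theater.
* The novel variant's 3′ end is resolved per compatible guide isoform; RNA
  evidence rarely determines which guide continuation is real.
* Conservation scoring is identity-based, not model-based; branch lengths
  are reported but rate-change inference is left to the user.
* Methylation arrives as scored intervals; bisulfite read processing is out
  of scope.
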