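---
title: "Models and methods behind cisnat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cisnat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modelling choices, conventions and numerical
decisions the package makes, in the spirit of a methods supplement. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## Coordinates and interval algebra

All internal coordinates are 0-based half-open (`[start, end)`), on plain
tibbles with `chrom`, `start`, `end`, `strand`. Conversion happens only at
I/O boundaries: GFF3 is 1-based inclusive, BED is already half-open, MAF
reference coordinates are half-open. This removes every off-by-one
ambiguity from the interval arithmetic (subtraction, overlap, the NOLP
partition identity `subtracted + overlapped = total`), which is tested as a
property over random intervals.

"Antisense" always means: opposite strand symbols and at least 1 bp of
genomic overlap. Unstranded (`*`) features never count as antisense
partners.

## Topology classification

The five NAT/gene topologies are defined geometrically on transcript
*spans* (exon chains are reserved for NOLP extraction, since typing is a
per-transcript-pair notion while NOLPs are defined against exons):

* **Type 5** — the NAT overlaps two or more distinct antisense genes.
* **Type 3** — NAT span contained in one antisense gene span.
* **Type 4** — antisense gene span contained in the NAT span.
* **Type 1 (divergent)** — partial overlap in which each transcript's 5'
  terminal base lies inside the other (head-to-head; transcription
  proceeds apart).
* **Type 2 (convergent)** — the complementary partial-overlap case
  (tail-to-tail).

Precedence is 5, 3, 4, 1, 2, so exactly one type is assigned; equality of
spans resolves to type 3 (precedence over 4). Classification is invariant
under relabeling which DNA strand is called "+" (a coordinate reflection
plus strand swap), which the tests assert. Where the divergent/convergent
naming of types 1 and 2 is described inconsistently in secondary sources,
we fix type 1 = divergent.

## NOLP extraction and the non-redundant set

NOLPs are the maximal sub-intervals of a NAT's exonic footprint covered by
no protein-coding exon (`mode = "exon"`, default) or by no protein-coding
transcript span (`mode = "transcript_span"`). Under exon mode a type-3 NAT
inside an intron-containing gene can retain intronic NOLPs; the
conservation stage nevertheless excludes all type-3 NATs, whose footprint
the containing gene fully explains.

The non-redundant (NR) set is built greedily: records sorted by decreasing
*total NOLP length* (we read "sequence length" of the sorted NOLP list as
NOLP length, since the list being sorted is the NOLP list), ties broken by
record id for determinism; a record is kept iff none of its NOLP intervals
overlaps any kept NOLP by ≥ 1 bp on either strand. The output is verified
non-overlapping and idempotent, and matches a brute-force oracle on random
instances. Cross-validation between NAT data sets uses ≥ 1 bp same-strand
overlap — the most permissive threshold, configurable.

## The branch-length-scale likelihood-ratio test

The neutral model is a tree with branch lengths in expected
substitutions/site plus a general reversible rate matrix and equilibrium
frequencies (phyloFit-style text files are read and written; the matrix is
re-normalised so the equilibrium rate is 1 per unit branch length).
Likelihoods use Felsenstein pruning with transition probabilities from the
eigendecomposition of the symmetrised rate matrix, vectorised over column
patterns.

* **Gaps, Ns and absent species are missing data** (partial-likelihood
  vector of ones), the phyloP convention; gaps are not a fifth state.
* **Alternative model**: every branch multiplied by one free scale
  `r ∈ [1e-3, 10]`, optimised by Brent-style bounded search with tolerance
  1e-6 in scale; the bounds are also evaluated so monotone profiles hit
  them exactly. The profile is unimodal in practice, so no restarts.
* **Null**: `r = 1`. `D = 2(lnL_alt − lnL_null)` is clamped at 0 against
  optimiser noise and referred to χ²(1); the two-sided p is reported with
  the direction (from the scale) separate, and a conservation call
  combines `p < 0.05` **and** `r < 1`.
* Columns with fewer than two non-missing species are skipped; loci with
  fewer than 10 usable columns are flagged untestable rather than scored.
* Testing is **per NOLP interval** (not per-NAT pooled, not windowed):
  this is what lets one NAT carry two independently significant conserved
  regions. Holm–Bonferroni is applied across all tested intervals of a
  run.

Correctness anchors: pruning equals the closed-form pairwise likelihood on
two-leaf trees; marginalising a leaf equals summing its observation over
the four bases; doubling branch lengths while halving the scale leaves the
likelihood unchanged (the scale is confounded with total tree depth, which
is why the neutral tree is an input, not re-estimated). Calibration: on
neutral simulations (9 taxa, 200 columns) the type-I error at p < 0.05
stays within [0.03, 0.07], and the scale MLE recovers 0.3 and 1.0 within
±20% in median — both recomputed by the test suite and the acceptance
script.

## Homology toolkit

The BLAST/BLAT-like steps are deliberately simplified bespoke equivalents
with documented defaults:

* **Smith–Waterman** (Rcpp, affine gaps, deterministic traceback with ties
  diagonal > up > left), verified against an independent full-matrix
  recurrence on random pairs. Nucleotide scoring +2/−3, gap open 5,
  extend 2; protein scoring BLOSUM62, gap 11/1.
* **E-values** via Karlin–Altschul `E = K·m·n·exp(−λS)` with K = 0.41,
  λ = 0.625 (nucleotide) and K = 0.041, λ = 0.267 (protein) as calibration
  defaults.
* **Transcript mapping**: exact 11-mer seeds on both strands, collinear
  chaining (quadratic DP, diagonal band 200), gapped extension of the best
  chain; acceptance at identity ≥ 0.90 over ≥ 0.50 of the query — a
  declared guess where the original tool thresholds are unstated, and
  configurable.
* **Orthologs**: bidirectional best hits on Smith–Waterman protein scores;
  ties exclude the pair. Protein scans are pre-filtered by an exact shared
  4-mer amino-acid word (a BLAST-like seeding heuristic) before the full
  alignment.
* **ORFs**: ATG to the next in-frame stop, length in codons excluding the
  stop; codons containing N never match.
* **Expression conservation** in the sister genome requires (i) antisense
  transcript evidence overlapping the mapped locus, (ii) no evidence ORF
  > 100 codons (sense strand), (iii) no sense-direction protein hit at
  E ≤ 1e-4. **Sequence conservation vs the sister** is a local alignment of
  the NOLP (both orientations) against a symmetric 5-kb flank of the
  orthologous gene at E < 1e-10; the flank size operationalises "adjacent
  to the orthologous gene" and is configurable. The pipeline looks the
  ortholog locus up at the focal gene's coordinates on the sister assembly
  — a conserved-synteny assumption that holds exactly in the synthetic
  worlds and approximately between close sister species.

## Matched resampling null

"Same length and relative positioning" is operationalised per observed
NOLP as an exact match of (length, side of nearest gene in the gene's
orientation, edge distance to the gene boundary): each replicate places an
interval with those attributes next to a uniformly drawn *different* gene,
rejecting placements that overlap any gene transcript or leave the
chromosome (≤ 1000 redraws, then a hard error naming the interval).
Anchors are drawn with replacement; replicate seeds derive deterministically
from the master seed, so a replicate set is byte-reproducible. Length
multisets are therefore invariant across replicates (a statistic equal to
total bp has null sd exactly 0). Observed-vs-null comparison uses normal
statistics (`z` against the replicate mean and sd, one tail), with the
degenerate sd = 0 case resolved by direct comparison and flagged. No GC or
repeat matching is attempted.

## Hypergeometric cross-referencing

All association tests are exact hypergeometric tails (log-space via the
standard distribution functions): enrichment `P(X ≥ k)`, depletion
`P(X ≤ k)`, with `enrichment + depletion = 1 + P(X = k)` asserted as an
identity. For conservation × expression tables the universe is all NATs of
the data set (type-3 NATs drop out as `NA`). For ChIP-peak enrichment the
peak counts themselves are reported at peak level (a peak spanning two
NOLPs counts once), while the test is taken at NAT level (N = NATs, K =
NATs with ≥ 1 peak, n = conserved NATs, k = conserved NATs with a peak),
because a peak-level universe is not well defined; the choice is recorded
in the output. siRNA uniqueness means exactly one forward-orientation
match across the combined reference set (protein-coding transcripts plus
NAT regions); compartment (NOLP/OLP) is assigned by the match midpoint so
the partition is exact; a unique NAT read is trans-acting iff it also
matches in reverse orientation at a *different* locus — a reverse match on
the NAT's own antisense gene is the definition of cis.

## The synthetic generator

`generate_world()` emulates the statistical structure the analysis
assumes: one locus module per NAT realising its topology exactly; gene
exons filled with valid ORFs; NOLP loci evolved under the 9-leaf
Brassicaceae-like default tree (total depth ≈ 1.3 substitutions/site,
HKY-style rates, AT-rich composition) at per-locus scales (30% conserved
at scale 0.3 by default); the alignment's reference row patched back into
the focal genome so alignment and genome agree; siRNAs drawn from OLP vs
NOLP at 9:1; peaks enriched 4× in 500-bp promoter windows; transposons
accepted in conserved NOLPs with probability 0.2; a sister genome evolved
at 0.10 substitutions/site (gene exons at 0.3× that rate) with antisense
evidence retained with probability q = 0.3, optionally coupled to the
conservation label (0.7 for conserved vs 0.13 for unconserved NATs, chosen
by a power calculation so that a 100-NAT world detects the dependence
reliably while keeping the marginal retention at 0.3).

What it does **not** emulate: indels in alignments (substitutions only),
genome rearrangements or synteny breaks, tiling-array noise, realistic
repeat structure, or lineage-specific turnover of unconserved NOLPs in the
sister genome — the sister evolves uniformly outside genes, so the
pairwise sister-sequence call is near-saturated in synthetic worlds and
its discriminative behaviour is exercised by constructed sequences in the
unit tests instead. Passing tests therefore demonstrate correctness of the
machinery and calibration under the model's assumptions, not performance
on real tiling-array data.

## Problem sizes and reproducibility

The test suite and acceptance script choose compact problem sizes that
keep the statistical checks well-powered: 1000 neutral loci (9 taxa × 200
columns) for type-I calibration; 200 loci each at scales 0.3 and 1.0 for
recovery; 100 generated NATs for topology recovery; 100 random instances
for the NR oracle; 500 replicates on a 1-Mb genome for the matched null;
200 random pairs for the alignment oracle; a 100-kb reference for the
mapping oracle; and a 100-NAT coupled world plus 100 (60 in the script)
20-NAT independent worlds for the end-to-end association check, whose
uniformity is assessed on mid-p values (p − ½P(X = k)) because exact-test
p-values are discretely super-uniform at these sample sizes. Every
stochastic step runs under seeds derived from one master seed; identical
configurations produce byte-identical outputs.

## Known limitations

* The geometric definitions of types 4 and 5 are reconstructions from the
  divergent/convergent description of types 1–3; a different figure-level
  convention would permute those labels (the definitions are centralised
  in `classify_topology()`).
* The conservation unit is the whole NOLP interval; a sliding-window mode
  would localise signal within long NOLPs but is not implemented.
* Karlin–Altschul constants are fixed defaults, not estimated for the
  configured scoring scheme.
* The matched null preserves position exactly per NOLP rather than
  matching the positional distribution as a whole; both readings are
  defensible, the stricter one is the default.
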