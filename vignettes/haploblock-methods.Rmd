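---
title: "Methods: comparing tandemly duplicated haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing tandemly duplicated haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploblock)
```

This vignette explains the models and procedures behind each stage of the
package, the parameters that matter and their defaults, what the simulator
emulates (and what it does not), and the numerical choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The locus model

The package targets loci like the cattle MHC class I region: a core of
tandemly duplicated blocks, one class-I-like gene per block, flanked on
both sides by sequence that is nearly identical between haplotypes.
Haplotypes differ in block copy number; gene starts repeat at the block
period; gene conversion shuffles the 5′ segments of the genes and leaves
GC-rich tracts near the conversion breakpoints. Every analysis stage is a
formalisation of one observable consequence of that model.

Coordinates are 1-based inclusive throughout (the GenBank convention used
by the annotation formats the package reads); only the BED/bedGraph
exporters convert to 0-based half-open at the boundary. Sequences live in
plain tibbles (`id`, `description`, `seq`, `length`), features in tibbles
with `seq_id`, `kind`, `start`, `end`, `strand`, `name`, `phase`. `N`
bases are accepted everywhere and never count as matches or as GC.

## Clone end-overlaps and variant calling

Overlaps between clones of one tiling path are near-identical, so
`find_end_overlap()` does not run a full quadratic alignment. It collects
exact shared 31-mers, votes for the dominant alignment diagonal (250-bp
bins, a ±2 kb band sized to the indel budget), chains colinear
non-overlapping seeds, projects the chain to the sequence ends — a genuine
end-overlap always reaches an end of each partner — and aligns only the
short inter-anchor gaps (Biostrings global alignment; match +1, mismatch
−2, gap open 4, extend 1). A gap piece whose two sides differ in length by
50 bp or more clearly contains a long indel; its opening cost is raised to
100 so the gap stays contiguous instead of being scattered among chance
matches. Identity is matches over aligned columns, excluding columns with
`N`; candidate overlaps below `min_identity` (default 0.9) or shorter than
`min_overlap` (default 1 kb) are rejected, and ties are broken by longer
alignment, then forward orientation.

`call_overlap_variants()` reads the stitched columns directly: mismatches
become SNPs (adjacent mismatches stay separate SNPs, matching how SNP
tallies are conventionally counted), gap runs become insertions or
deletions. Inversions are found as low-identity stretches (rolling
50-column match fraction below 0.75) whose reverse complement re-aligns
locally at ≥ 90% identity over at least `min_inversion` bp (default 100).
The stretch is re-labelled as a single inversion and all calls whose a- or
b-extent touches the re-labelled segment are dropped — the alignment
structure inside an inverted region is meaningless, and its internal
mismatches must not be double-counted as SNPs. Re-labelling never changes
the alignment, so `aligned_length` is conserved.

Coding effects are classified against a CDS gene model (joined length must
be a multiple of three, checked per gene): each CDS SNP is translated in
both alleles with the standard genetic code; indels inside a CDS are
frameshifts when their length is not a multiple of three. Minus-strand
models are handled by mapping through the reverse complement.

## Scaffolding

`scaffold_contigs()` re-uses the seed/chain machinery: each contig is
anchored to its best reference (both orientations), placements are ordered
by midpoint, and the gap between consecutive contigs is the distance
between the projected reference coordinates of their facing ends. Gaps are
floored at zero; a projected negative gap is reported as zero with an
overlap annotation, and a majority overlap between two placements demotes
the lower-scoring contig to unplaced with a warning. Contigs whose seed
anchor spans less than `min_anchor` (default 500 bp) are unplaced.

## Restriction digests

`digest()` finds every site occurrence (overlapping ones included; sites
containing `N` are conservatively not called) and cuts at the top-strand
offset — A^AGCTT for HindIII. Fragments always sum to the sequence length
in both topologies, and circular digests detect sites spanning the origin.
One consequence of top-strand accounting is worth knowing: for a
palindromic site, circular digests are exactly invariant under reverse
complement, but the two terminal fragments of a linear molecule shift by
the overhang length (4 nt for HindIII) when the strand is swapped — that
is the physics of a staggered cut, not an artefact.

`match_profiles()` compares an in-silico digest with a gel-derived size
list under the tolerance `|x − y| ≤ max(50 bp, 0.05·max(x, y))` — an
absolute floor for small fragments plus a relative gel-sizing error.
Matching is greedy, globally largest-first, which is deterministic and
symmetric in its two arguments; fragments under 500 bp are excluded by
default because gels do not resolve them. On well-separated sizes the
greedy matching attains the brute-force optimal assignment (checked in the
tests on ≤ 8 fragments).

## Identity matrices and duplication blocks

`identity_matrix()` is the dot-matrix comparison: ungapped exact-match
fraction between 200-bp windows (the conventional dot-plot setting), step one
quarter of the window, computed via per-diagonal cumulative sums in
O(n²/step). A `max_windows` cap (2 000 per axis) enlarges the step for
very long inputs.

Block *detection* deliberately does not rely on the window grid. A grid
samples only diagonal offsets that are multiples of the step, and an
ungapped 200-bp window shifted even 5 bp off the true offset of a
duplication falls to background identity — tandem copies spaced at
arbitrary distances would be invisible. `detect_blocks()` therefore first
finds candidate offsets by exact k-mer co-occurrence voting (duplicated
sequence at any realistic identity shares abundant exact 31-mers at its
true offset; unrelated sequence shares essentially none), then computes
windowed identity along each supported diagonal at 1-bp offset
resolution. Cells at or above the threshold (default 0.7) form runs, runs
on offsets within one step merge, and merged runs shorter than `min_block`
(default 5 kb) are dropped. Self-comparisons exclude the main diagonal and
report each mirror pair once. Against a background of unrelated sequence
the 0.7 threshold is unreachable (window identity is binomial around 0.25
with n = 200), so false positives require shared k-mers that random
sequence does not have.

`estimate_period()` clusters block offsets single-linkage with tolerance
twice the step, takes the most populous cluster (ties favour the smallest
offsets, since larger offsets are multiples of the period) and reports its
median as the period; copy number is one plus the largest offset divided
by the period. Gene spacing is reported start-to-start, because
start-to-start spacing equals the duplication period when genes sit at a
fixed offset inside tandem blocks; end-to-start distances are printed
alongside for transparency.

## GC anomaly scanning

`gc_profile()` slides a 100-bp window at 1-bp steps (both conventional GC-track
defaults; the step is adjustable for speed) and computes GC over non-`N`
bases; the baseline mean and standard deviation are computed per scanned
interval — per gene, as the comparison plots per-gene tracks — on
unclipped values. `flag_anomalies()` marks windows with z ≥ 2.5 (high side
only by default: conversion bias elevates GC; `low` and `both` exist for
completeness) and merges them into maximal runs.

Two numerical choices matter here. First, a run must span at least
`min_windows` qualifying windows (default 25): the z-test is applied to
thousands of heavily autocorrelated windows, so single-window 2.5σ spikes
occur on plain random sequence at a steady Poisson rate, while a real
conversion-scale tract (hundreds of bp) sustains its excursion across
hundreds of overlapping windows — an anomaly is a sustained excursion, not
a spike. Second, because the step is smaller than the window, runs
separated by a few non-qualifying windows can still have overlapping
intervals; such runs are merged so reported anomalies are disjoint and
maximal. `associate_boundaries()` then links each anomaly to the nearest
exon start/end within 200 bp (distance zero if the boundary falls inside
the interval).

## Segment-partitioned phylogenetics

The T92 distance is computed per pair with pairwise deletion of gap/`N`
columns (complete deletion would discard most of a short segment for one
ragged taxon) and θ estimated per pair over the included columns, matching
the pairwise closed form; an alignment-wide θ mode exists as an option. At
θ = 0.5 the formula reduces exactly to the Kimura two-parameter distance,
which the tests verify numerically, and the implementation is checked to
14+ digits against an independent one on simulated alignments. Saturated
pairs (non-positive log arguments) raise an error naming the pair.

Neighbor joining is the canonical Saitou–Nei algorithm with the Q
criterion; ties are broken by the lowest taxon-index pair so results are
deterministic, and negative branch lengths are clamped to zero. On
additive matrices NJ provably recovers the generating tree, which the
tests exercise over random 4–8 taxon trees and against an exhaustive
least-squares search over all 15 five-taxon topologies. NJ on T92
distances stands in for a likelihood tree search deliberately: the
inferences the pipeline draws are topology-level (monophyly, incongruence
between segments), for which NJ on a consistent distance is adequate,
deterministic and fully auditable in-package.

Robinson–Foulds distance is the symmetric difference of non-trivial
bipartition sets. `congruence_scan()` builds one tree per segment of the
partition (segments with fewer than 50 valid columns, or a saturated
pair, are skipped with a warning), computes all pairwise RF distances, and
flags adjacent segment pairs with RF > 0 as candidate conversion
breakpoints at their shared boundary. With three taxa there is a single
unrooted topology, so scans still return trees but can flag nothing.

## The simulator

`simulate_haplotype()` builds an ancestral block carrying a three-exon /
two-intron gene model (CDS length divisible by three), copies it in
tandem, mutates each copy independently at `block_divergence` per site
(transition chosen with probability κ/(κ+2), default κ = 2), and adds
flanks. The drawn gene spacing *is* the realised block period: each copy
is truncated — or padded with fresh random sequence — to its drawn
spacing, so start-to-start gene distances equal the period by
construction. Defaults are a 1:10 scale model of the motivating locus:
8-kb blocks for ~80-kb blocks, spacing drawn from 6.3–6.8 kb for 63–68 kb,
so end-to-end runs take seconds; the same code generates full-scale
sequence by passing full-scale parameters. `simulate_haplotype_pair()`
shares the ancestral block and flanks between two haplotypes (optionally
with different copy numbers) and diverges flanks at `flank_divergence`
only — the conserved-flank / variable-core structure.

`simulate_clones()` cuts clones out of a haplotype and implants a
specified number of SNPs, signed indels and an optional inversion into the
second clone of a pair, only inside the pair's overlap, with a minimum
spacing of 50 bp between implants so recovered counts are comparable to
truth exactly. Inversion placements whose flanking two bases would extend
the reverse-complement match with positive alignment score are re-drawn —
otherwise the implanted tract and the biologically unambiguous inversion
differ by a few bases and no caller could (or should) report the nominal
length. Colliding implants are re-drawn up to 100 times, then error.

`simulate_alignment()` evolves columns independently down a tree under a
reversible kernel whose target weights are κ·π for the transition partner
and π for each transversion partner, giving stationary GC = θ — the
process the T92 estimator assumes. A conversion event copies a column
interval from a donor tip into a recipient tip, keeping the GC-bearing
allele at differing sites with probability `gc_bias` (default 0.7, a free
parameter chosen once so the GC signature is detectable at desk scale; no
quantitative bias strength is established for the locus).

One integer seed governs each generator call; identical seeds give
byte-identical output.

## What the simulator does and does not emulate

It reproduces the features the analyses key on: tandem blocks with one
gene each, spacing equal to the period, conserved flanks, clone overlaps
with implanted variants at known positions, fragmented clones with known
gaps, conversion tracts with GC bias, and alignments evolved on a known
tree. It does not model coalescent population structure, recombination
graphs, sequencing error, repeat families unrelated to the block
structure, or alignment uncertainty (congruence scans consume pre-aligned
input; building the MSA is out of scope). Passing tests therefore
demonstrate that the algorithms recover planted truth under the locus
model — not that real data are free of the confounders above.

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script run at the 1:10 scale:
5–20-kb duplication units with 2–4 copies (sequences up to ~90 kb), 10-kb
clone overlaps, 7 × 1-kb alignment segments over six taxa, twenty seeds
per stochastic property. Degenerate inputs are defined rather than left to
chance: empty FASTA errors; sequences shorter than `min_overlap` return
`NULL` rather than erroring; a constant GC scan warns and flags nothing;
`estimate_period()` on an empty block list errors with "no duplication
detected"; single-clone validation errors; a clone set with no qualifying
overlaps returns a report with the `no_overlaps` verdict and a warning.

## Known limitations

Overlap detection assumes near-identity (it seeds on exact 31-mers), so
it is not a cross-species aligner. Inversion calling reports the maximal
reverse-complement match, which on real data may extend a few bases past
the historical breakpoint whenever the flanks happen to complement.
Block detection reports blocks at distinct offsets, so copies at *equal*
spacing merge into one run per offset rather than one block per copy
pair. The GC scan's per-gene baseline makes anomalies relative to each
gene, not to a genome-wide composition. And NJ topologies are not
likelihood estimates; where branch support matters, export the segment
alignments and trees and use a dedicated phylogenetics package.
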