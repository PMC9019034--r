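---
title: "Reconstructing ligation junctions and high-resolution contact matrices from tiled MCC libraries"
author: "tiledmcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ligation junctions and high-resolution contact matrices from tiled MCC libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method in brief

Micro-Capture-C (MCC) is an MNase-based chromosome conformation capture
protocol. Chromatin is digested with micrococcal nuclease — which cuts
largely independently of sequence, leaving mono-nucleosome-sized
(~180 bp) fragments — proximity-ligated, sonicated to an average of
~200 bp, and sequenced with 150 bp paired-end reads. In the *tiled*
variant, whole regions of interest are enriched by hybridisation to a
dense panel of 70 nt capture oligonucleotides overlapping by 35 nt.

Two consequences shape the analysis. First, because the sonicated
molecules are barely longer than a read, most ligation junctions are
*sequenced across*: a read is a chimera of two genomic fragments and the
junction base pair can be reconstructed exactly. Second, because MNase
imposes no restriction-site grid, junctions occur at essentially any
coordinate. Restriction-based 3C is bounded by the expected fragment
length `4^k` for a `k`-bp recognition motif (256 bp for a 4-cutter,
4096 bp for a 6-cutter; `expected_fragment_length()`); MNase-based
libraries have no such bound, which is what makes 20 bp contact matrices
meaningful.

The pipeline implemented here is:

1. trim 3' sequencing adapters (`trim_adapters()`);
2. merge overlapping mates into single molecules (`merge_pairs()`);
3. split chimeric reads by local alignment against the enriched region
   sequences (`split_chimeric()`), discarding reads that match no region
   (off-target);
4. confirm each split sub-read against the full reference
   (`place_segments()`), dropping ambiguous or discordant placements;
5. call one junction per pair of consecutive segments whose fragment
   ends lie < 5 bp apart in the read (`call_junctions()`);
6. remove PCR duplicates using the sonication ends plus the junction
   coordinates with a ±2 bp wobble (`dedup_junctions()`);
7. bin junctions into symmetric matrices, ICE-balance, and export
   density-plot points filtered to distances ≥ 10 bp
   (`bin_junctions()`, `ice_balance()`, `density_points()`).

## Coordinates and conventions

All internal coordinates are 0-based, half-open; BED files pass through
unchanged and the pairs-style junction TSV is 1-based on disk only. The
junction-proximal end of a `+`-strand segment is its `g_end`, of a
`-`-strand segment its `g_start`; partners are stored canonically with
`(chrom1, pos1) <= (chrom2, pos2)`. Bins are left-anchored; the last bin
of a grid may be short and is a full-status bin.

## Ambiguous junctions and canonical normalisation

When the base immediately after a ligation junction happens to equal the
next base of the first fragment's genomic continuation, the same read
sequence is explained by more than one junction placement — the
breakpoint is ambiguous in exactly the way indel positions are ambiguous
in read alignment. On random sequence this affects a sizeable minority
of junctions (each side independently with probability ~1/4 per base,
geometrically decaying). Both the simulator's ground truth and the
junction caller therefore normalise to a canonical representative: the
junction is shifted maximally along the first fragment's continuation
(the caller implements this by resolving query overlaps between
consecutive segments in favour of the upstream segment and trimming the
downstream one). The realised junction distance consequently differs
from the drawn distance by `2a` where `a` is the geometric shift.
Segment pairs whose read-coordinate overlap reaches 5 bp fall outside
the `< 5 bp` adjacency rule and are not called; this is the geometric
tail of the same ambiguity.

## Duplicate removal

PCR duplicates of a sonicated molecule share the molecule's outer
(sonication) ends and its junction, up to small mapping jitter. Two
junction records are treated as duplicates when they share the
chromosome pair and all four of {sonication_left, sonication_right,
pos1, pos2} differ by at most 2 bp, applied *per coordinate* (the most
permissive reading of a ±2 bp wobble; an aggregate-distance variant
would be stricter and is not implemented). Records are clustered by
single linkage over this relation and the representative with the
lexicographically smallest read id is kept, which makes the output
independent of input order. The production implementation (sorted
sliding window + union-find) is tested against a brute-force O(n²)
oracle.

## Matrices and normalisation

Each junction with both ends inside the region increments `[b1, b2]` and
`[b2, b1]` (the diagonal once), so total off-diagonal mass is twice the
off-diagonal junction count. ICE balancing masks zero-marginal bins,
iteratively divides by normalised row sums (`bias` accumulates the
correction) until the maximum row-sum deviation drops below `tol`
(default 1e-5, maximum 200 iterations), then rescales so the unmasked
mass equals the raw unmasked mass. Re-balancing a balanced matrix is a
no-op to within `tol`. Only zero-marginal masking is applied by default;
no percentile-based coverage filter is used because none is part of the
method's definition.

Display convention: large-scale matrices (≥ 100 bp bins, typically
500 bp) are drawn on a linear colour scale; fine-scale matrices
(20–50 bp) on a log10 scale with a pseudocount equal to the smallest
positive entry (the method specifies the scales but not the pseudocount;
the smallest positive entry keeps the transform monotone without
flattening sparse matrices).

For differential comparisons, junction tables are first downsampled
without replacement to the lowest unique-junction count across
conditions (`downsample_junctions()`, seed-deterministic), each table is
binned and ICE-balanced, and the per-bin difference of the *balanced*
matrices is taken with union masking and no smoothing. Whether raw or
balanced values should be subtracted is genuinely open; balanced
subtraction is implemented because the downsampling step exists
precisely to make balanced signal comparable. Replicates are pooled at
the junction level before matrix construction, since the downsampling
unit is the filtered unique-junction table.

Density plots use the exact junction coordinates, filtered to distances
≥ 10 bp (self-ligation and re-ligation artefacts dominate below that),
binned into 20 bp cells, smoothed with a separable Gaussian kernel
(σ = 3 cells), and returned sorted by ascending density so dense points
draw last.

## Alignment parameters

The chimeric splitter is a gap-free seed-and-extend local aligner:
exact 20-mer seeds on both strands, chained per diagonal, with query
gaps up to 35 bp bridged (one chain absorbs isolated substitutions; the
identity is then computed by direct comparison). Defaults: minimum
segment length 20 bp, minimum identity 0.9, scoring match +1 /
mismatch −1, greedy segment selection by descending score with query
overlaps < 5 bp tolerated — deliberately consistent with the 5 bp
junction-adjacency rule. The published pipeline delegates these stages
to external aligners without printing thresholds; the values here are
explicit, config-exposed substitutes chosen so that 20 bp MNase
fragments remain detectable. The second pass re-aligns each sub-read
against the full reference and discards segments whose best placement
moves by more than 1 kb or ties between distinct loci.

Adapter trimming removes 3' suffixes matching the standard Illumina
adapters (minimum match 3 bp, 10% mismatches allowed for matches of
≥ 10 bp); pairs shorter than 20 bp after trimming are dropped. Mate
merging requires a ≥ 10 bp overlap with mismatch density ≤ 0.25, the
higher-quality base winning at disagreements. Unmerged mates are
processed as two independent reads; junctions are never called across
mates, only within a sequenced molecule.

## The simulator: what it emulates, and what it does not

`simulate_library()` generates two-fragment proximity-ligation
molecules: fragment lengths Normal(180, 25) truncated at 50 bp;
junction-proximal ends separated by a distance drawn from a truncated
power law `p(d) ∝ d^-1` on [50, 20000] bp (exponent and support
configurable); random fragment orientations; a sonication window of
length Normal(200, 30) placed uniformly on the molecule; 150 bp reads
from both window ends with the second mate reverse-complemented;
constant Q37 qualities; optional i.i.d. substitution errors and PCR
duplicates (duplicates re-read the same window). Anchor pairs inject
loop-like contacts: an anchor with enrichment E receives (E−1)× the
background probability mass of its 500 bp window pair at its distance.
A fraction of events (default 0.2, emulating the ~80% on-target rate of
a real capture experiment) starts outside the target regions.

The truth table records canonical junction coordinates, sonication
ends, duplicate provenance and a `junction_in_read` flag — true when
the junction lies inside the sequenced window with at least 20 bp
(the aligner's minimum segment length) of flank on each side, i.e. the
detectability condition. Recovery statistics are computed over
detectable junctions with both ends inside the enriched region: a
junction with one end outside the panel cannot be split against the
region sequences and is outside the method's (region-local) scope.

Not simulated: indels, optical duplicates, capture-hybridisation
thermodynamics, chromatin-driven fragment-position bias, and multi-way
concatemers — the ligated molecule always contains exactly two
fragments, matching the pairwise junction model of the caller (reads
with ≥ 3 segments are still handled downstream: each consecutive pair
yields a junction). Passing tests therefore demonstrate the
correctness of the reconstruction logic under the stated library
geometry, not robustness to every artefact of real sequencing data.

One practical note for anchor-based checks: an anchor placed on a bin
boundary genuinely splits its signal across neighbouring bin pairs, so
enrichment assertions place anchors at bin centres.

## Problem sizes and determinism

The test-suite simulations use 50 kb genomes with a 30 kb enriched
region and 300–20,000 ligation events; the largest case (20,000 events,
the full pipeline plus a 50× anchor check) runs in about a minute on one
core. All randomness flows through explicit integer seeds
(`withr::with_seed`), and reruns with the same configuration produce
byte-identical FASTQ, truth tables, junction tables and matrices.

## Known limitations

* The aligner is gap-free; indel-containing segments will be split or
  truncated rather than aligned through the indel.
* Single-linkage wobble clustering can, in principle, chain distinct
  but unluckily close molecules; at realistic junction densities this
  is negligible (the dedup ratio on simulated data is ~1.0) but it is
  the permissive extreme of the wobble definition.
* No genome-wide uniqueness screen is applied to capture oligos (a
  k-mer off-target check would need a genome index); repeat filtering
  relies on the soft-masking of the input FASTA.
* Inter-chromosomal junctions are carried through tables but matrices
  are intra-regional by construction.
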