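---
title: "Breakpoint localization for balanced rearrangements from long reads: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint localization for balanced rearrangements from long reads: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanobnd)
```

## The problem

Balanced reciprocal translocations and inversions exchange or flip
chromosomal segments without changing copy number, so they are invisible to
arrays and very hard to localize with short reads, yet their exact
breakpoints matter clinically (gene disruption, preimplantation genetic
testing). Low-coverage (~10×) nanopore sequencing resolves them because a
single 10–20 kb read can span a junction with kilobases of uniquely mappable
sequence on both sides. A read that crosses a junction aligns as a *chimeric*
(split) alignment: a primary record plus SA-linked supplementary records,
whose boundary on the read marks the breakpoint.

`nanobnd` implements the full desk-side analysis around that signal:
split-read evidence extraction, clustering into consensus breakend (BND)
calls, reciprocal pairing with junction micro-indel sizing, merging of two
call sets, windowed read-depth copy-number estimation in no-control mode,
and read-backed haplotype phasing around breakpoints. A synthetic-data
module generates rearranged diploid genomes, nanopore-like reads, and
emulated alignments with complete truth tables, so every stage is testable
offline.

## Split-read evidence and breakend calls

For each read, aligned segments (primary + SA-linked supplementary; never
secondary) are ordered by their position *on the read* (computed from the
CIGAR including clips). Each adjacent pair passing quality gates
(`min_mapq` = 20, `min_segment_len` = 200 bases) yields one junction
observation:

* the read-proximal segment contributes its read-distal reference end
  (`ref_end` on `+`, `ref_start` on `-`) — the breakpoint is assigned to the
  *last aligned base* of that segment, which makes the reciprocal-gap
  arithmetic below exact;
* the read-distal segment contributes its read-proximal end;
* unaligned read bases between the segments (`read_gap`) measure inserted
  sequence at the junction;
* each breakend carries a side — `end` when retained sequence runs up to the
  breakend, `start` when it resumes there — printed as `+`/`-` in the
  two-character orientation. A reciprocal translocation produces `+-` and
  `-+` junctions, an inversion `++` and `--`.

Segments may overlap on the read by up to half the shorter segment
(nanopore aligners jitter at junctions); reads with three or more segments
contribute each adjacency independently. Intra-chromosomal same-strand pairs
spanning less than `min_sv_len` = 50 bases are discarded as alignment
artifacts; translocation evidence is always kept.

Evidence is clustered by single linkage within (chromosome pair,
orientation) strata: two observations link when **both** breakends are
within `cluster_tol` = 1000 bases. One kilobase comfortably exceeds nanopore
junction jitter while keeping karyotype-scale events unambiguous; opposite
orientations never merge, so the two junctions of a reciprocal event stay
separate even when their breakends nearly coincide. The consensus position
is the lower-middle median of member breakends (a deterministic tie-break);
the confidence interval spans the members' extremes. Support counts distinct
reads. Calls with support below `min_support` = 3 are *flagged*, not
dropped: the original pipeline ran its callers at support 1 and relied on
manual inspection, which this toolkit replaces with an explicit quality
gate. Breakends within 5 kb of a reference N-run of 100+ bases (centromeres,
assembly gaps) are marked imprecise — split alignments into such regions
cannot pin a junction to a base.

### Reciprocal pairing and micro-indels

Two calls on the same chromosome pair with complementary orientations and
breakends within 1 Mb are the two derivatives of one event. On each
chromosome one junction carries the stop breakend (side `end`) and the other
the resume breakend (side `start`); the signed reciprocal gap

```
gap = (resume - 1) - stop
```

counts bases present in neither derivative (positive: junction
micro-deletion) or in both (negative: duplication). A 79-base micro-deletion
with stop 20,656,021 and resume 20,656,101 covers the inclusive interval
20,656,022–20,656,100.

**Per-breakpoint spanning reads.** A chromosomal breakpoint of a reciprocal
event participates in *both* derivative junctions. In a heterozygous carrier
at 10× total coverage each derivative is covered at roughly 5×, so
single-junction support is ~5 while the per-breakpoint spanning-read count —
the sum over the two paired junctions, reported as `support_total` by
`pair_reciprocal()` — is ~10. That is the quantity comparable to published
per-breakpoint read counts.

### Merging call sets

Following the practice of combining two independent callers for inversions,
`merge_callsets()` matches calls across sets on (chromosome pair,
orientation) with both breakends within `merge_tol` = 200 bases, takes the
union of supporting reads (the VCF writer stores them under `RNAMES` so
external sets can participate), and a support-weighted lower-middle median
position. The operation is commutative and idempotent on
(locus, mate, orientation, read union); unmatched calls are retained with a
source tag.

## Read-depth copy number (no-control mode)

Reads are counted in consecutive, non-overlapping windows
(`cnv_window` = 10 kb), each read once, in the window containing its primary
alignment start — a partition, so counts are conserved. Windows that are
less than half non-N are masked. Each count becomes
`log2((count + 0.5) / (median + 0.5))` against the sample-wide median (the
0.5 pseudo-count keeps sparse windows finite). The source protocol names a
10 kb window size in its methods and a 100 kb size in its results; the
window is a configuration knob with 10 kb as default.

At ~10× a 10 kb window holds only ~8 read starts, so per-window ratios are
Poisson-noisy. Segmentation therefore (1) smooths the log2 track with a
15-window running median, (2) merges consecutive windows on the same side of
`±cnv_log2_thresh` (0.4), folding non-neutral runs shorter than
`cnv_min_windows` (3) into the background and bridging short neutral gaps
between same-sign runs, and (3) polishes each call boundary against the raw
counts with a local two-rate Poisson changepoint fit, with the neutral rate
fixed at the sample median count. On simulated heterozygous 2 Mb deletions
at 10× the boundary error is typically 0–1 window (median ≤ 2 across
replicates), with occasional multi-window excursions where a stretch of
windows is genuinely ambiguous between the two rates — an information limit
at these counts, not an estimator artifact. No GC or mappability correction
is applied (the no-control protocol defines none); this is a documented
limitation for real genomes.

## Breakpoint-anchored phasing

Within `phase_flank` = 2 Mb on each side of a breakpoint, heterozygous SNVs
are detected from the pileup of primary alignments (depth ≥ 5, non-reference
allele fraction in [0.2, 0.8]; indels are excluded — indel alleles in noisy
long reads would need an error model the protocol does not supply). Each
read is reduced to its alleles at those sites (reference 0, alternate 1,
anything else missing), and the reads are bipartitioned to minimize MEC —
the number of matrix entries that must be flipped for each partition to be
allele-consistent. Instances of up to 12 reads are solved exactly by
enumeration; larger ones by a positional sweep seed (reads joined left to
right against the running consensus) plus iterative reassignment with random
restarts, deterministic given `rng_seed`. The exact small-instance mode
doubles as an internal oracle for the heuristic. The upstream protocol used
an HMM-based phaser for this stage; the contract — reads in, two haplotypes
plus an SV assignment out — is preserved under the MEC formulation.

Sites are grouped into *phase sets*: connected components of sites linked by
reads covering both. Haplotype labels are arbitrary across phase sets, and
switch errors are only defined within a set. The rearrangement is assigned
to a haplotype when at least 80% of the junction-supporting reads present in
the matrix fall in one partition (at least 2 such reads); 80% is a
conservative default in the absence of published guidance.

## The synthetic-data module

The generator is a first-class part of the toolkit and defines the study
conditions used throughout the tests:

* **References**: uniform-random contigs, optionally stamped with a 300-base
  Alu-like repeat unit and N-runs, byte-reproducible per seed.
* **Diploids**: haplotype 2 carries heterozygous substitutions at a
  Bernoulli rate (0.001 in phasing experiments, ~1 SNV/kb) and, when it is
  the event carrier, the rearranged chromosomes.
* **Rearrangements**: reciprocal translocations and inversions with junction
  micro-deletions (negative values model junction duplications) and novel
  junction insertions. Deletions remove bases immediately distal to the
  breakpoint on the resuming fragment. Every derivative carries a block map
  back to reference coordinates and a junction truth table.
* **Reads**: starts uniform per haplotype; equally sized haplotypes
  alternate strictly, unequal ones (planted deletions) are sampled in
  proportion to their genome size. Lengths are lognormal (mean 13 kb,
  `sdlog` 0.55, truncated to 1–100 kb), chosen so the length N50 exceeds the
  mean as in real nanopore libraries (observed N50 ~15–20 kb at mean
  ~13 kb). The error model applies per-base mismatches (6%), insertions
  (4%) and deletions (5%), giving BLAST-style identity ≈ 0.85 — the R9.4
  regime.
* **Alignments**: the simulator emits SAM directly (aligner emulation): one
  record per reference block a read overlaps, the longest segment primary,
  the rest SA-linked supplementary with soft clips, CIGAR and `NM`
  consistent with the realized errors. This keeps the whole pipeline
  testable without an external aligner; it also means simulated junction
  positions carry no aligner jitter, so position-tolerance checks on noisy
  data exercise the machinery rather than aligner behavior. Features of real
  data that are *not* emulated: mapping ambiguity in repeats, reference
  bias, homopolymer error structure, basecalling quality scores, and
  chimeric artifacts. Passing tests therefore demonstrate correctness of the
  calling logic under the stated noise model, not end-to-end performance on
  real genomes.

`sequences = FALSE` runs the simulator structurally (CIGARs and tallies are
still realized; SAM `SEQ` is `*`) for experiments that only need positions
and counts.

## Numerical and design choices

* All user-facing coordinates are 1-based inclusive; interval arithmetic at
  I/O boundaries (BED/BEDPE) is 0-based half-open, converted exactly once.
* Identity is BLAST-style (gap columns in the denominator), not
  gap-compressed.
* Depth and coverage rate use the non-N reference length as denominator;
  assembly gaps cannot be covered.
* Medians over even counts take the lower-middle element everywhere — a
  deterministic tie-break.
* BED containment of a breakend is half-open on the 0-based coordinate of
  the breakend base.
* `min_mapq` defaults to 20 although the original callers ran unfiltered;
  the manual review stage they relied on is replaced by this gate.

## Problem sizes in the test suite

Simulations in the tests run on 0.3–10 Mb contigs at 10×: two 1 Mb contigs
for translocation recovery (20 noisy replicates), 0.6 Mb diploids for
phasing (~190 het sites, ~460 reads), a 10 Mb chromosome for the 2 Mb
deletion, and fifty 5 Mb flat-coverage null replicates for the CNV
false-positive rate. These sizes preserve the governing ratios of the study
conditions (coverage per haplotype, reads per window, SNVs per read) at
desk scale.

## Known limitations

* CNV estimation has no matched-control mode and no GC/mappability
  correction; the sample-median normalization assumes most of the genome is
  copy-neutral.
* The pileup het-site detector uses only depth and allele-fraction gates.
  That is adequate for the noiseless phasing experiments and for pre-called
  site lists, but on real ~85%-identity reads at 10× it would admit
  error-pileup artifacts; heterozygous sites for real data should come from
  a quality-aware SNV caller and be passed to `allele_matrix()` directly.
* Only SNVs are used for phasing; indel-only regions go unphased.
* Insertions, deletions and duplications away from junctions are out of
  scope — the focus is balanced translocation and inversion breakpoints.
* Genotyping likelihoods and multi-sample calling are not provided.
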