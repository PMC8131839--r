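---
title: "Searching noncoding RNA families in hybrid assembly graphs"
author: "graphRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching noncoding RNA families in hybrid assembly graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphRNA)
```

## The problem

A noncoding RNA (ncRNA) family is recognised by conserved sequence *and*
conserved nested base-pairing, which is why family models are stochastic
context-free grammar profiles rather than plain sequence profiles. In
metagenomes the reads are ~100 nt while many families are longer, so the
two standard strategies both lose homologs: classifying reads one at a
time misses any member whose conserved structure is split across reads,
and searching assembled contigs misses everything the assembler's
simplifications discarded — which is disproportionately the low-abundance
organisms. This package takes the intermediate representation seriously:
it searches *paths of an assembly graph* that deliberately retains
low-coverage structure, then maps the reads onto the homologous paths to
annotate and quantify each family.

## The hybrid assembly graph

Two graphs are built from the same reads and merged.

The **string graph** connects reads by maximal exact suffix–prefix
overlaps of at least `min_overlap` bases (both orientations; contained and
duplicate reads are absorbed into their container and re-emitted at read
assignment, so quantification counts every read). Overlaps implied by a
two-step chain are removed (transitive reduction), and unbranched chains
are condensed into unitig segments. It is accurate but fragments wherever
coverage dips below the overlap threshold.

The **de Bruijn graph** connects reads through shared k-mers (canonical
strand folding, multiplicity filter `min_kmer_count`). Its maximal
non-branching paths are extracted as contigs; no tip clipping or bubble
popping is done, since preserving low-coverage structure is the point. A
contig is *verified* when every base is covered by at least one read
placement. Placements are seed-anchored ungapped alignments tolerating up
to 5% mismatches, clipped only at contig ends: this is how a read mapper
establishes coverage, and on error-bearing reads it is the only workable
reading — requiring exact full-length occurrences would reject essentially
every contig longer than a few hundred bases at a 1% error rate (the
chance that every position is covered by a fully error-free read is
`exp(-L * exp(-c * 0.99^rl))`-small). A chimeric junction spelled by k-mer
chaining but crossed by no single read still fails verification, which is
the purpose of the rule.

**Merging.** Each open end (degree-0 end) of a condensed string-graph
segment is locally aligned to every verified contig under the read-mapper
scoring scheme (+1 match, −4 mismatch, affine gap `−6 − len`). An
alignment is *recruited* if score ≥ 45, aligned query length ≥ 100 (both
inclusive) and the open end is flush. Per contig:

* ≥ 2 recruited alignments: every orientation-consistent ordered pair
  (right-facing end upstream of a left-facing end) is connected through
  the intervening contig interval. A zero-length interval becomes a direct
  junction; a *negative* interval (the two spans overlap on the contig,
  which is exactly what a coverage dip with `k − 1 ≤ overlap <
  min_overlap` produces) becomes a direct link carrying that overlap,
  after checking that the two segment ends actually agree on the shared
  sequence. Pairs bridged by a fully interposed recruited segment are
  skipped: on a fragmented graph the all-pairs rule would add O(n²)
  connectors per contig while the chain already spells the same walks.
* exactly 1: the open end is extended by the contig overhang beyond the
  aligned span.
* 0: the contig is retained as an isolated segment.

Connectors and extensions are always *new* segments attached by links, so
the string graph is a subgraph of the hybrid graph — an invariant the
tests check. Only the alignment step caps the query at `max_query_tail`
bases from the open end; bases further away cannot affect any junction.

Why merging helps is easiest to see on an engineered fixture
(`simulateCoverageDip()`): error-free reads tile a random 300–500 bp
genome except at one junction where the two flanking reads overlap by only
16 bases. With `min_overlap = 20` the string graph always splits there;
with `k = 15` the de Bruijn contig still bridges the junction (16 ≥ k−1),
gets recruited by both components, and the hybrid graph spells the genome.
The classic illustration of this uses a miniature genome with 3-mers and a
minimum overlap of 4; those constants only work below ~60 bp (there are
only 64 distinct 3-mers, and random 4-mer matches appear by the hundreds
on longer sequences), so the package realises the same property at the
smallest self-consistent scale instead.

## The family model and its alignment

`buildProfileModel()` turns a Stockholm alignment with an `SS_cons` line
into a simplified covariance model: consensus columns are columns with at
most 50% gaps; nested bracket pairs restricted to consensus columns form
the pair set (pseudoknot letters are rejected); emissions are
Laplace-smoothed log2 odds against the background (pseudocount 1), with a
16-cell joint table per pair. Deleting a consensus column costs
`gapPenalty` (−2 bits, twice for a pair) and each inserted target base
costs `insertPenalty` (−2 bits). These are deliberately simple linear
penalties: the full profile-HMM-style position-specific transitions of a
real covariance model are not reimplemented, and neither are E-values or
truncated-alignment scoring — stringency is expressed directly on the bit
score.

`alignModel()` compiles the model into a guide tree (left-emit,
right-emit, pair, bifurcation nodes) and runs a CYK-style dynamic program
over target intervals, always local in the target, on both strands. In
`"local_in_model"` mode the columns outside any structural subtree may be
truncated at no cost; this is the principled version of "truncate a prefix
and suffix", because truncating half of a base pair is structurally
meaningless. One consequence worth knowing: subtrees are intervals
produced by peeling the model from the outside in, so a hit covering only
the model's 5′ half is represented as a subtree with internal deletions
rather than a shorter model span — extension budgets derived from such
hits are conservative. The engine was checked cell-for-cell against an
independent memoised recursion over the grammar on every structure shape
(including multiloops) at small sizes.

Long targets are scanned in half-overlapping windows of about 2.5 model
lengths, and `scanEdges()` pre-screens each edge with a structure-free
profile Smith–Waterman at half the reporting threshold — the same role the
HMM filter pipeline plays in production covariance-model search — plus an
admissible length bound (no aligned base can contribute more than the best
emission unit).

## Stage two: anchors, extension, classification, assignment

For each family: every hybrid-graph edge is scanned in model-local mode;
edges reaching `anchor_threshold` (default 0.4 × the gathering threshold;
the source method leaves this unspecified) become anchors. Each anchor is
extended depth-first in both directions by at most the unaligned model
prefix/suffix length plus 10% slack, truncating the final edge to the
budget; every branch combination, plus the unextended anchor, is a
candidate path (capped by `max_paths_per_anchor` and `max_path_depth`).
Candidates are de-duplicated by greedy containment clustering at 95%
identity over the shorter sequence (longest-first, either strand), the
survivors are re-aligned in model-global mode, and paths reaching the
family's gathering threshold are the homologous paths. They are templates
for read classification, not assembled genes.

A read is assigned to a family when it aligns (read-mapper scoring, both
strands) to some homologous path with strictly more than
`read_cover_frac = 60%` of its length inside the path's model-aligned
region, mirroring the ground-truth rule; the read's best-scoring
qualifying path wins, and family abundance is the assigned-read count.
Requiring only a 1-base overlap with the model region instead would turn
every flanking read on a long unitig into a false positive, so the
symmetric fraction is the only reading consistent with the method's
reported precision.

## Evaluation

Ground truth: a read is a family positive when the overlap between its
source interval and an annotated family interval strictly exceeds 60% of
the read length. Recall = TP/(TP+FN), precision = TP/(TP+FP), F is their
harmonic mean; undefined ratios are reported as 0 with a `degenerate`
flag, and the mean across families is unweighted. ROC curves sweep the
classification bit-score cutoff (this engine has no E-values), are
extrapolated to (recall 0, precision 1) and (recall 1, precision 0), and
integrated over recall by trapezoids, averaging duplicate recalls.

## The synthetic community

`simulateFamily()` builds a toy family: a random consensus with one
complementary hairpin stem, alignment rows at 3–5% per-column divergence
(stem columns re-complemented so the structure signal is real), and the
model built from them. The gathering threshold follows the curated-
database convention — low enough that every known member passes — applied
to the synthetic member population: the minimum model-global score of 50
sequences drawn from the model. `plantGenomes()` embeds model-sampled
instances at non-overlapping positions on random strands of i.i.d. uniform
background genomes and records every insertion as a truth interval;
`simulateReads()` draws fragments proportional to abundance × length
(uniform or geometric "staggered" profiles, default ratio 2), clamps a
normal fragment length, emits paired reads from fragment ends (mate on the
opposite strand) and applies i.i.d. substitution errors — no indels, so
exact-overlap assembly remains exercisable; no quality-score or GC-bias
modelling. Family and community use distinct seed streams so a planted
background can never replay the family consensus.

What the generator does *not* emulate — real genome composition, repeat
families, chimeric fragments, indel errors, platform quality profiles —
bounds what green tests mean: they demonstrate the algorithmic properties
(dip rescue, split-instance recovery, graph-over-read dominance), not
field performance on real metagenomes.

## Parameter choices for raw reads

The package defaults (`min_overlap = 45`, `k = 21`, `min_kmer_count = 1`)
suit error-corrected reads, where exact overlaps are long-lived. For raw
1%-error reads the controlling fact is that an exact overlap of length *w*
between two reads survives with probability `0.99^(2w)` — 0.40 at w = 45
but 0.74 at w = 15 — and that a k-mer must be seen error-free at least
twice to pass `min_kmer_count = 2` (expected clean multiplicity
`c · (rl − k + 1)/rl · 0.99^k`). The documented raw-read profile is
therefore `min_overlap = 15`, `k = 13`, `min_kmer_count = 2`: spurious
15-base exact matches are vanishingly rare (4⁻¹⁵), while the graph stays
connected at 10× coverage. The reference experiment
(`scripts/acceptance.R`) runs a 5-genome community, 1500 bp genomes, 20
planted instances of a 150-column family, 10× coverage, 100 nt paired
reads at 1% error — about 750 reads, sized so the whole experiment runs in
minutes on one core; the same code scales to larger communities by
changing `SimConfig`.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open throughout. `N` bases never match: they
cannot extend overlaps or form k-mers, score as mismatches in the local
aligner, and carry a fixed −2-bit emission in the model. Thresholds stated
as minima are inclusive. Ties in dynamic programs resolve to the first
maximising cell in scan order, making results deterministic; all
randomness flows from explicit integer seeds, and samplers restore the
caller's RNG state. Empty inputs return empty results rather than errors
wherever a sensible empty value exists (no reads for verification is the
exception: contigs become unverified). Reciprocal duplicate connections
are collapsed; a pair whose junction sequences disagree (read errors at
the junction) is skipped with a warning count rather than an error.

## Known limitations

Truncated homologs at graph dead-ends score against the full model with
deletion penalties (no truncated-alignment mode), so families whose
instances sit in barely-covered regions lose recall before they lose
precision. The redundancy step keeps the longest cluster member, which can
occasionally represent a cluster by a noisier super-path. Bifurcation
nodes make the dynamic program cubic in the window size, so deeply
multiloop-structured models scan more slowly. Paired-end information is
not used to constrain path extension.
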