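---
title: "Methods: consensus-read correction and partition-based OTU clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus-read correction and partition-based OTU clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rolling-circle amplification of self-ligated amplicons followed by nanopore
sequencing yields long reads containing several physically linked copies of
one amplicon. Aligning those copies and calling their consensus produces a
single "concatemer-consensus" read per molecule with a residual error rate of
roughly 2–3%. Two artifacts survive that consensus step and defeat naive
downstream analysis:

* **Circular permutation.** Fragmentation of the rolling-circle product is
  sequence-agnostic, so the consensus read is a rotated version of the
  amplicon: the forward and reverse primers sit co-located somewhere in the
  middle of the read (possibly on the reverse strand) instead of flanking it.
* **Tandem-repeat insertions.** 60–75% of consensus reads carry a spurious
  insertion made of two or more adjacent, near-identical copies of a local
  segment (median sizes 12–62 bp, rarely beyond 1,500 bp).

`nanoamplikit` implements the two post-processing stages that repair and
exploit such reads — chopSeq-style read correction and nanoClust-style
read-partitioning OTU clustering with within-OTU consensus calling — plus a
simulator that generates reads with exactly these artifacts and a
ground-truth ledger, so the whole pipeline can be exercised and scored with
no sequencer data.

## chopSeq: re-orientation, repeat removal, size selection

For each read, the forward primer and the reverse-complemented reverse
primer are aligned locally against the read (plus-strand hypothesis) and
against the reverse-complemented read (minus-strand hypothesis; by
reverse-complement symmetry this equals aligning the reverse-complemented
forward primer and the reverse primer on the read). Degenerate primer bases
(R/M/W in the default 8F/1387R pair) count as matches against any base of
their IUPAC expansion. A hit is accepted when its score reaches
`primer_accept_fraction` (default 0.6) of the maximal score; the strand
hypothesis with the higher mean accepted-hit score wins, and a hypothesis
with a missing primer scores `-Inf`. Reads with only one acceptable primer
hit have no defined rotation point and are discarded (and counted).

The read is then cut at the forward-primer start: the suffix becomes the
forward split, the prefix the reverse split, and any overhang in the reverse
split beyond the reverse-primer hit is trimmed. Tandem repeats are detected
within each split independently (observed repeats sit within the splits
rather than straddling the junction) by a windowed scan: for window sizes
descending from 350 bp to 10 bp, two adjacent windows of size `w` are
compared by global-alignment identity, and a hit requires identity at or
above a threshold that falls linearly from 92% at 10 bp to 70% at 350 bp —
longer repeats tolerate more divergence between copies. Hits extend over
consecutive copies, and larger windows claim their spans first, so maximal
repeats are reported without overlap; all copies beyond the first are
excised. The two defaults at the window endpoints are tunable; 92% at the
smallest window requires a 10-mer to repeat exactly, which keeps the
false-positive rate on repeat-free sequence at the per-ten-thousand-reads
level (at a 90% endpoint, a single chance match in ten makes short spurious
"repeats" common on random sequence). Splits are merged and only reads of
1,300–1,450 bp are kept.

Two implementation notes. First, the window comparison uses the *global*
(end-gaps-penalised) alignment identity over all columns: a score-maximising
ends-free alignment of two short windows can legally align a tiny
high-identity overlap and report near-100% identity, which floods the scan
with false positives. Second, the literal scan over every (position, window)
pair is quadratic in window range and infeasible at scale; candidates are
restricted to positions sharing an exact k-mer (k = min(8, smallest window))
at an in-range distance, verified by a Hamming fast-accept and then a banded
alignment. Planted-repeat recovery and repeat-free negative controls in the
test suite exercise the equivalence of this anchored scan with the intended
semantics.

## nanoClust: partition, cluster, recruit, consensus

Corrected reads are sliced at fixed coordinates (default
`0,450,451,900,901,1300`: three partitions of 450, 450 and 400 bp — the
per-slice *absolute* error count is what makes a fixed 97% identity
threshold workable at a ~2.5% error rate). Within each partition the
slices are dereplicated (exact string equality, abundance-sorted,
first-seen tie order), screened for two-parent chimeras, and clustered
greedily at 97% identity. The partition producing the most non-singleton
OTUs wins (ties: more reads retained, then lower partition index); its
read-id bins recruit the full-length corrected reads, each bin gates
members to ±10% of its own mean length, and the first 50 gated reads (file
order) are aligned and collapsed into a majority consensus per OTU.
Singleton OTUs are discarded throughout.

Three design choices here deserve their reasoning:

* **Clustering identity is substitution-only.** Identity is
  `matches / (matches + mismatches)` over the ends-free alignment, with gap
  columns excluded, under a scoring scheme in which gaps are cheaper than
  mismatches (`match +2, mismatch -2, gap open -0.5, gap extend -1`), so
  nearby indels in the two reads align as gaps rather than as runs of
  spurious mismatches. With deletion-dominated noise at 2–3% per read, a
  column-counting identity between two same-species reads sits near 94–95%
  — below the 97% threshold, so every read would found its own centroid
  and de novo clustering would dissolve into singletons (exactly the
  failure mode that motivates partitioning in the first place, and the
  reason naive full-length clustering of such reads inflates richness by
  two orders of magnitude). Species in 16S data are separated by
  substitutions, which this identity preserves: same-species slice pairs
  score ~99%, cross-species pairs ~90–95% at the mock's 5% reference
  divergence, so the hard-coded 97% threshold keeps its meaning.
* **Greedy membership is decided against cluster members, not the founder
  alone.** Clusters are tried nearest-founder-first (by 6-mer distance,
  ties in founding order) and a sequence joins the first cluster holding a
  member at ≥ 97% identity, scanning a bounded core sample of each cluster
  (founder plus earliest twelve members; a cluster whose founder scores
  below 92% is skipped outright). Under founder-only comparison, a founder
  in the upper tail of the per-read error distribution (substitution counts
  are approximately Poisson, so tails are routine at hundreds of reads)
  splits its own species into two internally coherent clusters; and because
  the best partition is chosen by *maximum* OTU count, any partition's
  splits propagate to the final table. Member-linkage makes founder
  atypicality harmless, while chaining across species would require a read
  within 3% of both of two clusters ≥ 5% apart — impossible at these
  divergences.
* **Consensus ties favour bases over gaps.** In the majority vote a column
  is dropped only when the gap is *strictly* most frequent; base-vs-gap
  ties keep the base (the platform's dominant error is deletion, so
  gap-favouring ties would compound the known bias), base-vs-base ties go
  lexicographically, and N never beats a concrete base.

The multiple alignment is progressive: average-linkage joining on pairwise
6-mer distances fixes the merge order, and profiles are merged by banded
global alignment of their column frequency vectors. The band half-width is
`max(60, |width difference| + 40)` columns, generous for reads that agree to
within a few percent. An optional `mafft` backend (global-pairwise mode)
produces the same structure when the executable is on the PATH; the test
suite checks that the two backends' consensus identities agree within 0.2
percentage points on synthetic OTUs.

## The simulator

`simulate_run()` draws reads by species abundance from references built as
one random ancestor core flanked by concrete instantiations of the 8F/1387R
primers, with each species carrying at least `0.05 × length` substitutions
(all pairwise identities verified < 95% by alignment). Each read passes
through:

1. **Per-base errors** — substitution/insertion/deletion at
   `0.005/0.005/0.015` per base, with deletion probability raised by
   `homopolymer_del_boost = 0.05` inside homopolymer runs longer than 4 bp.
   This lands the mean read identity near 97.5% (measured band 97–98.5%),
   makes deletions the dominant error, and concentrates the errors that
   survive consensus calling in homopolymers.
2. **Tandem-repeat insertion** — with probability 0.7, a local segment of
   log-normal length (median 30 bp, truncated at the 10 bp observability
   floor, 1% heavy tail up to 1,500 bp; the `1d2` chemistry preset mixes in
   a second, five-fold longer mode to give that chemistry's bimodal shape)
   is duplicated in place into 2–3 adjacent exact copies. Repeats larger
   than the 350 bp scan ceiling are intentionally generated occasionally:
   they are undetectable by design and are the reads the 1,300–1,450 bp
   size selection exists to remove.
3. **Circular permutation and strand flip** — a junction-safe breakpoint
   (uniform over positions outside the inserted repeat copies and outside
   the two primer sites) rotates the read, and the read is
   reverse-complemented with probability 0.5. The joint distribution of
   breakpoints and repeats is not documented for real libraries; this
   choice mirrors the observation that repeats appear within the forward
   and reverse splits, and reflects that a junction inside a primer
   destroys the anchors the consensus process itself needs. It also gives
   the error-free generator an exact round-trip guarantee, which the test
   suite uses as ground truth.

Every choice is logged in a per-read truth ledger (species, rotation,
strand, repeat coordinates, full edit list); replaying the ledger must
reproduce each emitted read byte-for-byte, and the whole run is
deterministic given the seed.

What the simulator does *not* emulate: basecaller pass/fail yields, chimeric
concatemers (removed upstream in the real workflow), abundance biases, and
any correlation of errors across reads beyond the shared homopolymer
geometry of the reference. Passing tests on this generator therefore
demonstrate the pipeline's logic — orientation recovery, repeat excision,
partition clustering, consensus voting — not robustness to every failure
mode of real libraries.

## Evaluation

`reference_accuracy()` aligns each query ends-free against every reference,
keeps the best score, and reports identity, the fraction of the query
covered (diagnostic of misorientation: rotated reads align over ~50–75% of
their length), the query/reference aligned-length ratio (below 1 when
deletions dominate) and typed error counts; a deletion inside a reference
homopolymer run *strictly longer than* 4 bp is typed separately.
`otu_recovery()` scores a consensus set against the truth references at 97%:
detected, spurious (below threshold everywhere, or duplicate hits beyond the
first per reference), and missed.

## Problem sizes and numerical choices

The packaged study conditions are a 10-species equimolar mock, 1,000 reads,
default error model — one seed runs the full pipeline in well under a
minute, and the 20-seed recovery experiment in a few minutes. Consensus
experiments use 20 single-reference OTUs with 10 and 50 reads each.
Alignment scores are computed in single precision (exact for the
integer-and-half scores used), bands are chosen to exceed the maximum
plausible coordinate drift several-fold, and every tie-break in the
pipeline (strand hypotheses, clustering scan order, consensus votes,
partition selection) is fixed and documented so that identical inputs give
identical outputs on any platform.

## Known limitations

* The chimera screen is a simplified two-parent test (prefix/suffix
  identity against more-abundant candidates over a split grid); it is
  exercised with constructed chimeras and can be disabled, but it is not a
  full reimplementation of uchime's voting heuristics.
* The anchored tandem scan requires one exact shared k-mer between adjacent
  copies; copies diverged enough to share none (possible only for noisy
  copies near the similarity threshold, not for the exact duplications the
  consensus artifact produces) would be missed.
* Reads whose permutation junction falls inside a primer site are
  unrecoverable by design and would be discarded in real data; the
  simulator does not generate them.
* Consensus accuracy is bounded by shared deletions: when a majority of
  reads lose the same homopolymer base, the consensus loses it too — this
  reproduces, rather than solves, the platform's residual error mode.
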