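---
title: "Haplotype-aware correction of noisy long reads with variation graphs"
author: "HapCorrect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-aware correction of noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Third-generation long reads (PacBio CLR, Oxford Nanopore) carry 5-15%
errors, dominated by indels. Standard self-correction polishes each read
against a consensus of its overlapping reads. When the sample mixes closely
related sequences — a polyploid genome, a metagenome with several strains at
96-99% average nucleotide identity (ANI) — that consensus is a chimera of
haplotypes: true heterozygous variants look like errors at 50% frequency
and are "corrected" away, so reads lose their haplotype identity exactly
where it matters.

HapCorrect corrects reads against a *graph* rather than a consensus
sequence. Errors and true variants are both branches in that graph; they are
distinguished statistically, not by majority vote.

## The method

Correction runs in two cycles of the same six steps.

**Step 1 — overlaps.** All-vs-all read overlaps come from canonical
(w,k)-minimizer anchors (defaults k = 15, w = 5), clustered by diagonal;
a cluster of at least 4 anchors on one strand yields one overlap record.
Overlaps are filtered: mapped length must exceed 500 bp; self-overlaps and
internal matches (both overhangs on one read exceed
`min(1000, 0.8 x mapped length)`) are removed; and overlaps failing the
mapping-length-ratio test `|1 - min(Lq,Lt)/max(Lq,Lt)| >= e` (default
e = 0.3) are removed. Precomputed PAF overlaps may be supplied instead, so
the correctness of the core never depends on the internal overlapper's
sensitivity. In cycle 2 the mapped substrings of each overlap are also
aligned at base level and the overlap identity (matches / alignment
columns) must reach delta — 0.99 for 5-10% error data, 0.98 for 15% —
which restricts every pile to a single haplotype: after cycle 1 the
residual error is ~0.5%, so same-haplotype overlap identity is at least
1 - 2 x 0.5% = 0.99, while cross-haplotype overlaps at ANI 98% stay near
0.975-0.98.

**Steps 2-3 — pile and windows.** For each target read, every surviving
overlap contributes a fragment: the overlapping read is oriented into
target coordinates, trimmed to the overlap interval (dangling ends
removed), and aligned to the target substring by banded global edit
distance. The traceback gives a monotone column map, along which the pile
is cut into non-overlapping 500-bp windows of the target (the last window
may be shorter). Fragments contributing under 50 bp to a window are
dropped; windows cap fragments at 200 (highest identity kept; inactive at
30x coverage).

**Step 4, cycle 1 — variation graph and pruning.** Per window, a
partial-order-alignment (POA) graph is built: nodes are single
nucleotides, the target subread is the backbone, and each fragment — taken
in decreasing overlap identity, ties broken by read id — is aligned
semi-globally to the current graph (free leading/trailing graph nodes, the
fragment consumed end to end) and fused: matches reuse nodes, mismatches
and insertions create nodes, deletions induce skip edges. Each read is a
walk; edges record which reads traverse them.

Spurious edges are identified with two statistics from frequent itemset
mining. With `p_{r,v}` the Phred-derived base error probability (0 for
FASTA input),

- node weight `w(v) = sum_{r in R(v)} (1 - p_{r,v})` — the expected number
  of reads covering v;
- edge weight `w(e) = sum_{r in R(vi,vj)} (1 - p_i/2 - p_j/2)` — for FASTA
  input exactly the traversal count. (The arithmetic-mean form is the
  method's deliberate approximation of the product `(1-p_i)(1-p_j)`; the
  per-read gap is `(p_i+p_j)/2 - p_i p_j`, negligible at the scale where
  pruning decisions are made, and the approximation preserves the FASTA
  count exactly.)
- `Support(e) = w(e)`; `Confidence(e)` is the larger of `w(e)` over the
  total out-weight of its source and `w(e)` over the total in-weight of
  its sink.

Edges with `Support < s` or `Confidence < c` are pruned (ties kept), where
c = 0.2 and `s = 0.2 x C` with `C = sum_v w(v) / L` the mean per-position
coverage of the window (L = window length). C is recomputed fresh at the
start of every round. After pruning, all window reads are realigned to the
surviving graph — realignment never adds nodes or edges — and statistics
are recomputed; the cycle runs for at most 3 rounds, stopping early when a
round removes nothing (that is our reading of "convergence": zero
removals). The intuition: sequencing errors are random and private to a
read (Support ~ 1 against a threshold of ~0.2 x coverage), while true
variants recur across the reads of their haplotype (a balanced 15/15
bubble in a 30-read window has Support 15 and forward confidence 0.5 —
comfortably retained).

Finally the raw target subread is realigned to the fully pruned graph and
the walk of its optimal alignment is spelled out: target insertions are
dropped, substitutions and deletions are replaced by the graph bases along
the walk. Because both haplotype branches survive pruning, the target's
own alleles anchor the walk on its haplotype. Pre-corrected subreads are
concatenated in window order (Step 5) and all pre-corrected reads merged
(Step 6).

**Step 4, cycle 2 — heaviest bundle.** With piles now haplotype-pure,
per-window graphs are not pruned; instead the maximum-weight
source-to-sink path under the edge weights `w(e)` (the heaviest bundle,
computed by dynamic programming over the topological order) replaces the
target subread. This removes the residual random errors of cycle 1 —
including the occasional wrong allele the target's own sequencing errors
introduced — by a consensus that is now safe, because every read in the
window can be assumed to stem from the same haplotype. Corrected reads
shorter than 500 bp are filtered from the output.

## Statistics on walks

A read "covers" a node when its walk consumes it (match or mismatch); a
deletion-traversed node contributes to the edge statistics of the walk but
not to node coverage (the read exhibits the adjacency, not the base).
After realignment against a pruned graph, a walk may connect two consumed
nodes through an edge the pair no longer has; such pairs simply contribute
to no edge. For FASTQ weighting of a deletion-traversed step, the error
probability of the most recent consumed base is carried forward.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_len` | 500 bp | target-anchored window size |
| `confidence` (c) | 0.2 | minimum edge Confidence |
| `support_factor` | 0.2 | s = support_factor x C |
| `iterations` | 3 | prune/realign rounds |
| `delta` | 0.99 / 0.98 | cycle-2 minimum overlap identity (simulated / real preset) |
| `min_len` | 500 bp | minimum overlap length |
| `max_len_ratio_err` (e) | 0.3 | overlap length-ratio filter |
| `min_window_reads` | 4 | below this a window passes through |
| `min_frag` | 50 bp | minimum fragment contribution per window |
| scoring | 3 / -5 / -4 | match / mismatch / linear gap |
| `band` | 32 | initial alignment band half-width |

Values c = 0.2, s = 0.2C, 3 iterations, 500-bp windows and the delta
presets are the method's published operating point. The POA scores and the
semi-global mode are not published; the defaults follow the convention of
the POA-consensus polishing lineage and are configurable. The value of e
is likewise not printed anywhere; 0.3 matches the convention of the
consensus tool the workflow builds on. The internal-match parameters
(1000 bp / 0.8) are adopted from the overlap-classification heuristic the
method cites.

## Numerical choices

- **Banding.** All pairwise and sequence-to-graph alignments are banded.
  Rather than a fixed 15%-of-length band, the band starts narrow (64 for
  pairwise, 32 for graph alignment), and doubles whenever the optimal path
  touches a band boundary or the end cell is unreachable, falling back to
  the full matrix as a last resort. This returns the same optimum as an
  unbanded computation whenever the narrow band suffices (the common
  case), at a fraction of the cost.
- **Boundary completion.** The free graph ends of the semi-global target
  alignment would silently swallow a deletion of the very first or last
  base of a window (the walk simply starts one node later). The extracted
  walk is therefore extended to a graph source/sink along the heaviest
  incident edges before spelling (`complete_window = TRUE` in
  `correctSubread()`), restoring boundary deletions like interior ones.
- **Tie-breaks.** DP ties resolve in a fixed candidate order (start,
  predecessors in insertion order, insertion move), making every result
  bit-reproducible; the heaviest-bundle traceback prefers the heavier
  incoming edge, then the smaller node id.
- **Degenerate inputs.** Empty sequences are skipped with a warning. A
  window whose graph prunes to nothing passes its raw subread through,
  flagged and counted. Windows with fewer than `min_window_reads`
  fragments pass through. Reads with no surviving overlaps are emitted
  uncorrected (kept by default; a flag drops them).
- **Thresholds.** Pruning uses strict `<`: an edge exactly at s or c is
  kept. Node removal is purely the cleanup of isolated nodes after edge
  removal; no independent node criterion exists.
- **Order effects.** POA construction order matters in principle; the
  backbone is always the target subread and fragments enter by decreasing
  overlap identity with ties broken by read id, so results are independent
  of overlap input order.

## The simulator and what it does (not) emulate

`generateHaplotypes()` mutates a random ancestor independently per
haplotype — ~90% substitutions, ~10% indels of 1-3 bp — with the per-
haplotype rate calibrated so realized pairwise ANI (measured by global
alignment) hits the target within ~0.1 percentage point.
`simulateReads()` draws per-haplotype read counts Poisson at the requested
coverage, lengths Normal(10 kb, 2.5 kb) truncated at [1 kb, L], uniform
start positions, random strands, and injects i.i.d. per-base errors with a
CLR-like mismatch:ins:del mix of 25:35:40; qualities are constant at
`Q = -10 log10(error rate)`. It does **not** model homopolymer-dependent
error, chimeras, coverage waves, or circular genomes. Passing tests on
this generator therefore demonstrate the statistical mechanism — random
errors pruned, recurrent variants kept — not robustness to real-platform
artifacts. One consequence of a 50-kb linear toy genome is pronounced
end effects: windows near haplotype ends have tapering coverage, which
real megabase genomes dilute.

When re-measuring the simulator's own error rate with the evaluator, the
optimal alignment compresses adjacent and cancelling edits, so the
re-estimated rate sits a few percent (relative) below the injected one;
the simulator/evaluator consistency test asserts the rate inside
[0.8e, 1.05e] rather than a naive sampling band.

## Evaluation

`evaluateCorrected()` aligns each read end-to-end (free ends on the
haplotype) to every truth haplotype on both strands and keeps the best;
error rate = (mismatches + insertions + deletions) / alignment columns,
aggregated over reads, and haplotype coverage = fraction of truth bases
covered by at least one aligned read. `haplotypeSNPs()` +
`snpConcordance()` form the haplotype-preservation harness: a corrected
read is concordant when it carries its origin haplotype's allele at every
truth SNP its alignment spans.

## Problem sizes

The package's reference experiment — also what `scripts/acceptance.R`
reruns — is a diploid toy: two 50-kb haplotypes at ANI 98%, 30x coverage
per haplotype, 10% error, ~270 reads of ~10 kb. This is deliberately a
scaled-down analogue of whole-genome polyploid benchmarks: large enough
for ~1000 heterozygous SNPs and stable window statistics, small enough to
run in minutes. On this toy, cycle 1 brings the error rate from ~9% to
under 0.5% (the operating point from which delta = 0.99 is derived), and
cycle 2 reduces it several-fold further while preserving SNP alleles.

## What the SNP-concordance harness shows — and what it cannot

`snpConcordance()` is deliberately all-or-nothing per read: one wrong
allele among the ~160 SNPs a 10-kb read spans marks the whole read
discordant. That makes it exquisitely sensitive to rare failures: with a
per-allele error of p, the per-read statistic is roughly `(1-p)^160`, so
even p = 3×10⁻³ (per-allele concordance 99.7%) caps the per-read fraction
near 60%. On the 50-kb toy the pipeline reaches ~99.6% per-allele
concordance but ~85% per-read, and the failures have a specific anatomy:

1. Cycle 1 flips an allele wherever the *target read itself* errs at a
   SNP position (~10% of SNPs at 10% error; the pruned graph retains both
   branches and an erroneous target base cannot arbitrate between them).
   This is by design — the first cycle protects variation, the second
   repairs alleles by haplotype-pure consensus.
2. Cycle 2 repairs these only where the identity filter leaves a usable
   pile. Reads crossing Poisson coverage dips (30x globally, locally down
   to ~7x per haplotype) come out of cycle 1 with locally elevated
   residual error, which pushes their *whole-overlap* identity just below
   delta = 0.99 — excluding precisely the reads that need the consensus
   most. This self-reinforcing exclusion, together with the toy genome's
   end taper, accounts for the discordant minority.

On a megabase-scale genome the same mechanism operates but each dip
affects a vanishing fraction of reads; on a 50-kb toy every dip is a
visible fraction of the read set. The per-allele concordance, final error
rate, and the cycle-1-to-cycle-2 improvement are the robust quantities at
this scale.

## Known limitations

- The minimizer overlapper is deliberately simple (single best diagonal
  cluster per pair); highly repetitive genomes would need a real chainer —
  use the PAF bypass there.
- Confidence as defined (maximum of the two directions) never falls below
  1 for an edge whose far endpoint has no alternative, so bubble branches
  are pruned by Support alone; this is the published definition, worth
  knowing when tuning c.
- Coverage below ~10x per haplotype leaves too little Support for reliable
  branch classification; windows fall back to pass-through.
- Reads shorter than the window length are corrected as a single window;
  reads under 500 bp after correction are dropped from the output.
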