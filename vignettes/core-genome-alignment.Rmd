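---
title: "Progressive core-genome alignment without a guide tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive core-genome alignment without a guide tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corealign)
```

## The problem

Given N genome assemblies, the *core genome* is the sequence present in every
member of the set; everything absent from at least one member is *accessory*.
corealign identifies and aligns the core by progressive pairwise alignment:
no guide tree is computed, no all-versus-all alignment is performed, and the
result is a multi-genome alignment (MAF and concatenated multi-FASTA)
restricted to the core. The intended scale ranges from bacterial and fungal
assemblies to large eukaryote genomes (with an external pairwise aligner);
this package also includes a compiled seed-and-extend aligner so the whole
pipeline runs self-contained at test scale.

## The procedure

1. **Initial query.** The longest genome with the fewest ambiguous (non-ATGC)
   bases becomes the query; every other genome is a subject, visited in input
   order (optionally by decreasing size). The output can depend on subject
   order; only the initial query is fixed by a rule.
2. **Pairwise alignment.** The current query (the *consensus*) is aligned to
   the next subject, yielding a pool of high-scoring segment pairs (HSPs).
   Two sensitivity modes exist: `low_divergence` (seed k = 15, band 100;
   external preset `asm5`) and `high_divergence` (k = 11, band 400, `asm20`).
   By default, consensus regions that the primary mode leaves uncovered are
   re-aligned once in the high-divergence mode and the pooled HSP set is
   chained together.
3. **Chaining** (per query chromosome):
   - *order* by ascending query start, then descending score;
   - *select* by sequential insertion — an incoming HSP overlapping an
     accepted one by more than half (`overlap_reject_frac`) of the shorter
     interval is kept only if its score is strictly higher than every
     conflicting HSP, which are then displaced;
   - *merge* overlapping (> 1 bp) similar-scored HSPs on the same subject
     chromosome and strand when their subject order is consistent;
   - *resolve conflicts*: with a chromosome homology map, similar-scored
     alternatives hitting different homoeologous chromosomes are decided by
     matching the query chromosome's homology group (important for
     polyploids, e.g. wheat 1A/1B/1D); then crossing pairs — implied
     translocations — lose their lower-scored member, highest-scoring
     conflict first, until the set is order-consistent. Inverted HSPs are
     order-checked on the reversed subject axis, so inversions stay in the
     core;
   - *trim* residual overlaps (the lower-scored HSP loses the overlap) so
     accepted intervals are disjoint, and drop HSPs whose query span is
     below `min_hsp_len` (default 500 bp, inclusive).
4. **Consensus extraction.** The surviving query substrings are concatenated
   per chromosome and become the next iteration's query. Bases are carried
   verbatim (no voting); a coordinate map records each segment's provenance.
   The consensus can only shrink, which is what makes the procedure an
   intersection over the genome set.
5. **Backtracking.** After the last subject, each accepted block of the final
   iteration seeds a core block. Its interval is translated back through
   every coordinate map; the block is split at map discontinuities, and each
   level's subject row is threaded into the profile by *gap projection*:
   per inter-base slot of the shared reference, the merged profile holds the
   slot-wise maximum (union) of the gap columns of the profile and of the
   incoming pairwise alignment; inserted bases are left-aligned within their
   slot. Ungapping a row is invariant under projection, which yields the
   pipeline's load-bearing guarantee: removing the gaps from any row of any
   block reproduces the corresponding genome substring exactly.

Downstream, `core_stats()` reports fragment number, core length, maximum
block length and N50 (all on ungapped reference rows); `jc_distance()`
computes Jukes–Cantor distances d = −(3/4)·ln(1 − (4/3)·p) with p pooled
over all blocks; `nj_tree()` builds a neighbor-joining tree and
`rf_distance()` compares topologies (unrooted Robinson–Foulds, halved).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `overlap_reject_frac` | 0.5 | overlap fraction (of the shorter query interval) above which the lower-scored HSP is rejected |
| `merge_min_overlap` | 1 bp | minimum overlap for merging |
| `similar_score_tol` | 0.1 | relative score difference treated as "similar-scored" |
| `min_hsp_len` | 500 bp | minimum query span, inclusive; applied to accepted HSPs and to emitted core blocks |
| `seed_k` / `band` | 15/100 or 11/400 | internal aligner seed length and diagonal band per sensitivity mode |
| internal scoring | +1/−2/−4/−2 | match, mismatch, gap open, gap extend (a gap of length L costs 4 + 2L) |

## Design choices made where the contract was open

- **Overlap denominator.** ">50% overlap" is measured against the shorter of
  the two query intervals, making rejection symmetric and preventing long
  HSPs from absorbing unlimited short ones.
- **Merged score.** The merged HSP's score is the sum of its components
  (alignment scores are additive over concatenated columns), and merged
  cigars are spliced at the junction from the two originals rather than
  re-aligned, so `chain()` works on interval/score data alone (e.g. PAF
  without sequences). Similarity is judged on raw scores; merging proceeds
  in query order to a fixpoint, so results are independent of input order.
- **Rule precedence.** Chromosome-homology resolution runs before the
  synteny rule: a homoeologous mis-assignment would otherwise masquerade as
  a translocation and be resolved by score alone.
- **Gap union.** The gap-projection post-condition is implemented with
  slot-wise *maximum* rather than summed gap counts: threading k subjects
  then costs |union| columns instead of growing with every pair, the merged
  width equals reference length + |union of gap columns|, and threading
  order does not change the column set. Bases inserted into the same slot by
  different rows are left-aligned; no claim of homology is made between
  them.
- **Block splitting.** Backtracked intervals that cross a consensus-map
  discontinuity are split, never bridged: adjacency that no iteration
  observed is not fabricated. Columns rendered all-gap by splitting are
  deleted, and emitted blocks shorter than `min_hsp_len` (a possible result
  of splitting) are dropped so the length contract holds for the output,
  not just for accepted HSPs.
- **Subject-side coordinates.** Chaining guarantees disjoint *query*
  intervals; subject intervals of different blocks may share a handful of
  junction bases where trimmed query overlaps met. The reference genome's
  rows are strictly disjoint.
- **Distances.** Sites with a gap or N in either row are excluded pairwise
  ("pairwise deletion"; complete deletion is available). Negative NJ branch
  lengths are clamped to zero with the deficit moved to the sister branch.
- **Minus-strand bookkeeping.** Subject intervals are always stored on the
  forward strand with a strand flag; cigars align the forward query against
  the reverse-complemented subject interval. MAF output follows the strict
  reverse-coordinate convention for '-' rows. The external adapter converts
  minimap2's minus-strand cigar orientation (reverse-complemented query vs
  forward target) by reversing the run order.

## The simulator, and what passing tests do and do not show

`simulate_population()` derives N genomes from one random ancestor: per
genome, inversions and translocations first, then accessory insertions of
GC-matched random sequence (so they cannot spuriously align), then small
indels (geometric lengths, capped), then SNPs — with ancestor coordinates
tracked per base. The true core is the ancestor sequence deleted in no
genome; every inserted base is accessory. Defaults emulate a small
population of closely related genomes: 100 kb ancestor over two
chromosomes, five genomes, 1% SNPs, 0.1% indels (geometric p = 0.5, max
50 bp), and two accessory insertions of 2–5 kb per genome.
`simulate_tree_population()` instead evolves substitutions down a given
bifurcating topology, providing ground truth for phylogeny recovery.

The simulator does not model repeat families, recombination, empirical
mutation spectra, or sequencing artefacts, so passing tests demonstrate
algorithmic correctness (coordinate bookkeeping, selection rules, gap
projection, distance arithmetic) rather than performance on real repetitive
genomes — where seeding behaviour and orthology assignment are the hard
part and the external aligner presets matter.

One consequence of the core definition worth knowing: a 2 bp deletion in a
single genome makes those ancestor bases non-core, yet any reasonable
aligner retains them inside a core block as columns with a gap in one row.
Measured precision against the simulated truth is therefore bounded by
1 − (fraction of the ancestor deleted in at least one genome), slightly
below 1 even for a perfect alignment.

## Problem sizes

The test suite and the acceptance script run the full pipeline on 100 kb
ancestors with five to six genomes (seconds per run on one CPU), 500
randomized chaining instances of up to 20 HSPs against a literal replay of
the selection rules, and 50 kb six-taxon phylogeny simulations. The
internal aligner is capped at 5 Mb per sequence; beyond that, use the
external minimap2 adapter (`backend = "external"`), which exchanges PAF
with `cg:Z` cigars.

## Known limitations

- The internal aligner is a test-scale tool: a hash-based exact-seed index
  with greedy chain extraction, not a production minimizer index.
- Subject visit order can change the recovered core (documented above);
  only the initial query is canonical.
- Merging splices cigars at the junction; column-level placement inside a
  merged junction window is approximate even though interval arithmetic and
  the round-trip guarantee are exact.
- One core copy per genome: paralog sets and duplications are out of scope,
  as is re-alignment/polish of final MSA columns.
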