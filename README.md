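# corealign

Guide-tree-free progressive core-genome alignment in R.

Given a set of genome assemblies, `corealign` identifies the **core
genome** — the sequence present in every member of the set — and produces a
multi-genome alignment of it (MAF and concatenated multi-FASTA), together
with Jukes–Cantor distances, a neighbor-joining tree, and core-genome
summary statistics. It is aimed at comparative and population genomics
work where a pangenome's conserved backbone is the object of interest:
fungal isolate panels, cultivar sets, or diverged species groups, including
polyploids where chromosome-homology information (e.g. wheat 1A/1B/1D)
disambiguates orthologues.

## Method in brief

The longest genome with the fewest ambiguous bases becomes the query. The
query is pairwise-aligned to one subject at a time; the pool of high-scoring
segment pairs (HSPs) is chained — ordered by query position and descending
score, filtered at >50% mutual overlap (lower score loses), merged when
similar-scored and order-consistent, cleared of translocation crossings,
and length-filtered (default 500 bp) — and the covered query substrings
become the next iteration's query (*consensus*). Since the consensus only
ever shrinks, after the last subject it approximates the core of the whole
set. A backtracking pass then translates each final block through every
iteration's coordinate map and threads each subject row into a profile by
gap projection (slot-wise union of gap columns on the shared reference),
yielding blocks with one row per genome. The invariant maintained
throughout: removing the gaps from any row of any block reproduces the
corresponding genome substring exactly.

Distances use JC69, d = −(3/4)·ln(1 − (4/3)·p), with p pooled over all
aligned blocks; trees are Saitou–Nei neighbor joining; N50 is the block
length L such that blocks ≥ L contain half the core.

No guide tree is involved at any point, and alignment is core-only — the
two properties that keep memory and runtime flat as genomes get bigger and
more divergent.

## Worked example

```r
library(corealign)

# five genomes descended from a 100 kb ancestor: 1% SNPs, 0.1% indels,
# two 2-5 kb accessory insertions each; the true core is known
sim <- simulate_population(sim_config(seed = 11))
res <- core_align(sim$genomes, outdir = "demo_out")

res$run
#> <progressive_run> query g3 + 4 subjects; final consensus 100,020 bp in 2 sequence(s)
res$core
#> <core_alignment> 5 genomes, 17 blocks, 100,061 aligned columns
str(res$stats)
#> List of 4
#>  $ fragment_number: int 17
#>  $ core_length    : num 99613
#>  $ max_length     : num 18674
#>  $ n50            : num 13041

score_core_recovery(res$core, sim$truth)[c("sensitivity", "precision")]
#> sensitivity 0.996  precision 0.995

tr <- nj_tree(jc_distance(res$core))
cat(ape::write.tree(tr))
#> (g3:0.00981,(g4:0.01011,g5:0.01055):2.57e-05,(g1:0.01012,g2:0.01016):1.6e-05);
```

The pipeline recovered 99.6 kb of the ~100 kb true core in 17 blocks
(accessory insertions and occasional indel clusters fragment the
alignment); 99.6% of true-core bases are in the alignment and 99.5% of
aligned bases are true core. Pairwise JC distances of ~0.02 match the 2 ×
1% substitution divergence between any two genomes, and the star-like tree
reflects the star-shaped simulation.

`demo_out/core.maf` and `demo_out/core.mfa` hold the alignment. A thin
command-line front end covering `simulate`, `align`, `chain`, `stats` and
`tree` is installed at `system.file("cli", "corealign", package =
"corealign")`.

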