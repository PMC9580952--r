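---
title: "Taxonomy-informed clustering of 16S amplicons: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomy-informed clustering of 16S amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ticlust)
```

## The problem

Classic OTU pipelines cluster denoised 16S rRNA amplicons (zOTUs/ASVs) by
sequence identity alone. Because real clades differ in how much sequence
variation a rank contains, a single global cutoff merges sequences from
different genera — and sometimes different families — into one cluster,
then assigns that cluster a single taxonomy. `ticlust` implements the
opposite contract: clustering is *restricted to sequences that share the
same classified taxonomic path*, so a cluster can never span two known
genera or families. Sequences whose classification stops at a shallow rank
are placed incrementally against the clusters that already exist, and
whatever cannot be placed founds novel, deterministically named OTUs.

## The clustering model

Each sequence carries a seven-rank path (domain … species); `NA` marks an
unknown rank. Three nested cluster layers are built:

* **sOTU** — molecular species, 97% identity,
* **gOTU** — genus, 95%,
* **fOTU** — family, 90%,

the conventional whole-molecule 16S cutoffs (`tic_cutoffs()`; tailor them
to your amplicon region, since a V-region captures less variation than the
full gene). The algorithm runs four stages, each seeing the state left by
the previous one:

1. **Genus-known sequences** are partitioned by their full genus path and
   greedy-clustered *within each genus* at the species cutoff. Every
   cluster becomes an sOTU carrying the genus path plus its own novel
   species name.
2. **Family-known sequences** (genus unknown) are compared against the
   sOTU centroids of their family. At ≥ 97% they join the sOTU and adopt
   its full taxonomy; in [95%, 97%) they found a novel sOTU inside the
   hit's genus; otherwise they are deferred. Deferred sequences are
   greedy-clustered at 97% into novel sOTUs, whose centroids are clustered
   at 95% into novel gOTUs within the family.
3. **Order-known sequences** (family unknown) do the same against all
   sOTUs of their order, with one more rule — a hit in [90%, 95%) founds a
   novel sOTU *and* a novel gOTU inside the hit's family — and one more
   deferred layer: novel gOTU centroids are clustered at 90% into novel
   fOTUs.
4. **Everything else** is binned by its deepest known rank (class, phylum,
   domain, nothing) and runs the stage-3 cascade against the sOTUs sharing
   that prefix. Ranks above a novel fOTU that remain unknown are filled
   with the placeholders `UNKORDER`, `UNKCLASS`, `UNKPHYLUM`. No
   placeholder exists for the domain: a fully unclassified sequence keeps
   an unknown domain, the one rank at which output paths may be
   non-contiguous. No OTUs are created above the family rank, because no
   accepted identity cutoffs exist for order and above.

Two consequences follow by construction and are asserted in the test
suite: every cluster is *pure* at every rank its members' input taxonomies
know (known labels are never contradicted, only deepened), and the whole
pipeline is deterministic — independent of input row order.

## Identity, search and greedy clustering

The identity underlying all cutoffs is pinned, because cutoff semantics
are meaningless without it: an optimal Needleman–Wunsch global alignment
under match +1, mismatch −1, gap −2 (linear), scored as matching columns
divided by alignment columns excluding terminal gaps (the "iddef 2"-style
convention of the usual clustering tools). Optimal-alignment ties are
resolved by preferring a substitution over a gap during traceback; since
that tie rule is orientation-dependent, operands are first put in a
canonical order (shorter, then lexicographically smaller sequence first)
so that `global_identity(a, b)` is exactly symmetric. `N`
never counts as a match. The published description leaves the identity
formula to the wrapped clustering tool (which differ among themselves), so
this definition is a documented package choice.

`greedy_cluster()` is an abundance-greedy (AGC) engine: sequences are
processed by size descending (ties by sequence string, then id, in the C
locale), the first founds a cluster, each next joins the best centroid at
or above the threshold (inclusive) or founds a new one. Centroids are
never recomputed. Preordering by abundance rather than input order makes
the result reproducible. Search is exhaustive — no k-mer prefilter — which
is exact and fast enough at desk scale (a full benchmark run is minutes on
one CPU).

During the placement stages, sequences are matched against sOTU
*centroids* only, not all members: it keeps complexity linear and matches
the published description of searching "among sOTUs". Novel sOTUs founded
during a matching pass join the search set immediately (greedy
semantics); deferred sequences are clustered in a batch after the pass.
Both choices are pinned for determinism where the published description is
silent; likewise a [90%, 95%) hit at the order level attaches the novel
gOTU to the *hit's* family (mirroring the adoption logic one level down)
rather than founding an independent fOTU.

## The kNN-LCA classifier

`knn_lca_classify()` places a query at the last common ancestor supported
by at least `consensus` of its `k` closest references (defaults 7 of 10).
Consensus is counted per rank, top-down, stopping at the first rank
without a winning name; whether the published 7-of-10 rule applies per
rank or to whole paths is not stated, and the per-rank reading matches how
LCA classifiers behave. `min_identity` (default 0.5) exists only to
exclude junk hits; with fewer than `k` references available the absolute
consensus count is unchanged.

## Benchmark perturbations

Real classifications are incomplete in two ways, and both are simulated
against a fully labelled community:

* `hard_prune()` removes *whole clades* — novel taxa. At each of the four
  prunable ranks (defaults: 10% of genera, 5% of families, 2.5% of orders,
  1% of classes) the requested fraction of distinct clades is sampled and
  erased for every member, the count rounded *up* so a positive rate on a
  handful of clades still removes one. Note a consequence on the bundled
  fixture, which plants a single synthetic order and class: hard pruning
  always erases them for the entire community, which turns the benchmark
  into a worst-case stress of the deferred novel-fOTU pathway — exactly
  the regime the placeholders exist for.
* `soft_prune()` removes labels per sequence, per rank, independently —
  classifier noise. The marginal chance of losing a genus label is
  `1 − (1−0.10)(1−0.05)(1−0.025)(1−0.01) ≈ 0.175`, and the suite checks
  the realised count against this closed form.

Erasing a rank always erases everything deeper (a sequence cannot know its
genus but not its family), and per-rank sampling is independent, with
shallow erasures dominating — the published text does not specify the
nested-clade interaction, so this is a documented reading. Species is
never pruned directly, only transitively.

## Evaluation metrics

`purity()` is the pooled majority-label fraction `Σ_i max_j n_ij / n`;
sequences whose *true* label is unknown at the evaluated rank are excluded
so pruned labels never count for or against a cluster. The phrase "mean
fraction across all clusters" could also be read macro-averaged, so that
variant is available behind `macro = TRUE`. `adjusted_rand_index()` is the
standard permutation-model ARI from the contingency table (degenerate
cases: a single element, or two identical trivial partitions, are defined
as 1). `normalized_mutual_information()` normalises by the *arithmetic
mean* of the two natural-log entropies — one of several conventions, so it
is pinned and documented. `count_mixed_clusters()` counts clusters whose
members carry two or more distinct known true names at a rank — the
impurity statistic reported per level. All three agree with independent
pair-counting/entropy oracles to 1e-12 in the suite. The evaluation unit
is the unique sequence, never read abundance.

## The synthetic community generator

`make_benchmark()` replaces the external reference datasets with a seeded
community whose ground truth is known exactly: a planted tree of families,
genera, species and zOTUs under one synthetic order/class/phylum, 300 nt
fragments (the scale of an extracted V-region), and divergence tiers
chosen so the 97/95/90 cutoffs separate them with a guard band of at least
0.005 — identities within a species stay above 0.975, between species of a
genus inside (0.955, 0.965), between genera of a family inside
(0.905, 0.945), and across families below 0.895. The guard bands make
parameter recovery *exact*: on the standard fixture (20 families × 5
genera × 5 species × 3 zOTUs = 1,500 sequences) the pipeline must return
exactly 500 sOTUs, 100 gOTUs and 20 fOTUs, not approximately.

Realising those bands deterministically is the one genuinely delicate
design point. Within a family, every edge (genus, species, zOTU)
substitutes a drawn number of *distinct* positions, all edge sets mutually
disjoint, so within-family pairwise divergences are exact sums — e.g. two
species of one genus differ at exactly `2*(m_s + m_z)` positions. Across
families this cannot work: 20 family subtrees would need ~4,800 distinct
positions in a 300 nt fragment, and with ~1.07 million cross-family pairs
the extreme-value tail of random position collisions reliably pushes a few
pairs above any band chosen inside the published-scale tier (we measured
worst-pair identities of 0.91 against a 0.895 requirement). The generator
therefore reserves a *barcode block* of positions in which each family
carries a random word, built by seeded rejection so that every pairwise
word distance lies in a window whose floor alone guarantees cross-family
identity ≤ 0.8933 — no matter how descendant mutations collide. The cost
is honesty about the family tier: its realised divergences run up to
~0.22 rather than the 0.15 a strict reading of "family-level divergence"
might suggest (`between_families` defaults to `c(0.12, 0.22)`), which is
biologically unremarkable (distinct families frequently share < 85%
identity over a V-region) and irrelevant to every cutoff, since 90% is the
lowest one. An exhaustive Hamming audit of all pairs re-checks every band
after generation and regenerates on violation (bounded retries); Hamming
equals alignment identity here because the default generator is
substitution-only (no indels), which keeps the identity arithmetic exact.

Abundances are log-normal (meanlog `log(100)`, sdlog `dispersion`,
default 1 — a realistic heavy tail for amplicon libraries), integerised
with a floor of 1 across `n_samples` (default 10) samples; `dispersion =
0` gives flat counts for testing. Sample count and dispersion are not
constrained by any published value; they were fixed once at these values
and are not tuned against test outcomes.

What a green test on this generator does **not** establish: robustness to
indels and alignment ambiguity, to chimeras, to intra-genome 16S copy
variation, to taxonomies whose true structure violates the identity
cutoffs (real genera overlapping across the 95% line — the adversarial
fixture in the acceptance suite probes exactly that case for the blind
baseline), or to reference databases with conflicting nomenclature.

## Naming and novelty

Novel OTUs are named `sOTU_n` / `gOTU_n` / `fOTU_n` from global counters
in deterministic processing order, so outputs are diffable across runs.
Novelty is carried by the name itself (`is_novel_name()`,
`is_placeholder()`) rather than a parallel flag structure; a cluster's
`novel` column in the result tables is derived from it. sOTUs are *always*
flagged novel: a molecular species is a TIC-defined unit even when its
members carry described species names, and indeed one sOTU may absorb two
described species more than 97% identical — species-rank purity is not
claimed, matching the observation that no identity-based tool recovers
described species exactly.

## Numerical and degenerate-input choices

* Threshold comparisons are inclusive (`identity >= cutoff` joins): "97%"
  conventionally includes 97.0.
* Hit ties are broken by identity, then larger cluster/reference size,
  then id (C locale) — pinned everywhere a tie can occur.
* `adjusted_rand_index` on a single-element universe is 1; NMI of two
  trivial partitions is 1; both are documented edges, not errors.
* Cutoff ordering `family < genus < species` is validated up front.
* All randomness flows through explicit seeds (`sim_params(seed=)`,
  `prune_spec(seed=)`); library calls restore the caller's RNG state.

## Known limitations

Exhaustive search is quadratic in the worst case (everything unclassified)
and intended for desk-scale inputs, roughly ≤ 10⁴ sequences; the fixture's
hard-pruned worst case (1,500 fully order-erased sequences) runs in about
four and a half minutes on one CPU. Cutoffs are global — clade-specific
adaptive cutoffs are out of scope. No OTUs are created above family rank.
The CLI covers region/coverage utilities, clustering, simulation,
benchmarking and classification, but not raw-read processing (primer
trimming, merging, denoising) or reference alignment, which belong to
upstream tools.
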