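---
title: "Discovering ordered conserved motifs in rapidly evolving noncoding sequences"
author: "synmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering ordered conserved motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmotif)
```

## The problem and the model

Long noncoding RNAs and 3'UTRs diverge so quickly that orthologs from
distant species often cannot be aligned at all, even when synteny makes the
orthology certain. What does tend to persist is a small set of short
functional elements — miRNA seed sites, RNA-binding-protein motifs,
polyadenylation signals — of roughly 6–15 nt, and, across long evolutionary
distances, their *linear order*. `synmotif` searches for exactly that
signal: combinations of short exact k-mers that occur in the same order in
an ordered set of putatively homologous sequences.

Two assumptions underlie the model. First, functional elements require exact
conservation of a short core (inexact matching makes the search space
explode and destroys the significance calculus). Second, element order is
preserved, either because order matters for function or because independent
gain of the same ordered combination is rare. Both assumptions fail for some
real elements; what they buy is specificity — an ordered combination of
k-mers is far less likely to arise by chance than the same k-mers scattered
freely. For scale: a fixed 6-mer occurs by chance about once every
`r expected_chance_spacing(6)` nt (`4^6`), so two unrelated multi-kilobase
sequences share many 6-mers; order is what separates signal from that noise.

### The layered graph

Each sequence is a *layer* of nodes; the first sequence is the anchor
(query) and defines layer 1. The remaining layers should be ordered by
increasing evolutionary distance — either given by the user or computed with
`order_by_similarity()`, a greedy chain that repeatedly appends the
unplaced sequence with the best local-alignment score to the previously
placed one. A node is a k-mer window (windows containing ambiguity codes are
skipped); an edge connects identical k-mers in *consecutive* layers.
Conserved ordered combinations correspond to sets of non-crossing paths
anchored in layer 1.

### The integer program

Path selection maximizes the number of selected edges subject to four
constraint families (all binary variables, one per edge):

* **Crossing** — two edges between the same pair of layers whose endpoint
  order is inverted cannot both be selected. Pairs of edges carrying the
  *same* k-mer (repeat networks) are exempt, unless an edge of a different
  k-mer crosses the network; in that case the constraint is imposed so the
  network splits into non-crossing subpaths around the foreign path.
* **Flow balance** — for every node in a layer strictly between the anchor
  and the current minimum depth `y`, the number of selected out-edges equals
  the number of selected in-edges. This forbids paths that stop short of
  depth `y` while still allowing branching into tandem repeats. (The
  formulation scales both sides by a large constant M = 100; the constant
  cancels and the implementation uses the equality directly.)
* **Merge consistency** — overlapping adjacent k-mers may only be selected
  together when the overlap offset is identical in both layers, so that
  merging overlapping selected nodes into a longer motif never absorbs a
  layer-specific insertion.
* **Coverage** — when previously found complex paths are re-inserted
  ("favored"), at least one of their layer-1→2 edges must be selected,
  guaranteeing the refined path survives.

No MILP library is used: the program is solved by an exact branch-and-bound
search (`src/bnb.cpp`) specialized to this structure. Variables are
assigned most-conflicted-first, 1-branch first; conflict propagation fixes
crossing partners to 0; per-constraint counters prune infeasible flow and
coverage states; the bound is the current objective plus the number of
undecided variables. Independent constraint components are solved
separately. The search is exhaustive up to pruning, so the objective is a
proven optimum, and the fixed variable order makes the selected edge set
deterministic. (Ties between optima exist; the package promises a
reproducible optimum, not a canonical one — tests assert objective values
and invariants, never one specific edge set.)

### The elimination schedule

`discover_motifs()` iterates k from `k_max` (default 15) down to `k_min`
(default 6); within each k, the elimination depth `y` runs from the full
dataset depth D down to 2, each time pruning the graph to nodes lying on a
chain from layer 1 to layer `y` and dropping the last layer for the next
iteration. Deep simple paths found early become *partition boundaries*:
subsequent subgraphs only contain nodes strictly between consecutive
boundaries (in every layer), which both shrinks the programs and pins
shorter, shallower motifs into the gaps between deeply conserved ones.
Boundaries accumulate across k values, which is how paths of longer k-mers
constrain the placement of shorter ones.

Complex paths — those with several nodes in some layer, i.e. repeats and
branches — cannot serve as boundaries because in an unconstrained graph one
cannot tell which repeat is the conserved one. They are stored separately
and re-refined at every level: first against each other (deeper paths
protected by coverage constraints), then re-inserted into the current
subgraph and re-solved. Edges of a stored path that lie below the current
depth ride along unchanged, so a deep complex path is never truncated by
refinement at a shallower level.

When a subgraph still exceeds the edge cap (`max_edges`, default 1200,
anything above 50 allowed), its candidate path clusters are optimized one at
a time against the refined set, smallest first, until the remainder fits; a
single cluster that alone exceeds the cap is dropped and only previously
refined paths are kept for it. This trades global optimality for bounded
runtime, by construction.

After all k values, overlapping selected nodes are merged into longer
motifs, nested motifs that are no deeper than their container are absorbed,
and a final consistency pass enforces end-to-end non-intersection: passes at
different k are solved independently, so a shallow motif selected at a long
k can invert order against a deeper motif discovered later at a shorter k;
the pass keeps motifs in priority order (deeper, then longer, then
leftmost) and drops any simple motif that strictly inverts order against a
kept one in a shared layer. Complex motifs are exempt, mirroring the
repeat-network exemption in the crossing constraints.

### Extended 5'/3' ends

Input sets often contain 5'- or 3'-truncated sequences (assembly gaps are
common around G/C-rich first exons). These break layer-by-layer chains for
motifs near the ends. After the primary solution, layers whose first motif
starts later than `t` times the median first-motif start (`t = 0.5` by
default) are taken to have upstream room, and a separate graph over their
upstream windows is built and solved; the 3' side is analogous with
positions normalized by sequence length. The stage runs only when the
anchor itself qualifies. A caveat worth knowing: the qualification rule
selects layers whose first motif is *late* — it harvests upstream sequence
where there is any — so a truncated layer is excluded from the extension
graph (it has no upstream room) and extension motifs are reported at the
reduced depth of the qualifying layers. With `min_depth` set, boundary
positions are computed only from motifs conserved to at least that depth,
and shallower motifs are removed from the solution; this is the intended way
to protect deep-end detection from shallow chance motifs near the ends.

## Significance

Empirical P values come from re-running the entire engine on null datasets:

* **MSA column shuffle** (the stringent null): columns of a multiple
  sequence alignment of the input are permuted uniformly (gaps travel with
  their column) and gaps are then stripped row-wise. Per-row length and
  composition and the *inter-row identity structure* are preserved, so
  motifs that are "significant" merely because the sequences are similar are
  penalized. MAFFT is used when on the PATH (the default); an internal
  center-star progressive aligner (pairwise global alignments merged on the
  anchor with once-a-gap-always-a-gap) is the zero-dependency fallback.
* **Dinucleotide shuffle** (the permissive null): each layer independently
  replaced by an exact dinucleotide-preserving Eulerian-walk shuffle;
  inter-layer identity is destroyed.

For a motif of length L conserved to depth d, `p_exact` is the
pseudo-counted fraction of null runs containing that precise motif at depth
≥ d, and `p_combination` the fraction containing at least as many distinct
motifs of length ≥ L at depth ≥ d. The `(r + 1) / (n + 1)` convention means
P values are never 0 and floor at ~0.01 for the default 100 iterations. One
subtlety: on *near-identical* inputs the column shuffle preserves identity
structure but scrambles the actual strings, so the exact-string P can stay
small while the combination P correctly saturates — for datasets like that,
`p_combination` is the honest test. No multiple-testing correction is
applied; raw empirical P values are reported, and users comparing many
motifs should treat them accordingly.

`motif_enrichment()` answers a different question — is a given (possibly
degenerate IUPAC) pattern over-represented at all, order aside — by
counting occurrences against 1000 dinucleotide-preserving null sets.

## Annotation and reporting

Discovered motifs can be typed against a TargetScan-style miRNA seed table:
a site requires the full 6-mer seed core (reverse complement of miRNA
positions 2–7) inside the motif, and the flanking base on each side decides
the type (8mer > 7mer-m8 / 7mer-A1 > 6mer; only the strongest is reported;
a flank beyond the sequence end is marked end-truncated and cannot upgrade
a site). Anchor motifs can be lifted to genome coordinates through the
query transcript's exon BED (BED12 blocks or BED6 rows, strand-aware,
split across junctions) and intersected with scored interval tracks such as
CLIP peaks; peaks with enrichment below 2 are discarded and peaks covering
more than half the transcript are flagged as broad binders. Reports are
rendered as tab-delimited tables, a JSON dump that round-trips through
`load_solution_json()`, an HTML view with motifs colored by conservation
depth (fixed 20-color palette, recycled) and exon junctions marked, and a
BED9 genome-browser track with depth-encoded `itemRgb`.

Motif *modules* (ordered combinations of ≥ 2 unique motifs per depth, with
tandem repeats collapsed) and *neighborhoods* (all motifs attached to one
merged anchor region, with offsets and flanks against the reference k-mer)
summarize the structure of the solution.

## The synthetic benchmark generator

`plant_spec()` / `generate_planted()` create datasets with known ground
truth: i.i.d. uniform (or first-order Markov) background layers with motifs
planted in a fixed order down to per-motif intended depths, plus the
disruptive features that make real homolog sets hard — per-layer random
insertion blocks (transposon-like), 5' truncations (assembly gaps) and
point substitutions outside motifs. The truth table lists every planted
occurrence and is guaranteed re-readable from the sequences.

What the generator does *not* emulate: phylogenetically correlated
divergence (layers are conditionally independent given the plants), motif
turnover and movement, repeat families and compositional heterogeneity
beyond first-order Markov structure. Passing the planted-recovery tests
therefore demonstrates algorithmic correctness on the stated evolutionary
caricature, not performance on real genomes.

## Validation and problem sizes

The test suite and `scripts/acceptance.R` validate, at these scales:

* exact-solver agreement with full 2^|E| enumeration on 200 random layered
  graphs of ≤ 12 edges (2–4 layers, dense two-letter alphabet);
* equivalence with an independent longest-common-subsequence dynamic
  program on 100 two-layer graphs whose k-mers are unique per layer (with
  k = 1 the selection problem *is* the LCS problem);
* recovery of 4 planted 7–10-mers at depth 5 across 50 seeded fixtures of
  5 × 1000 nt with 100-nt lineage-specific insertions, requiring ≥ 95%
  recovery and zero order inversions among reported simple motifs;
* calibration: planted motifs reach `p_exact` ≤ 0.05 under the 100-iteration
  column-shuffle null, and on unplanted 3 × 400 nt random datasets the
  combination P of the minimal-length depth-2 motif is approximately
  uniform over 200 independent datasets (Kolmogorov–Smirnov, 20 iterations
  each). The uniformity check runs under the dinucleotide null, the one
  under which the empirical P of i.i.d. data is exchangeable and uniformity
  is the theoretical expectation; the column-shuffle null conditions on an
  alignment fitted to the observed adjacency and is deliberately
  conservative on unrelated sequences. Even under the exchangeable null,
  the `(r + 1)/(n + 1)` tie-counting convention on an integer count
  statistic makes P values mildly super-uniform — "approximately" is doing
  real work in that sentence;
* null invariants: 1000 dinucleotide shuffles with zero count-vector
  violations; column shuffles preserving row lengths, composition and
  inter-row identity;
* seed-site typing in exhaustive agreement with an independent naive
  scanner over all 4^9 contexts against 5 seed families.

The 3 × 400 nt calibration datasets and the 5 × 1000 nt recovery fixtures
are small compared to real lncRNA sets (dozens of layers, kilobases); they
were chosen as the smallest sizes at which chance motifs are abundant and
the statistics well-populated.

## Numerical and design choices

* **Coordinates** are 1-based inclusive throughout, the native R and
  IRanges convention; BED I/O converts at the boundary.
* **Alphabet**: uppercase DNA; `U` maps to `T`; other IUPAC letters are
  kept in the sequence but no k-mer window spans them, preventing spurious
  matches through ambiguity codes.
* **Repeat cap**: a k-mer occurring more than `max_repeats` (default 15)
  times in any single layer is excluded from all layers.
* **Internal aligner**: ungapped seed-and-extend (word size 7, match +2,
  mismatch −3) with Karlin–Altschul E-values (λ solved from the score
  distribution; K fixed at 0.3, adequate for thresholding). "Significant"
  for the ordering fallback means E < 0.05; overlapping HSPs keep the
  lowest E-value, ties broken by raw score then leftmost start, and a
  source segment keeps at most one target.
* **HSP containment** is strict: both nodes of an edge must lie entirely
  inside the two sides of the same HSP. Layer pairs with no HSPs are
  unrestricted, so an empty constraint set is never a death sentence.
* **Complex-path depth** is the deepest layer reached by any branch.
* **Degenerate inputs**: D = 2 runs a single depth-2 pass with extensions
  disabled (medians over two values are ill-conditioned) unless forced;
  empty graphs and empty solutions flow through every stage and produce
  valid empty reports.
* **Determinism**: with a fixed seed the whole pipeline — generator, nulls,
  solver — is reproducible bit-for-bit; the solver is single-threaded with
  a fixed variable order.

## Limitations

Exact matching only (no degenerate cores in discovery), a single linear
order of layers (no phylogeny), one isoform per species, and empirical
significance that inherits the quality of the MSA used for the stringent
null. On shallowly diverged inputs the tool reports many long motifs, which
is correct but unhelpful; it is most informative when the most distant
layers are beyond alignment reach.
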