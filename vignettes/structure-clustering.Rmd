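---
title: "Clustering RNA consensus structures by tree edit distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering RNA consensus structures by tree edit distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestclust)
```

## The problem

Families of non-coding RNAs are curated from seed alignments, each with
a consensus secondary structure; *clans* relate families whose homology
is recognizable but whose sequences no longer align, and *RNA classes*
(microRNAs, the two snoRNA classes, CRISPR repeats, ...) group families
by shared structural character without requiring common descent.
`forestclust` implements an unsupervised counterpart to that curation:
every family is reduced to its consensus structure, all pairs of
structures are compared by a full tree edit distance, the distance
matrix is clustered hierarchically, and curated groupings are scored
against the resulting dendrogram. The package covers the whole chain —
Stockholm input, WUSS normalization, the distance, three linkage
methods, concordance scores, SVG rendering and a synthetic data
generator — so each stage can be validated in isolation.

## From WUSS to ordered forests

Consensus structure lines use WUSS notation: bracket families `<>`,
`[]`, `{}`, `()` for nested pairs, `_ - , : . ~` for unpaired
positions, and letter pairs for pseudoknots. `normalize_wuss()` maps
every bracket family to plain parentheses and everything else to dots.
Two consequences are deliberate:

* **Pseudoknots are dropped.** Crossing pairs cannot be represented in
  an ordered tree; their positions become unpaired dots.
* **Nesting is checked per bracket type** with a typed stack, so an
  improperly interleaved string such as `<[>]` is rejected even though
  its projection onto a single bracket alphabet would balance. Rfam
  `SS_cons` strings are properly nested, so this only guards against
  corrupt input.

A dot-bracket string is then read as an ordered forest: each matched
pair an interior PAIR node, each dot an UNPAIRED leaf, sibling order
following string order. Nodes carry no nucleotide labels, since only
structures are compared. The postorder/leftmost-leaf arrays needed by
the distance algorithm are derived from this forest, with a zero-cost
virtual root appended so that multi-rooted forests (external regions of
an RNA) become trees without changing the distance.

## The distance and its cost model

The edit distance is the minimum total cost of node insertions,
deletions and relabelings transforming one forest into the other, with
a deleted node's children promoted to its parent. Costs count
nucleotides: a PAIR node represents two bases (indel cost 2), an
UNPAIRED node one (indel cost 1). The distance of a forest to the empty
forest therefore equals its nucleotide weight, which is simply the
length of its dot-bracket string.

Relabeling costs are not dictated by the indel argument, and this is
the one genuinely open knob of the cost model. The default charges 1
for PAIR ↔ UNPAIRED (the nucleotide-count difference |2 − 1|, and
cheaper than the delete-plus-insert alternative of 3) and 0 between
equal labels. `cost_model()` exposes all three numbers (CLI flags
`--cost-pair`, `--cost-unpaired`, `--cost-sub`); setting the
substitution cost to `indel_pair + indel_unpaired` reproduces a
substitution-free scheme exactly, and a validation rejects values above
that bound because a relabeling must never cost more than an indel
pair. Analyses on real data should report both the default and the
substitution-free variant, since individual published distances are not
available to pin the choice.

The implementation is the keyroot dynamic program of Zhang and Shasha
in C++ (`src/treedist.cpp`), quadratic-ish in practice and exact. An
independent oracle, `brute_force_distance()`, implements the textbook
three-way recursion directly on dot-bracket substrings with
memoization and no keyroot machinery; it refuses forests above 14
nodes. The two routes share nothing but the cost semantics, and the
test suite asserts exact agreement on hundreds of random pairs as well
as the metric axioms (identity, symmetry, triangle inequality) — the
property that motivates tree *editing* over tree *alignment* for
clustering — and the weight bounds
|w(F₁) − w(F₂)| ≤ d ≤ w(F₁) + w(F₂).

Distances are stored as doubles even though the defaults make them
integers, so fractional custom cost models work unchanged. The
all-vs-all stage computes exactly n(n − 1)/2 pairs in input order
(the count is recorded as an attribute and checked in tests) and
serializes as a square PHYLIP matrix in strict (10-character names) or
relaxed dialect.

## Agglomerative clustering

`agglomerate()` starts from singletons and repeatedly unites the two
closest clusters, recording the merge at their current inter-cluster
distance. The method determines the Lance–Williams update after a
merge of X and Y:

* UPGMA (group average, size-weighted):
  D(X ∪ Y, Z) = (|X| D(X,Z) + |Y| D(Y,Z)) / (|X| + |Y|);
* single linkage: min(D(X,Z), D(Y,Z));
* complete linkage: max(D(X,Z), D(Y,Z)).

The size-weighted recursion is the true group average, matching the
UPGMA name; WPGMA is deliberately out. Heights are the raw merge
distances, not halved, so a leaf has height 0 and the cophenetic
distance of two leaves is the height of their lowest common ancestor —
an ultrametric, which the tests verify on random triples.

**Tie-breaking.** Integer-valued distances make exact ties common on
real data. Each cluster is tagged with the smallest original row index
among its members; among tied candidate pairs, the lexicographically
smallest (min tag, max tag) pair merges first. This makes dendrograms
byte-reproducible regardless of internal storage order. Because the
source material does not state its own tie rule, leaf orders of
published figures are not claimed — only cluster memberships and
heights, which ties cannot change within a fixed rule. The caterpillar
shape that single linkage produces on homogeneous data is accepted as a
property of the method, not corrected.

All three methods are validated against a naive oracle that recomputes
every inter-cluster distance from its definition (mean/min/max over all
cross pairs) at every step, and single-linkage heights are additionally
checked against the sorted minimum-spanning-tree edge weights of the
distance graph. Newick export writes branch lengths as height
differences with the root height in a trailing comment;
`read_newick()` reconstructs heights bottom-up assuming leaves at
height zero.

## Scoring external groupings

`clan_report()` evaluates each group G of a membership table against
all 2n − 1 clusters of the dendrogram:

* α, the maximal Jaccard index, balancing coverage against
  contamination;
* β = |G| / |C_min| with C_min the smallest enclosing cluster —
  outlier-sensitive by design (one stray member inflates C_min to the
  whole tree);
* γ = h_in(G) / h(C_min), where h_in(G) is the largest height of a
  cluster wholly inside G.

**γ is a reconstruction.** The printed formula for γ is not readable
in the source material; the implementation here is constrained by its
three stated properties — it uses cluster heights, it measures
dispersion, and it equals the perfect score 1 when G appears exactly as
a cluster (then h_in and h(C_min) are the same node). Conventions: γ
= 1 for singleton groups and when h(C_min) = 0 (a group of identical
structures should not be penalized). The formula lives in a single
internal function (`.score_group`) so an alternative reconstruction can
be swapped in without touching callers. Reported γ values should be
read with this caveat.

Group members absent from the dendrogram (for example families skipped
for lacking a consensus structure) are dropped with a warning rather
than scored as misses, and reports are ordered by descending β, then
descending α, then accession — a deterministic analogue of ranking
clans from tight to dispersed.

## The synthetic generator

`simulate_families()` emulates the features of the real data that the
pipeline actually consumes: a set of families whose consensus
structures fall into planted structural classes of graded complexity,
plus planted clans. Defaults (chosen once, as the study conditions for
all seeded tests):

* 3 classes × 20 families; templates `hairpin`
  (`((((((....))))))`, a miRNA-precursor-like stem-loop), `twohairpin`
  (H/ACA-snoRNA-like) and `multiloop` (a branched fold standing in for
  larger structured RNAs);
* per-node mutation rate 0.03 — small enough that classes stay
  separable, large enough that within-class distances are non-trivial;
* 2 tight clans (members from one class) and 2 dispersed clans
  (members spanning ≥ 2 classes) of 4 families each, disjoint.

Mutation acts in structure space: the edit count is drawn as
Binomial(#nodes, rate) and each edit, applied sequentially to the
re-serialized structure, is one of delete-a-node (children promoted),
insert-an-unpaired-leaf at a random position, or wrap a random
contiguous sibling run in a new pair. This matches the distance's own
edit moves, keeps the generator dependency-free, and makes the
expected template-to-mutant distance grow with the rate (verified by
Monte-Carlo in the tests). What it does **not** emulate: sequence
evolution and thermodynamic folding, realistic family-size
distributions, pseudoknots, or the heavy length heterogeneity of real
databases — so passing recovery tests show the pipeline's correctness
and its behaviour under clean class structure, not performance on real
data, where class overlap and length effects dominate. One global seed
drives everything; identical parameters give byte-identical datasets.

## Numerical and degenerate-input choices

* Distances compare exactly (no tolerance) under integer costs; PHYLIP
  round-trips are checked at 1e−9; asymmetry beyond 1e−6 on read is an
  error.
* The empty structure is a valid forest (weight 0); a mutation run may
  legally empty a structure.
* Duplicate accessions abort the distance stage; a family missing a
  consensus structure is skipped at parse time with a message naming
  it.
* The renderer caps displayed node heights at `height_cap` (if set),
  marking shortened branches with a double tick; horizontal node
  positions are proportional to height, leaves evenly spaced in
  dendrogram order; the first matching highlight rule wins.

## Problem sizes

The bundled tests and the acceptance script run on deliberately small
instances: oracle agreement on 300 random structure pairs of length ≤
12, clustering oracles on 50 random 10-point matrices per method, and
end-to-end recovery on the default 60-family dataset (1,770 tree-edit
distances) with ten replicates of the clan contrast. These sizes keep
the whole suite in the tens of seconds while exercising every code
path; the same functions scale to databases of a few thousand families
(millions of pairwise distances) in hours on one core, with
`progress_every` for monitoring.

## Known limitations

* A global structure distance punishes overall size differences: two
  structures sharing a motif but differing greatly in length are always
  far apart. Structurally divergent homologs (the tmRNA–tRNA case) will
  not cluster, and very small RNAs drift toward other small RNAs
  regardless of ancestry.
* Pseudoknots are invisible to the comparison.
* γ is a reconstruction (above).
* Flat cluster proposals (cutting the tree) are out of scope; cluster
  delineation on real data remains an act of curation.
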