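# forestclust

Structure-based clustering of RNA families by tree edit distance.

Curated RNA family databases group homologous sequences into families,
each with a hand-built seed alignment and a consensus secondary
structure, and relate some families further into *clans* (recognizable
homology, too divergent to align) while broader *RNA classes* (miRNA,
box C/D and H/ACA snoRNA, CRISPR, ...) share structural character
without common descent. `forestclust` asks how far these groupings are
recoverable from the consensus structures alone: it compares every pair
of families by a full tree edit distance on their structures, clusters
the resulting matrix hierarchically, and scores any externally defined
grouping against the dendrogram. It is aimed at people studying
non-coding RNA classification who want an unsupervised, structure-only
view to set against curated annotation.

## Model

A consensus structure in dot-bracket notation is read as an **ordered
forest**: each matched pair of parentheses is an interior node (a base
pair, two nucleotides), each dot a leaf (one unpaired nucleotide).
Distance between two forests *F₁*, *F₂* is the minimum-cost sequence of
node edits transforming one into the other,

* delete / insert a pair node: cost 2,
* delete / insert an unpaired node: cost 1,
* relabel pair ↔ unpaired: cost 1 (free between equal labels),

computed exactly with the Zhang–Shasha keyroot dynamic program
(`src/treedist.cpp`). Unlike tree-alignment scores this distance is a
metric, so it can feed agglomerative clustering directly. UPGMA, single
and complete linkage are provided via the Lance–Williams recursions,
with the merge height *h(v)* of each internal node recorded as the
inter-cluster distance at the merge (zero for leaves).

A grouping *G* (a clan, a class) is scored against a dendrogram *T* by

* **α** = max over all clusters *C* of the Jaccard index
  |G ∩ C| / |G ∪ C| — coverage vs. contamination;
* **β** = |G| / |C_min|, where *C_min* is the smallest cluster wholly
  containing *G* — dispersion, sensitive to single outliers;
* **γ** = h_in(G) / h(C_min), with h_in(G) the largest height of a
  cluster lying entirely inside *G* — height-based dispersion that does
  not punish groups of near-identical structures.

All three equal 1 exactly when *G* appears as a cluster of *T*.

## Worked example

The built-in generator plants three structural classes (hairpin,
two-hairpin, multiloop; 20 families each, per-node mutation rate 0.03)
plus two tight and two dispersed clans:

```r
library(forestclust)

ds <- simulate_families(sim_params(seed = 1))
m  <- distance_matrix(ds$families)     # 60 x 60, 1770 comparisons
t  <- agglomerate(m, "upgma")
t
#> <rna_dendrogram> 60 leaves, method 'upgma', root height 28.78

clan_report(t, ds$clans)
#>     group size alpha   beta gamma best_cluster_size enclosing_cluster_size
#> 1 CLT0002    4  0.50 0.5000     1                 8                      8
#> 2 CLT0001    4  0.40 0.2000     0                 3                     20
#> 3 CLD0001    4  0.25 0.1000     0                 1                     40
#> 4 CLD0002    4  0.25 0.0667     0                 1                     60

g <- ds$families$accession[ds$families$class == "hairpin"]
max_jaccard_alpha(t, g)
#> [1] 1
```

The report ranks groups from tight to dispersed by β: the within-class
clans (`CLT...`) sit above the cross-class ones (`CLD...`), and every
planted class is recovered as an exact cluster (α = 1). `to_newick()`,
`render_dendrogram()` (SVG with regex-driven leaf highlighting) and
`write_phylip_matrix()` export the results.

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "forestclust.R", package = "forestclust"))')
Rscript $CLI simulate --outdir demo --seed 1
Rscript $CLI run-all --stockholm demo/families.sto --clans demo/clans.tsv \
        --outdir demo/out --method upgma
```

Stages (`extract`, `distmat`, `cluster`, `clanstats`, `render`) also run
individually and hand off through plain TSV / PHYLIP / Newick / SVG
files; `run-all` writes a JSON manifest alongside the artifacts.

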