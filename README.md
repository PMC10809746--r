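# anchorclust

Scalable clonal clustering of B-cell receptor (BCR) junction nucleotide
sequences in R.

Sequences descending from one ancestral B cell (a *clone*) have identical
junction (CDR3) lengths and small Hamming distances, so clonal grouping is
conventionally single-linkage clustering of equal-length junctions under a
normalized Hamming-distance cutoff. All-versus-all comparison is *O(n²)* and
becomes infeasible at repertoire scale. `anchorclust` partitions before
comparing:

1. **Anchor selection (point packing).** Within each length stratum, a greedy
   lexicode scan — accept a sequence iff its Hamming distance to every
   previously accepted one is at least `d_min = ⌈ratio · L⌉` — runs inside a
   small steady-state evolutionary loop (recombination of packings plus
   random input points, re-filtered through the scan; fitness = packing
   size). The result is a set of maximally spaced real sequences.
2. **Distance-vector embedding.** Every sequence becomes the vector of its
   normalized Hamming distances to the anchors.
3. **Incremental partitioning.** A clustering-feature (BIRCH-style) model
   with merge radius 0.5 splits the embedding into at most one part per
   anchor; parts above the size threshold are re-packed and re-split
   recursively. The model can be fitted on a fraction of the rows and then
   assigns all rows to the nearest subcluster centroid.
4. **Single linkage within leaves.** Each leaf (≤ 1000 sequences by default)
   is clustered exactly: connected components of pairs with normalized
   HD ≤ 0.12.

Evaluation utilities implement pairwise sensitivity / precision / F-measure
(`sensitivity = TP/(TP+FN)`, `precision = TP/(TP+FP)`, F = harmonic mean)
against ground-truth clones, and singleton/non-singleton retention and
fraction percentages against categorical labels. A simulator generates
clonally structured repertoires with known clone membership, and V/J
gene-usage grouping can be applied before (`vj_mode = "pre"`) or after
(`"post"`) distance clustering.

## Worked example

```r
library(anchorclust)

sim <- simulate_repertoire(seed = 11)   # 250 clones, lengths 48-60 nt
fit <- cluster_repertoire(sim, seed = 11)
fit
#> Anchor clustering result
#>   5591 sequences in 252 clusters (1 singletons)
#>   cutoff 0.12, ratio 0.6, radius 0.5, size threshold 1000, vj_mode none

cluster_quality(fit, truth = sim)
#> # A tibble: 1 × 3
#>   sensitivity precision f_measure
#>         <dbl>     <dbl>     <dbl>
#> 1       0.998         1     0.999

head(tidy(fit), 2)
#> # A tibble: 2 × 6
#>   sequence_id junction                  junction_length v_call j_call cluster_id
#>   <chr>       <chr>                               <int> <chr>  <chr>  <chr>
#> 1 sim000001   AACTTTAATGTTGTTAAAGTGGGC…              54 ""     ""     AC000001
#> 2 sim000002   AACTTTGATGTTGTTAAAGTGGGC…              54 ""     ""     AC000001
```

The simulator emitted 7,500 records collapsing to 5,591 unique junctions; the
pipeline recovered the 250 true clones almost exactly (252 clusters, pairwise
F-measure 0.999: no unrelated pairs were merged and 0.2% of related pairs
were separated). `tidy()` returns the per-sequence assignment table,
`glance()` a one-row run summary, `autoplot()` the cluster-size
distribution, and `write_clusters()` writes a TSV with duplicates re-expanded
onto their representative's cluster.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "anchor-clustering", package = "anchorclust"))')" \
  cluster --in repertoire.tsv --out clusters.tsv --seed 1 --report run.json
```

with `simulate` and `evaluate` subcommands for the other entry points.

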