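# catens — ensemble clustering of categorical data

`catens` clusters categorical observations — attribute tables and aligned
nucleotide sequences — by **ensembling hierarchical clusterings under
normalized Hamming distance**. It is aimed at analysts who need population
substructure from data where arithmetic on values is meaningless (every
variable is an unordered code) and where a single dendrogram is too
unstable to trust.

## The method

For observations x_i = (x_i1, ..., x_iJ) the base dissimilarity is the
normalized Hamming distance

> d(x_i, x_k) = (1/m) · #{ j : x_ij ≠ x_kj },

with m the number of compared positions (alignment gaps are missing values,
excluded under the default `pairwise_complete` policy). B base hierarchical
clusterings (average linkage by default) are generated, each cut at a
cluster count K_b drawn uniformly from {kmin, ..., kmax} (default kmax =
⌈√n⌉), and collected in an **incidence matrix** I whose (i, b) entry is the
cluster index of observation i in base clustering b. The **ensembled
dissimilarity**

> T(i, j) = (1/B) · #{ b : I(i, b) ≠ I(j, b) }

is the fraction of base clusterings separating i and j — the Hamming
distance between rows of I — and the final dendrogram is agglomerated on T.
With `perturb = "rows"` each base clustering fits its own bootstrap
resample of observations, which gives the consensus genuine diversity and
is what the stability comparisons use. For high-dimensional data (J ≫ n),
`ensembleClusterHighDim()` instead draws a random variable subspace per
base clustering by bootstrap-with-deduplication (single, double, or triple
bootstrap; double by default).

Cluster stability is quantified by bootstrap reclustering
(`bootstrapStability()`): each reference cluster is scored by the best
Jaccard coefficient it achieves against the clusters of a resampled and
reclustered dataset; `compareStability()` contrasts two methods by pooled
median Jaccard per K. A deterministic K-modes baseline (`kmodes()`), a
multinomial-mixture generator (`generateCategorical()`), and a
full-factorial study runner (`runStudy()`) round out the toolkit.

## Worked example

Three planted clusters of 40 observations on 12 mixed-cardinality
categorical variables, in a regime hard enough that clusterings are
imperfect:

```r
library(catens)

d   <- generateCategorical(120, profile = "mixed12", K = 3,
                           separation = "high", pHigh = 0.6, seed = 42)
ens <- ensembleCluster(d$X, B = 200, seed = 7, perturb = "rows")
cls <- cutClusters(finalTree(ens), 3)
table(cluster = cls, truth = d$labels)
#>        truth
#> cluster  1  2  3
#>       1 37  4  2
#>       2  2  1 38
#>       3  1 35  0
adjustedRand(cls, d$labels)
#> [1] 0.762

se <- bootstrapStability(d$X, "ensemble", Ks = c(3, 5), resamples = 50, seed = 1)
sh <- bootstrapStability(d$X, "hier",     Ks = c(3, 5), resamples = 50, seed = 1)
compareStability(se, sh)
#>   K   medianA   medianB difference
#> 1 3 0.9032258 0.8095238  0.0937020
#> 2 5 0.8571429 0.7257053  0.1314375
```

The contingency table shows the 3-cluster cut recovering the planted
groups (adjusted Rand 0.76, against 0.74 for the single hierarchical
clustering on the same data). The stability comparison is the method's
selling point: at K = 3 the ensemble's clusters reappear in bootstrap
resamples with pooled median Jaccard 0.90 versus 0.81 for plain
hierarchical clustering, a difference of +0.09 (+0.13 at K = 5) — the
consensus is more reproducible than any single dendrogram.

Aligned sequences enter through `readAlignedFasta("aligned.fa")` (gaps and
ambiguity codes become missing values); `toNewick(finalTree(ens))` exports
the dendrogram for any tree viewer.

A command-line interface wrapping the same functions ships in
`inst/scripts/catens.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "catens.R", package = "catens"))')" \
    ensemble --input X.csv --B 200 --seed 17 --out-dist T.tsv --newick tree.nwk
```

Subcommands: `hamming`, `cluster`, `ensemble`, `ensemble-hi`, `kmodes`,
`stability`, `simulate`, `simulate-data`, `encode-fasta`. All are
deterministic given `--seed` and write a `.meta` sidecar recording their
parameters.

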