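---
title: "Ensemble clustering of categorical data: model, choices, limitations"
author: "catens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble clustering of categorical data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catens)
```

## The problem

Categorical observations — survey answers, attribute tables, and above all
aligned nucleotide sequences — have no meaningful arithmetic: the "distance"
between A and G is not half the distance between A and anything else. The
natural dissimilarity is the normalized Hamming distance, the fraction of
positions at which two observations disagree, which weights every variable
equally and corresponds to classification loss. Hierarchical clustering on
that matrix works, but a single dendrogram is a high-variance object: small
perturbations of the data can rearrange branches wholesale, and with only
J compared positions all distances are multiples of 1/J, so ties are
endemic and much of the tree is arbitrary.

`catens` reduces that variance by consensus. Many base hierarchical
clusterings are generated, summarized in an *incidence matrix* I (entry
(i, b) is the cluster index of observation i in base clustering b), and
combined into an *ensembled dissimilarity*

T(i, j) = (1/B) * #{ b : I(i, b) != I(j, b) },

the fraction of base clusterings that separate i and j — the normalized
Hamming distance between rows i and j of I. A final dendrogram is fitted on
T. Pairs that every perspective keeps together end at distance 0, pairs
that every perspective separates at 1, and the resulting trees show longer
branch lifetimes: clusters separate more visibly, which also makes reading
off the number of clusters easier. No automatic selection of K is
performed; `cutClusters()` extracts any K-cluster partition on demand.

## The base clusterings, and why they must differ

Each base clustering b cuts an average-linkage Hamming dendrogram at a
cluster count K_b drawn uniformly from {kmin, ..., kmax} (defaults: kmin =
2, kmax = ceiling(sqrt(n)) via `defaultKmax()`, clamped to [2, n-1]; B =
200). Varying K_b alone, however, is provably not enough: if all B cuts
come from the *same* tree, T is a monotone function of the step at which
each pair merges in that tree, so the final dendrogram encodes exactly the
same nested partitions with rescaled heights — we verified empirically that
cutting the final tree then reproduces the single hierarchical clustering
with adjusted Rand 1.00 at every K. An ensemble whose members are
deterministic functions of one object has nothing to average.

`ensembleCluster()` therefore exposes a `perturb` argument:

* `perturb = "none"` — the deterministic form. It is the package default
  because its contracts are exactly checkable (a fixed-K ensemble equals the
  plain K-cut; T equals the enumeration over cut sizes in the large-B
  limit) and because the transformed heights alone already lengthen
  lifetimes for visual inspection.
* `perturb = "rows"` — each base clustering draws a bootstrap resample of
  the n observations, reduces it to the distinct drawn rows, clusters that
  subset, and assigns every left-out observation to the cluster of its
  nearest included row (smallest Hamming distance; first index on ties).
  This gives the members genuine diversity, and it is what the stability
  pipeline (`bootstrapStability()`, `runStudy()`) uses, since comparing the
  stability of a consensus against a single clustering is only meaningful
  when the consensus actually averages over data perturbations.

In high dimensions (J >> n) diversity comes from the data itself:
`ensembleClusterHighDim()` draws, per base clustering, a random *subspace*
of variables by bootstrap-with-deduplication — J draws with replacement
from {1..J}, keep the distinct values (about 63% of J), optionally repeat
the step on the result (`level = 2`, the default double bootstrap, about
47%; `level = 3` for a third pass). Every column has the same inclusion
probability, and each base clustering recomputes its own Hamming matrix on
its own subspace, so no row perturbation is needed there.

## Missing data

Alignment gaps (and, by default, IUPAC ambiguity codes) are coded as
missing, not as a fifth symbol. Two policies govern their contribution to
distances:

* `pairwise_complete` (default): mismatches are counted over positions
  where both values are observed and renormalized by that count — a gap is
  absence of information. A pair with no jointly observed positions gets
  distance 1 with a warning (a defined worst case rather than NaN, so
  downstream linkage stays well-defined).
* `mismatch`: any position with at least one missing value counts as a
  mismatch, denominator J. This treats a gap as "known to differ" and is
  offered because reasonable implementations differ on the question.

## Determinism

Hamming distances are exact integer ratios, so tied minimum linkage values
are the norm, not the exception. The agglomerator resolves them by a fixed
rule: clusters carry node ids (leaves 1..n, the cluster born at merge s is
n+s) and among all pairs attaining the minimal linkage value the
lexicographically smallest id pair merges first. Average linkage maintains
cross-cluster distance *sums* and divides only when comparing, so the
arithmetic is plain summation of input entries and bit-for-bit reproducible.
Every stochastic entry point takes a `seed`; pipelines derive per-stage
sub-seeds through `deriveSeed()` (a fixed stage-name hash folded into the
master seed), so adding a stage never perturbs the draws of earlier stages,
and two runs with the same seed produce byte-identical outputs.

## Stability assessment

`bootstrapStability()` follows the bootstrap reclustering scheme: draw n
row indices with replacement, reduce to the distinct rows (duplicate rows
sit at Hamming distance 0 and would otherwise dominate average linkage),
recluster at K, and score each reference cluster by the best Jaccard
coefficient it achieves against the resample's clusters, restricted to the
resampled rows. Per K the report pools all (cluster, resample)
coefficients and summarizes by the median ("pooled", the default), with
mean and per-cluster aggregation available because the pooling convention
is a genuine free choice. Resamples whose distinct-row count falls below K
are skipped and counted. The unadjusted Rand index is deliberately not
offered; `adjustedRand()` (Hubert–Arabie) is, as the chance-corrected
alternative to the Jaccard view.

## The synthetic generator and the factorial study

`generateCategorical()` draws from a K-component mixture of products of
categorical distributions — the cleanest model in which "cluster" has an
unambiguous meaning. The full factorial design (`makeDesign()`): sample
sizes 100/300/1000; 12 mixed-cardinality variables (2,2,2,3,3,3,4,4,4,4,8,8)
or 100 quaternary variables; 3/5/7 true clusters; equal or (1:K)-proportional
cluster sizes; low or high separation — 72 cells, 24 per sample size. The
concrete concentration scheme (probability `pHigh = 0.8` on a preferred
category that rotates across columns as 1 + ((c + j) mod m_j); the rest
spread uniformly) is this package's canonical instantiation of the stated
design axes; all of it is configurable.

Two caveats follow directly from that instantiation and matter when
interpreting `runStudy()` output. At high separation the clusters are easy:
both the ensemble and the single hierarchical clustering recover them on
essentially every resample, and both pooled median Jaccards saturate at
1.0. At low separation the labels carry no signal at all, and both methods
sit at a common noise floor. The ensemble-minus-hierarchical stability
difference is therefore positive but modest under these defaults, and it
grows with sample size; regimes between the two extremes (structured but
hard) are where consensus clustering shows its largest gains, and can be
explored by lowering `pHigh`. What the generator does *not* emulate about
real data: dependence between columns, missing values, unequal sequence
lengths, and within-cluster heterogeneity — passing tests on this generator
demonstrate correctness of the machinery, not performance guarantees on
real genomes.

Problem sizes used by the packaged experiments: the study runner is
exercised at the 24-cell n = 100 and n = 300 slices with K in {3, 5, 7} and
100 bootstrap resamples (25 in the quick test suite); ensemble size B = 200
(low-dimensional) and B = 100 with a double bootstrap (high-dimensional),
matching the method's defaults.

## The K-modes baseline

`kmodes()` implements the classical Lloyd-style alternation (assign to the
mode with fewest mismatches, recompute modes column-wise) with a fully
deterministic contract: assignment ties to the lowest cluster index, mode
ties to the smallest code, and an emptied cluster is re-seeded with the
observation farthest from its current mode. Its known sensitivity to
initialization is reproduced in the test suite — it is the baseline the
ensemble is meant to improve on, not a recommended method.

## Numerical and degenerate-input choices

* Distances are exact ratios k/m; no floating fuzz is introduced anywhere
  before linkage sums.
* `cutClusters(tree, K)` undoes the last K-1 merges; labels are canonical
  (first observation's cluster is 1). K = 1 and K = n are valid.
* An all-missing column is allowed from sequence input (it contributes no
  compared positions) but rejected in tabular input, where it is almost
  certainly a formatting error.
* Newick export maps merge heights to branch lengths so that a leaf's
  branch length equals its parent's merge height; trees parse back to the
  same topology with any standard reader.
* `agglomerate()` requires n >= 2; `ensembleCluster()` requires kmax < n;
  `defaultKmax()` requires n >= 4.

## Known limitations

Only equal-length (aligned) sequences are handled; alignment itself is out
of scope, as are protein alphabets, weighted Hamming variants, model-based
clustering, and optimization-based consensus methods. The lexicographic
tie rule makes results reproducible but is still a convention: on heavily
tied data other valid conventions produce other (equally defensible)
dendrograms.
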