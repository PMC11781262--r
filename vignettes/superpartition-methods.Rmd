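---
title: "Methods: information-loss-constrained feature reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-loss-constrained feature reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superpartition)
```

This vignette documents the models, estimators and design choices behind
the package, the way the synthetic data used for validation is built, and
the limits of what the validation shows.

## The reduction model

The package reduces an `n x N` feature matrix by merging related features
into single summary features, under a hard floor on information loss. Two
pluggable components define a merge:

* a **reducer** collapses a set of feature columns to one vector — the
  row-wise mean of the standardized columns (default), or the scores on
  their first principal component;
* a **metric** scores how much information the merged set retains. The
  default is the intraclass correlation coefficient ICC(1,1) from a
  one-way random-effects ANOVA in which samples are subjects and the
  cluster's features are repeated measures:
  `(MSB - MSW) / (MSB + (k - 1) MSW)`. For clearly non-Gaussian data a
  normalized mutual-information score is provided instead.

A merge is accepted only if the metric reaches the **information loss
criterion** `t` (default 0.6). Singletons score 1 by convention — an
unreduced feature loses nothing — so the guarantee
`min(information) >= t` over multi-member outputs is unconditional.

Three choices here were genuinely open and are worth recording:

* **ICC variant and scaling.** ICC(1,1) is used because the information
  floor is defined as a single per-cluster scalar. It is computed on
  standardized columns (mean 0, sd 1) so that differences in feature
  scale cannot masquerade as information loss; with raw columns, a large-
  variance feature would dominate both mean squares. A consequence worth
  knowing: for two standardized features the ICC equals
  `((1+r) - (n-1)(1-r)/n) / ((1+r) + (n-1)(1-r)/n)`, which converges to
  the Pearson correlation from below as `n` grows — at small `n` the ICC
  is slightly more permissive than `r`.
* **Metric is scored against original columns.** When two already-merged
  variables are merged again, the metric is evaluated on the full union
  of *original* features, not on the two intermediate vectors. The floor
  therefore always refers to the input features' information, and an
  accepted cluster's score never hides earlier losses. The alternative
  (scoring against current vectors) would let information decay
  geometrically across merge generations.
* **Negative ICC** is returned as-is; it simply fails any nonnegative
  threshold.

### The greedy director

Pairs are tried closest-first, with the distance `1 - r` between the
variables' current vectors (`1 - |r|` is available for sign-agnostic
matching). The signed default is deliberate: the mean reducer only gains
from positively correlated members, so anticorrelated pairs should rank
far apart (distance near 2). Rejected pairs are remembered and skipped;
the memory for a variable is cleared when that variable changes, because
a new merged vector invalidates old verdicts. Equal distances are broken
lexicographically by member names, making runs reproducible. If a
tentative reduction degenerates to a constant vector (possible for
exactly anticorrelated pairs under the mean reducer), the pair is treated
as rejected rather than erroring mid-run.

### The mutual-information estimator

MI is estimated by a histogram plug-in on **equal-frequency bins** with
`B = max(2, ceiling(n^(1/3)))` bins per axis, Miller–Madow bias
correction, normalized by the geometric mean of the (corrected) marginal
entropies, and clamped to `[0, 1]`; the cluster score is the minimum over
members of this quantity against the reduced vector. The bin count is the
binding choice: with `B` near `sqrt(n)` per axis the joint histogram has
about `n` cells and the plug-in bias `(B-1)^2 / 2n` is of order the MI
being measured — independent variables then score far from zero. The
cube-root rule keeps about `n^(1/3)` observations per joint cell, and
with the Miller–Madow correction the estimator scores independent draws
near 0.0005 and a correlated Gaussian pair (rho = 0.8, n = 5000) within
about 0.01 of the closed form `-log(1 - rho^2)/2` after normalization.
Kernel and nearest-neighbour estimators are more efficient but were left
out deliberately: the binned estimator is deterministic, cheap at the
cluster sizes the engine sees, and directly testable against the
Gaussian closed form.

## The scaling layer

The engine computes all pairwise distances within a cluster, so feature
sets beyond tens of thousands must first be split. The split uses
single-linkage agglomeration over the minimum-spanning-tree edges of the
same feature distance the engine uses — so the super-step groups exactly
what the engine would want to merge — taken in ascending weight, with one
modification: whenever the Gini index of the current cluster sizes
exceeds `g` (default 0.05), the next merge must be the cheapest remaining
edge incident to a cluster of minimal current size (ties broken by edge
weight, then by original edge order). With `g = 1` the procedure is
exactly a single-linkage cut, and the test suite holds it to that oracle.

The Gini index of sizes `n_1..n_k` is computed in the sorted-coefficient
form `sum_i (k + 1 - 2i) n_(i) / ((k - 1) sum n)` and cross-checked in
tests against the pairwise-difference form.

Decisions taken where the design was open:

* **The size bound is enforced as `<= c` by recursion.** An initial cut
  into `ceiling(N / c)` clusters only bounds the *average* size, so any
  cluster with `N_k > c` is re-split at `k = ceiling(N_k / c)` until all
  sizes comply; each split strictly reduces the largest part, so the
  recursion terminates.
* **The k-means fallback applies per split step.** If a re-split's
  smallest part has 50 features or fewer — typical when a cluster is a
  tight knot of highly correlated features whose MST is star-like, so
  constrained linkage peels off single features — the linkage split is
  discarded and the cluster is split by k-means with the same number of
  centroids (features as points in standardized sample space, k-means++
  style seeding from the configured seed, Lloyd iterations). The k-means
  output is accepted as-is, small parts included; re-checking it would
  recurse forever on pathological geometry. The fallback is used only
  when re-splitting oversized clusters, not after the first global cut,
  whose cluster count is a hard requirement.
* **Sequential recombination.** Clusters are reduced one at a time in
  label order, and multi-member outputs are numbered `reduced_var_1,
  reduced_var_2, ...` globally across clusters (singletons keep their
  names). Numbering globally rather than per-cluster makes the flat
  mapping table unambiguous without a cluster column.

The price of locality is explicit: two features in different
super-clusters are never merged, even if their pooled score would clear
the floor. One test constructs exactly this situation (a panel of
near-duplicates forced across two clusters) and asserts the non-merge;
users should read the output feature count's lower bound
`ceiling(N / c)` as a property, not an artifact.

## The synthetic-data generator

`generate_block_data()` draws each block from a one-way random-effects
model: `x_ij = u_bi + e_bij`, `u_bi ~ N(0, rho * sd^2)`,
`e_bij ~ N(0, (1 - rho) * sd^2)`. This model was chosen because its
population ICC is exactly `rho`, so the reduction's reported information
values have a known truth: a recovered block should score near `rho`, and
the validation asserts the sample ICC lands within ±0.05 of it at
n = 500. Blocks are mutually independent; singleton blocks give
independent noise features.

What the generator deliberately does **not** emulate: skewed or bounded
marginals (methylation beta values), count distributions (RNA-seq),
heteroscedastic noise, batch effects, or overlapping correlation
structure between blocks. Passing tests therefore demonstrate the
algorithmic contracts — the information floor, surjectivity, the size
bound, recovery of exchangeable blocks — not performance on any real
assay. On real data the ICC metric inherits its Gaussian leanings; the
MI metric is the intended escape hatch, at the cost of a coarser
estimator.

One behavior of the aggregate ICC is worth flagging: a large, tight
block can absorb a weakly related feature while keeping its pooled ICC
above the floor, because the ICC is a cluster-level summary rather than
a per-member minimum. This is faithful to the method's definition; users
wanting per-member guarantees should use the MI metric, whose cluster
score *is* a minimum over members.

## Numerical and validation choices

* Standardization rejects near-constant columns
  (`sd <= 1e-12 * max(|mean|, 1)`) with a "constant feature" error —
  silently imputing them would make every metric undefined.
* The first principal component's sign is fixed by positive correlation
  with the scaled row means, removing eigenvector sign ambiguity.
* All randomness (k-means seeding, simulation) flows from explicit seeds,
  and RNG state is restored after internal use, so identical inputs give
  byte-identical outputs.
* Validation problem sizes: the engine's contracts are exercised on
  panels of 12–420 features with 30–500 samples; the exhaustive oracle
  enumerates all 203 set partitions of 6 features; the constrained
  linkage is checked against the single-linkage oracle on matrices up to
  120 points. These sizes make every guarantee checkable exhaustively or
  against closed forms while keeping the full suite quick on a laptop.

## Known limitations

* The greedy director is not globally optimal: it finds *a* feasible
  partition, typically but not provably the coarsest one; the exhaustive
  small-instance oracle confirms feasibility and block recovery, not
  optimality.
* Reduction quality across super-cluster boundaries depends on the first
  cut; the lower bound `ceiling(N / c)` is unavoidable by construction.
* Runtime of the engine is quadratic in the within-cluster feature count
  in the worst case (high ILC, many rejections); `c` is the lever.
* The MI metric's binned estimator is coarse for very small `n`
  (`n < ~30` gives 2–3 bins per axis).
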