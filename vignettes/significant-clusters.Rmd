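---
title: "Detecting significant groups in hierarchical clustering by resampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting significant groups in hierarchical clustering by resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigdendro)
```

## The problem

Hierarchical clustering orders `n_s` sample profiles (columns of a
variables-by-samples matrix) into a dendrogram, but it never says whether the
groups it displays are real: even pure noise produces a tree with apparent
structure. The question practitioners actually ask — "are these clusters more
than random?" — needs a null distribution for the heights at which the tree's
branch points occur.

`sigdendro` answers it with a permutation argument. If there are no clusters,
the joint distribution of a sample's variables carries no column structure,
so independently reshuffling the entries of each *row* of the standardized
matrix produces data that are exchangeable with the original under the null
while preserving every variable's marginal distribution exactly. Clustering
the reshuffled data gives a draw of the `n_s - 1` merge heights under "no
clusters"; averaging `r` such draws (element-wise, after sorting) gives the
reference distribution `D_e`. Cutting the observed dendrogram at the `p`-th
percentile of `D_e` keeps only splits whose heights would be unlikely in
random data, and the detected clusters carry a significance level
`alpha = 1 - p/100`: under the null, `alpha` is the expected proportion of
falsely detected clusters.

## The procedure

For a data matrix `X` (`n_v` variables x `n_s` samples), `sigdendro()`:

1. standardizes each row (mean 0, sample sd 1; a trimmed variant is
   available for outlier-prone data);
2. clusters the columns with **Euclidean distance and complete linkage**
   and stores the sorted merge heights, divided by `sqrt(n_v)`, as `D_o`
   (the normalization puts heights on a per-variable, root-mean-square
   scale, comparable across dimensions);
3. repeats `r` times: reshuffle every row independently, re-cluster, record
   the sorted normalized heights; `D_e` is the element-wise mean;
4. cuts the observed tree at `reference_percentile(D_e, p)`: all merges at
   or below the threshold are performed, so the number of clusters is one
   plus the number of observed heights above it.

Complete linkage matters twice: its merge heights are monotone
non-decreasing, so sorting is merely a formality and "cutting at a height"
is unambiguous, and its inter-cluster distance (maximum pairwise distance)
makes between-cluster merges overshoot the null sharply when clusters are
real.

The QQ plot of `D_o` against `D_e` (`plot(fit)`) is the companion
diagnostic. Points hugging the diagonal mean no detectable structure. With
real clusters the bulk of the observed heights — within-cluster merges —
falls *below* the diagonal (profiles in a cluster are more alike than
random profiles) while the right tail — between-cluster merges —
overshoots it. Note that the crossing happens near the extreme tail: most
ranks of a strongly clustered dataset sit below the diagonal, and it is the
top few dozen heights that carry the signal.

```{r example}
sim <- generate_dataset(n_c = 4, n_v = 10, n_s = 300, sigma = 5, seed = 7)
fit <- sigdendro(sim$x, percentile = 95, r = 10, seed = 8)
summary(fit)
jaccard_similarity(sim$labels, fit$labels)
```

Several percentiles can be scanned against one fit — the reference does not
depend on `p` — with `recut()`:

```{r recut}
sapply(c(95, 97.5, 99, 99.5, 99.9),
       function(p) suppressWarnings(recut(fit, p)$n_clusters))
```

## Parameters that matter

* **`percentile` / `alpha`** (default 95, i.e. `alpha = 0.05`). The only
  substantive tuning knob. When the QQ plot shows wide separation between
  `D_o` and `D_e`, a moderate percentile recovers the structure; when
  separation is limited, extreme percentiles (99-99.9) trade sensitivity
  for specificity. The package deliberately does not auto-select it: the
  QQ plot is the intended instrument.
* **`r`** (default 10). Ten reshuffles are enough in practice because the
  reference averages `n_s - 1` heights per replicate; its Monte-Carlo
  variance already scales like `1/r` element-wise, and going to 1000
  replicates changes thresholds negligibly. The default is kept
  configurable for small `n_s`, where the percentile of interest may sit
  between sparse order statistics.
* **`standardize`** (`"mean_sd"` default). Row standardization is not
  optional in spirit: Euclidean distance otherwise weights variables by
  their scales. The sample standard deviation (divisor `n_s - 1`) is used;
  the population convention would rescale every row identically and leave
  all detected partitions unchanged. `"trimmed"` centers by the symmetric
  trimmed mean (default `trim_fraction = 0.05`) and scales by the sd of
  the retained observations — a pragmatic robust recipe for data with
  heavy-tailed variables.
* **`seed`**. One RNG stream drives all permutation replicates; fits are
  bit-reproducible given `(X, percentile, r, seed)`.

## Numerical conventions

These are pinned so results are deterministic and testable:

* Percentiles use linear interpolation between order statistics
  (`stats::quantile` type 7). With hundreds of reference values the choice
  is immaterial, but it must be fixed.
* Replicate height vectors are sorted before element-wise averaging. With
  complete linkage merge order already sorts them; sorting makes "element
  j across replicates" well defined for any linkage.
* Heights are normalized per replicate; because every replicate is divided
  by the same `sqrt(n_v)`, normalizing before or after averaging is
  mathematically identical.
* A merge exactly at the threshold is performed (cuts keep merges with
  height `<= h`); a cluster is significant when its merge height strictly
  exceeds the threshold.
* Distance ties during agglomeration resolve to the smallest-index pair
  (the convention of `stats::hclust`); ties have probability zero under
  the continuous generators used here but determinism matters for tests.
* Cluster labels are always renumbered 1..k by decreasing cluster size,
  ties broken by first-appearing sample.
* If the threshold reaches the top of the observed dendrogram the fit
  returns one cluster with a warning, not an error: "no significant
  structure at alpha" is a legitimate finding.
* Degenerate inputs are rejected up front: missing values (no imputation
  is attempted), constant rows (no scale), fewer than two variables or
  samples.

## The synthetic benchmarks

`generate_dataset()` emulates a family of multivariate-normal scenarios:
`n_c` true mean profiles — one all-zero, the rest iid `N(0, sigma^2)`
entries — with identity observation covariance, and cluster sizes drawn by
a symmetric Dirichlet(1)-weighted multinomial with a minimum size of 2.
The Dirichlet scheme produces the strongly unequal sizes (a few hundred
down to a handful) typical of real biomarker clusters; it is pluggable via
`sizes=` because accuracy summaries are sensitive to it.
`benchmark_scenario()` fixes a reference configuration: 2000 profiles of
16 variables from 13 clusters with `sigma = 2` and sizes within [2, 532].
`generate_null()` provides the one-cluster null.

What these generators do *not* emulate about real data: correlated
variables (covariance is identity), non-Gaussian marginals, outliers, and
missingness. Passing the simulation suite therefore demonstrates
calibration and power under clean Gaussian separation, not robustness to
the pathologies of production data — the trimmed standardization and the
QQ diagnostic are the tools for those.

Two behaviors of the benchmark are worth understanding before reading the
study output:

* Profile separation is random. With 13 profiles drawn from `N(0, 4)` in
  16 dimensions, some pairs land closer than the detection threshold, and
  those clusters merge at the cut; single realizations range from 9 to 13
  detected clusters at `p = 95`. This is the same phenomenon that caps
  exact-recovery rates near 10% in the grid study below, and it is a
  property of the scenario, not of the estimator.
* Calibration at extreme percentiles is resolution-limited. The 99.9th
  percentile of a reference supported on `n_s - 1` points interpolates
  between the top two order statistics of an `r`-replicate average; for
  `n_s` of a few hundred the realized false-split rate sits slightly above
  nominal. The effect fades as `n_s` grows.

## The evaluation harness

`run_fpr_study()` (one-cluster data) and `run_tpr_study()` (clustered
grids) replicate the calibration/power design: per dataset, scenario
parameters are drawn uniformly (`n_c` from 2-20, `n_v` from 2-20,
`sigma` from {2, 5, 10}), detection runs at several percentiles, and the
outcome is scored with three complementary metrics:

* **PWC**, `(n_detected - n_true)/(n_s - n_true)`: a signed count error
  scaled by the worst case. Under the null its mean equals `alpha`.
* **Cramer's V index**, `(chi^2/n) / min(r - 1, c - 1)` on the
  true-by-inferred contingency table — exactly this ratio, without the
  textbook square root, which is available as `classic = TRUE`. It is 1
  for perfect dependency but *stays* 1 when true clusters are cleanly
  merged, and it is undefined (an error) when either partition is a single
  cluster.
* **Average Jaccard similarity**, `sum |intersection|/|union| / max(r, c)`:
  1 only for identical partitions, penalized by merges and splits — the
  pair of indices separates composition errors from count errors.

Default study sizes are 200-300 datasets with `n_s` drawn from 300-1500,
which keeps a full run in minutes on one core while leaving Monte-Carlo
standard errors of a few percent; the ranges are arguments, so the heavier
configuration (thousands of datasets, `n_s` up to 5000) is one call away.
Per-dataset seeds are derived from the master seed, so studies are
reproducible and resumable.

## The Beale comparator

`beale_select()` implements the classical pseudo-F alternative used as the
baseline: for `k = 2, ...` the dendrogram is cut into exactly `k` groups
and

\[
F_k \;=\; \frac{(S_1 - S_2)/S_2}{\frac{n_s - 1}{n_s - k}\,k^{2/n_v} - 1}
\]

compares the within-cluster sum of squares `S_2` against the one-cluster
total `S_1`, referred to `F` with `n_v(k - 1)` and `n_v(n_s - k)` degrees
of freedom. If the maximum `F` over the scan (capped at `k_max = 500`) is
significant, that `k` is selected, ties toward smaller `k`; otherwise one
cluster.

Two structural caveats, both visible in the simulations. First, the scan
stops at `k = n_s - 1`: at `k = n_s`, `S_2 = 0` and the statistic is
undefined; near that endpoint `S_2` collapses and `F` diverges for *any*
data, so the cap must be small relative to `n_s` for the test to be
meaningful — with `n_s` below roughly twice the cap, the scan enters this
runaway region and the selection loses its null calibration. Second, even
away from the endpoint, `F` tends to drift upward with `k` on null data
when `n_v` is large (the `k^{2/n_v}` penalty flattens), so the comparator
either keeps one cluster or runs to the cap — behavior that motivates the
resampling method in the first place. The degrees of freedom above are the
standard choice for this statistic; published operating percentages for
the heuristic are sensitive to the exact variant, so cross-study
comparisons of those rates should be read as qualitative.

## Design choices made here

* The reference averages sorted replicates rather than pooling them; the
  element-wise mean is what "expected heights" means here, and it keeps
  `D_e` the same length as `D_o` for rank-by-rank QQ pairing.
* Only complete linkage and Euclidean distance are accepted. The
  permutation argument itself is linkage-agnostic, but monotone heights
  and the max-distance merge rule are what make the cut semantics and the
  tail behavior clean; other linkages would need their own validation and
  are deliberately out of scope.
* Row permutation is reshuffling without replacement, not bootstrap
  resampling: the null preserves each variable's empirical distribution
  exactly.
* The per-clade bootstrap approach (pvclust-style approximately unbiased
  p-values) answers a different question — significance of individual
  clades — and is intentionally not reimplemented; this method tests the
  global hypothesis that there are clusters and chooses where to cut.

## Limitations

* The method calibrates the *expected proportion* of false clusters, not
  per-cluster p-values; individual small clusters at the margin deserve
  scrutiny (e.g. by stability across percentiles, see `recut()`).
* With small `n_s` the achievable significance levels are limited by the
  `n_s - 1` support points of the reference.
* Complete linkage is outlier-sensitive; gross outliers become singleton
  "significant" clusters. Trimmed standardization mitigates scale
  distortion but not leverage; screen outliers first.
* Exact recovery of the number of clusters degrades gracefully when true
  profiles overlap — detected clusters are then unions of overlapping true
  ones, which Jaccard flags while Cramer's V forgives.
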