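---
title: "Group concept mapping with conceptmapr: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group concept mapping with conceptmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conceptmapr)
```

## The method in brief

Group concept mapping turns two kinds of participant input — card sorts and
importance ratings — into an interpretable thematic map. The pipeline this
package implements has five quantitative stages:

1. **Co-occurrence similarity.** Each sorter partitions the $S$ statements
   into piles. Sorter $m$'s binary matrix has $x^{(m)}_{ij} = 1$ when $i$ and
   $j$ share a pile. The aggregate similarity is
   $s_{ij} = \sum_{m=1}^{N} x^{(m)}_{ij}$, an integer in $[0, N]$ with
   diagonal $N$.
2. **Nonmetric multidimensional scaling.** Dissimilarities
   $d_{ij} = N - s_{ij}$ are embedded in two dimensions by minimizing
   Kruskal stress-1,
   $$\sigma_1 = \sqrt{\frac{\sum_{i<j} (\hat d_{ij} - \delta_{ij})^2}
   {\sum_{i<j} \delta_{ij}^2}},$$
   where $\delta_{ij}$ are configuration distances and $\hat d_{ij}$ is the
   least-squares monotone (isotonic) regression of $\delta$ onto the rank
   order of $d$. Stress 0 means the map reproduces the dissimilarity ranks
   perfectly; values between 0.10 and 0.35 are typical for concept-mapping
   projects.
3. **Ward clustering of the map.** The 2-D coordinates — not the raw
   similarity matrix — are agglomerated under Ward's minimum-variance
   criterion; cutting the tree at $k$ gives the cluster solution. The
   interpretation step usually examines a small range of $k$ (the packaged
   example's study weighed 6–8 and settled on 7).
4. **Label suggestion.** Every participant pile is scored against every
   cluster by the Jaccard index of their member sets; each cluster's
   top-ranked pile titles become candidate labels.
5. **Rating aggregation and pattern matching.** Statement means (over
   available raters; 1–5 Likert scale), cluster means, and the per-group
   comparison: a ladder of cluster means per stakeholder group with their
   Pearson correlation and top-$k$ overlap.

## Numerical and algorithmic choices

**Optimizer.** `nonmetric_mds()` alternates a monotone-regression update of
the disparities with a Guttman (majorization) update of the configuration.
Stress-1 is recomputed each cycle and is non-increasing within a run; the
per-run trace is returned so this property is checkable, and a run that
would increase stress stops at the previous configuration. Convergence is
declared when the per-cycle improvement in stress-1 drops below `tol`
(default `1e-6`). The threshold is absolute rather than relative: stress-1
is already normalized to $[0,1]$, and in near-perfect-fit problems stress
decays geometrically toward zero so a relative criterion would never
trigger. Runs that exhaust `max_iter` (default 500) return
`converged = FALSE` with a warning, never silently.

**Starts.** The first start is classical (metric) scaling of the
dissimilarities — deterministic and usually near-optimal; the remaining
`n_starts - 1` (default 10 total) are seeded uniform random configurations
guarding against local minima. One integer seed drives everything, so equal
inputs and seed give bit-identical maps.

**Ties.** Tied dissimilarities are handled by Kruskal's primary approach:
within a tie block the fitted disparities may differ (implemented by
ordering each block's distances ascending before pool-adjacent-violators).
Co-occurrence counts take at most $N + 1$ distinct values, so ties are
pervasive and this choice matters; the primary approach is the standard
one and keeps the perfectly-fitting configuration at stress 0.

**Identification.** Stress is invariant under rotation, translation,
reflection, and uniform scaling, so the returned configuration is
canonicalized: centered, scaled to unit root-mean-square point norm,
rotated so the first principal axis is horizontal, and sign-fixed per axis
(first statement with a non-zero coordinate is positive). A consequence is
that the `count_complement` and `proportion_complement` dissimilarity
transforms — which differ only by the factor $N$ — return identical maps
and stress, which is why the choice between them (not stated in most study
reports) is immaterial here.

**Ward tree.** `ward_tree()` is backed by `stats::hclust(method =
"ward.D2")` on Euclidean map distances, with merge heights reported as
$\Delta\mathrm{ESS}$ (the increase in within-cluster sum of squares; for
`ward.D2` this is height$^2/2$, verified in the suite against a brute-force
agglomeration oracle). Exact $\Delta\mathrm{ESS}$ ties essentially never
occur on continuous MDS coordinates; when they do, `hclust`'s internal
order decides. Clusters are renumbered by the lowest statement ID they
contain so solutions are comparable across runs. Complete and average
linkage are available behind a flag for sensitivity analysis.

**Rating conventions.** All arithmetic is at full precision; presentation
rounds half-up (away from zero) to 2 decimals via `round_half_up()`,
matching how published concept-mapping tables are printed. The cluster SD
is the population SD (divide by the number of statements) of the cluster's
statement means — the convention that reproduces published table cells.
Combined-scope means pool all raters one-vote-each; when a per-group
weighted aggregate is wanted, compute per-scope summaries and combine
explicitly. Missing ratings are allowed and handled by pairwise deletion.

**Data policies.** Sorts must be exact partitions; an incomplete sort is an
error by default (in-person card sorting yields complete sorts), with an
explicit `incomplete = "drop"` option that drops the sorter and warns.
Degenerate sorters — one pile for everything, or all singletons — are
retained (practice varies on exclusion) but exposed by `sort_quality()`.
Label scoring uses Jaccard rather than the overlap coefficient because it
penalizes oversized piles; score ties break by label frequency across
sorters, then lexicographically.

## What the synthetic generator emulates

`synthetic_config()` defaults describe a study-scale dataset: $S = 70$
statements in $K = 7$ planted clusters of near-equal size, $N = 23$
sorters, and two rater groups of 23 (consumers) and 34 (providers). Sorter
noise is three-layered, mimicking "lumper/splitter" behavior documented in
the concept-mapping literature: with probability `split_prob` (0.3) a
sorter splits one planted cluster, with probability `merge_prob` (0.3) they
merge two, and each statement independently jumps to a different pile with
probability `epsilon` (0.15). A single jitter parameter alone cannot
produce the stress levels real sort data show; the structural layers can.
With these defaults the two-dimensional map of the simulated data lands in
the 0.10–0.35 stress band typical of real projects (the validation suite
checks this across seeded replicates), while the planted partition remains
recoverable (median adjusted Rand index is checked against 0.9).

Ratings come from a latent value per (group, statement): group baseline
(consumers 4.0, providers 3.6 — consumers a shade higher, as stakeholder
comparisons often find), a group-specific cluster effect (evenly spaced
from $+0.35$ to $-0.35$ across clusters, with the provider ordering
permuted in the top two and bottom two ranks so the groups share top
clusters in different order), a per-statement effect (SD 0.25), and rater
noise (SD 0.9, typical single-item Likert dispersion), discretized by
round-then-clip to 1–5. Round-then-clip was chosen over an ordinal
threshold model for transparency; the clip introduces a small bias toward
the interior at extreme latent means, which is why convergence of sample
means to latent means is only checked away from the scale boundary.

One global seed feeds a separate sub-stream to the sort and rating stages,
so enlarging the rater panel never perturbs the generated sorts.

What the generator does **not** emulate: real pile-title text (labels are
cluster-tagged strings, so label recovery is mechanically checkable, which
real free-text titles would not be); sorter-specific skill or statement
ambiguity (noise is homogeneous); correlated rater panels; missing
ratings (generated panels are complete, though the pipeline accepts
partial ones). Passing recovery tests therefore shows the pipeline is
correct and well-behaved at study scale — not that any particular real
dataset's structure is this clean.

## Problem sizes in the validation suite

The suite exercises the pipeline end-to-end at the study scale (S = 70,
K = 7, N = 23) over 25 seeded replicates for the stress-distribution and
recovery checks, and uses small configurations (S ≤ 25) elsewhere so the
whole suite runs in a few minutes on one CPU. Brute-force oracles (exhaustive
$\Delta\mathrm{ESS}$ agglomeration; all-pairs Rand counting) are compared
on 50 random configurations with $S \le 12$, where exhaustive recomputation
is cheap.

## Known limitations

- A published study's exact stress value cannot be reproduced without its
  raw sort records; stress here is validated by its invariances, descent,
  exact small cases, and its distribution on study-scale simulations.
- The original concept-mapping software's algorithm, tie policy and linkage
  are not public; Kruskal stress-1, primary ties and Ward linkage are fixed
  here as the field-standard choices and documented as such.
- Published tables print statement means rounded to 2 decimals; recomputing
  cluster SDs from rounded inputs can differ from SDs computed on unrounded
  data in the last digit. The packaged example pins only the cells that
  reproduce from the printed precision.
- Nonmetric MDS in two dimensions can have local minima; the multistart
  default (10) makes results stable in practice but global optimality is
  not guaranteed.

## A worked example

```{r, eval = FALSE}
library(conceptmapr)

# simulate a study-scale dataset with planted structure
g <- generate_dataset(synthetic_config(seed = 1))
g$dataset

# run the pipeline into a directory of canonical exports
manifest <- run_pipeline(g$dataset, "cm-run", seed = 1, k = 7,
                         k_range = c(6, 8))
manifest$stress

# how well was the planted structure recovered?
recovery_report(g$dataset, g$ground_truth, seed = 1)[c("ari", "stress")]

# the packaged MOUD example: recompute the published cluster table
ex <- moud_example()
cluster_summary(as_solution(ex$membership), ex$statement_means)
```
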