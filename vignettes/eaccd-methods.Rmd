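---
title: "Methods: ensemble clustering of prognostic-factor combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble clustering of prognostic-factor combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaccd)
```

## The problem and the model

Staging systems place cancer patients into groups by combinations of
categorical prognostic factors (tumor-size level, nodal-status level, ...).
Given patient-level right-censored survival data, we want a data-driven
grouping of the *combinations* — the sets of patients sharing one level of
every factor — such that combinations in a group have similar survival.

The pipeline clusters combinations in three steps.

**Step 1 — initial dissimilarity.**  For each pair of combinations, a
weighted two-sample survival test is computed over the pooled distinct
event times $t_j$ with pooled events $d_j$, pooled at-risk count $n_j$, and
first-group counts $d_{aj}, n_{aj}$:

$$U=\sum_j w_j\left(d_{aj}-\frac{n_{aj}d_j}{n_j}\right),\qquad
V=\sum_j w_j^2\,\frac{n_{aj}}{n_j}\left(1-\frac{n_{aj}}{n_j}\right)
\frac{n_j-d_j}{n_j-1}\,d_j,$$

with $w_j=1$ (log-rank), $w_j=n_j$ (Gehan–Wilcoxon) or $w_j=\sqrt{n_j}$
(Tarone–Ware).  The initial dissimilarity is the chi-square-form statistic
$d_0=U^2/V$.  We use the quadratic form rather than the signed
$z=U/\sqrt{V}$ because a dissimilarity must be nonnegative; the two are
monotonically related for a fixed sign.  Variance terms with $n_j\le 1$
contribute zero, ties at an event time use the hypergeometric variance with
pooled $d_j$, and censored observations tied with an event time are treated
as still at risk at that time (the standard convention, also used by
`survival::survdiff`).  If $V=0$ (for example, no events in the pooled
pair), the statistic is defined as $0$ with p-value $1$ and the result is
flagged degenerate; `initial_dissimilarity()` additionally warns, naming
the pair.

$d_0$ is a *test statistic*, not a distance: it grows roughly linearly with
the number of events for a fixed true difference, satisfies no triangle
inequality, and two combinations are "close" only relative to how much data
they carry.  This sample-size dependence is precisely what the learning
step removes — and what makes approach A1 (below) fragile.

**Step 2 — learnt (consensus) dissimilarity.**  The combinations are
partitioned $m$ times.  Each run draws $K$ uniformly from the inclusive
integer interval $[K_1,K_2]$ and a partitioning procedure uniformly from a
configured collection (by default the collection holds a single procedure:
PAM with random initial medoids), then partitions the $n$ combinations on
the initial dissimilarity.  With $\delta_l(i,j)=1$ if run $l$ separates
combinations $i$ and $j$ and $0$ otherwise,

$$\mathrm{dis}(x_i,x_j)=\frac{1}{m}\sum_{l=1}^{m}\delta_l(i,j)\in[0,1].$$

The summation runs to $m$, matching the denominator.  PAM minimizes the
within-cluster scatter $\sum_k\sum_{C(x_i)=k}\mathrm{dis}_0(x_i,x_{i_k})$;
a $1/K$ prefactor would not change the argmin for fixed $K$, so the
reported objective is the unscaled sum.  One PAM run per ensemble
iteration is used — the averaging over $m$ runs, not per-run restarts, is
what smooths the landscape.

**Step 3 — hierarchical clustering.**  The consensus matrix is
agglomerated under average (default), complete or single linkage with the
Lance–Williams updates.  Cutting the dendrogram at $k$ gives the $k$-group
staging proposal.

## Assumptions

* Right censoring is non-informative and the survival experience within a
  combination is homogeneous (one survival function per combination).
* The two-sample tests are most sensitive to proportional-hazards-type
  differences; crossing survival curves reduce power (a property of the
  test family, inherited by the pipeline).
* Combinations are treated as fixed, pre-defined units; continuous factors
  must be discretized before entering the pipeline.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `m` | 10000 | runs | Consensus entries are Monte-Carlo frequencies with s.e. $\le 1/(2\sqrt{m})=0.005$; dendrograms are stable run to run at this size, visibly unstable at $m\le 100$. |
| `k_min`, `k_max` | 2, $n-1$ | clusters | All non-trivial partition sizes; uniform draw over $[K_1,K_2]$. |
| `test` | log-rank | — | Equal weighting of event times; the learnt dissimilarity is nearly invariant to this choice at large $m$. |
| `linkage` | average | — | The merge topology is typically shared with complete linkage, but merge *heights* depend on the linkage. |
| `seed` | none | — | Seeds R's RNG; identical seed and config give a bit-identical consensus matrix and tree. |

## Determinism, tie-breaking, degenerate inputs

* PAM (`src/pam.cpp`) accepts the best strictly improving medoid swap per
  iteration, scanning medoid slots and candidates in index order, so each
  accepted swap strictly decreases the objective and the result is
  deterministic given the initial medoids.  Points tied between equidistant
  medoids go to the lowest medoid index; a medoid always belongs to its own
  cluster, even when another medoid sits at dissimilarity zero (zero rows in
  the input are legal).  `init = "build"` is the greedy BUILD phase,
  classical PAM's default initialisation, and is used by approach A4;
  the ensemble itself uses `init = "random"` only.
* `k = n` returns every point as its own medoid with objective 0; `k = 1`
  returns the row-sum argmin.
* Agglomeration breaks ties among equal-height merge candidates toward the
  pair containing the lowest leaf indices (lexicographically).  Consensus
  matrices are lattices of multiples of $1/m$, so exact ties are common at
  small $m$; a fixed tie-break is required for cross-run topology
  comparisons to be meaningful.
* Heights are non-decreasing for all three linkages (no inversions), so
  `cut_tree()` is well defined for every $k$.
* p-values are kept in full double precision.  This matters for approach
  A2: with large well-separated cohorts, $1-p$ rounds to exactly 1 in
  double precision for most pairs, which is the documented failure mode of
  that approach, reproduced honestly rather than masked.

## The comparison approaches

* **A1** divides $\mathrm{dis}_0$ by its maximum and clusters directly.
  Because $d_0$ scales with sample size, an oversized combination inflates
  every entry in its row and ends up a root-adjacent singleton; equalizing
  cohort sizes (keeping the same survival difference) removes the artifact.
* **A2** uses $1-p$: bounded, but saturates (see above), compressing the
  top of the dendrogram into a sliver narrower than $10^{-6}$.
* **A3** clusters on min–max standardized mean raw tumor size $\hat T^s$
  and mean raw node count $\hat N^s$ with the $L_1$ distance
  $|\hat T^s_i - \hat T^s_j| + |\hat N^s_i - \hat N^s_j|$, standardized by
  its maximum.  Raw continuous covariates are required because within a
  combination the categorical level is constant; the means are taken on the
  raw scales (cm, node count), which is also why the tumor mean has a much
  larger range than the node mean before standardization.  Survival is
  never read, so combinations with identical covariate distributions but
  different hazards receive distance 0.  **A3\*** feeds A3's distance into
  the learning step; the blindness to survival is inherited.
* **A4** applies PAM with BUILD initialisation directly to A1's
  standardized matrix for each requested $k$.  Its partitions often agree
  with cutting the ensemble dendrogram, but not for every $k$; the test
  suite records per-$k$ agreement without asserting it.

## The synthetic-cohort generator

`generate_cohorts()` draws, per combination, exponential event times with
the combination's hazard (its latent group's base rate times a
per-combination multiplier), censoring as the minimum of an exponential
dropout time and an administrative follow-up cutoff, and raw covariates
uniform within the combination's clinical level ranges (tumor size: T1
$\le$ 2 cm, 2 < T2 $\le$ 5, T3 > 5 capped at 15 cm; nodes: 0, 1–3, 4–10,
>10 capped at 30).  Everything is deterministic given the scenario seed.

`standard_fixture()` is the canonical scenario: the 3×4 T×N grid with four
planted outcome groups of sizes 1/3/2/6 that cut across the factor grid,
monthly hazards from 0.0016 (T1N0) to 0.057 (T3N3), 4000 patients per
combination, dropout at 0.008/month, cutoff at 132 months.  Design choices
worth recording:

* **Unequal group sizes and staggered within-group hazards.**  Real
  registry combinations are never exactly tied; more importantly, idealized
  symmetric designs (equal-size groups, identical within-group hazards)
  make the fine merge order pure noise — different tests then disagree on
  topology — and make PAM's split patterns so symmetric that average and
  complete linkage produce *exactly* equal heights.  Both artifacts
  disappear when the within-group hazards form small, unequally spaced
  ladders (tight sub-pairs separated by larger gaps), which is also the
  more realistic shape of survival data.
* **Cohort size 4000.**  Large enough that the ordering of the pairwise
  statistics reflects the planted structure rather than sampling noise
  (the consequential gaps are several noise standard deviations), small
  enough that a full m = 10000 run takes seconds.
* **The oversized variant** (`inflate = TRUE`) gives T1N0 twenty times the
  patients *and* a markedly better hazard (0.0005/month ≈ 94% ten-year
  survival).  Both are needed: a two-sample statistic does not grow with
  $n$ under an exact null, so inflating a combination whose survival is
  identical to its neighbors' would not reproduce the size artifact.  The
  equalized comparator (`equalize_inflated = TRUE`) keeps the better hazard
  at the standard cohort size.
* **Exponential times** keep the implied censoring fraction in closed form
  (used as a generator check); the administrative cutoff mirrors the
  truncated follow-up window of registry extracts.

What the generator does **not** emulate: covariate–survival dependence
within a combination, stage migration, calendar-time effects, or the joint
covariate distribution of any real registry.  Tests passing on these
cohorts show the pipeline's algorithmic properties (recovery of planted
structure, convergence in $m$, invariances), not clinical validity on real
data.

## Problem sizes used by the test suite

The suite runs the full evaluation settings ($m=10000$, $K\in[2,11]$) on
the 12-combination fixture for the end-to-end checks (planted-group
recovery across five ensemble seeds, stability, and setting-invariance),
and smaller scenarios (4–6 combinations, a few hundred patients,
$m\le 2000$) for module-level properties.  Oracle checks use exhaustive
enumeration (PAM optima for $n=7$), literal transcriptions of the $U/V$
sums, `survival::survdiff`, `cluster::pam` and `stats::hclust` as
independent references.

## Known limitations

* The learnt dissimilarity is only defined relative to the chosen
  $[K_1,K_2]$; with $K_2=n-1$, members of large groups are frequently
  separated at large $K$, so within-group consensus values are nonzero by
  construction.
* Only PAM is shipped as a partitioner; the collection is pluggable
  (`ensemble_config(partitioners = ...)`) but alternatives are out of
  scope.
* Two-sample tests only: no multi-group, stratified or trend tests, and no
  confidence bands on the Kaplan–Meier curves.
* At desk scale (thousands of patients), near-ties in the initial
  dissimilarity can make one or two fine-grained clades test-dependent on
  unlucky realizations; at registry scale the statistics dwarf their
  sampling noise and this vanishes.
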