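---
title: "Differential co-expression networks and seeded subnetwork discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression networks and seeded subnetwork discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcnet)
```

## The model

`dcnet` analyses paired two-condition expression cohorts — the same
subjects measured in, say, tumour and adjacent normal tissue — on the
log2 scale. Its object of interest is the *change in co-expression*: a
gene pair whose Pearson correlation differs between the conditions. The
statistic is the classical two-sample comparison of correlations via the
Fisher transformation. For a correlation `r` estimated from `n` samples,
`z = arctanh(r)` is approximately normal with variance `1/(n − 3)`, so

$$\Delta z_{ij} = \frac{z^T_{ij} - z^N_{ij}}
{\sqrt{\tfrac{1}{n_T-3} + \tfrac{1}{n_N-3}}}$$

is approximately standard normal when the two population correlations are
equal. This approximation is the package's central distributional claim,
and the acceptance script re-verifies it by simulation: at `n = 60` per
group the empirical mean of $\Delta z$ over $10^5$ null pairs is within
±0.02 of 0, its variance within ±0.05 of 1, and the two-sided 5% test
rejects at 5% ± 1%.

The differential co-expression network (DCN) keeps a pair as an edge iff

* the BH-adjusted z-test p-value is below `t_z`, **and**
* the pair is co-expressed in at least one condition — an edge of the
  normal (NCN) or tumour (TCN) co-expression network, themselves
  thresholded at BH-adjusted correlation p-values `t_N`, `t_T`.

Edges carry the weight $|\Delta z|$ (the extent of change; the signed
value is retained on the edge for inspection). The second condition makes
the DCN interpretable: a correlation change between two genes that are
co-expressed in neither condition is most often noise around zero.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `t_n`, `t_t`, `t_z` | `1e-7` | BH-adjusted p cutoffs for NCN, TCN and the z-test. The stringent default keeps only pairs whose co-expression is unambiguous at n ≈ 60. |
| `d_max` | 2 | Greedy search: maximum hop distance from the seed in the full DCN. Controls the search space; subnetwork size is non-decreasing in it. |
| `improvement_rate` | 0.1 | Minimum relative score gain `(new − old)/old` to accept an addition. Subnetwork size is non-increasing in it. |
| `alpha` | 0.7 | Weight of differential expression vs differential co-expression in `D_G = α·DE_G + (1−α)·DC_G`. `α = 1` reduces `D_G` to `DE_G` exactly, `α = 0` to `DC_G`. |
| `n_permutations` | 100 | Permutations / random subnetworks per significance test. With the add-one rule the smallest attainable p is 1/101. |
| `bh_universe` | `union_edges` | Pair set over which z-test p-values are BH-corrected: only NCN ∪ TCN edges (the only pairs eligible for the DCN) or all evaluated pairs. The wording of the multiple-testing step is ambiguous in this design; both are provided and recorded in the DCN provenance, and results can differ near the threshold. |

## Numerical and procedural choices

These are the places where the procedure needed a concrete decision; each
is fixed, documented, and (where relevant) switchable.

**Correlation edge cases.** Correlations are clamped to
±(1 − 10⁻¹⁵) before `arctanh`, so numerically perfect correlations give
large finite z rather than infinities; the corresponding p-value for
|r| = 1 is defined as exactly 0 (the analytic limit). Pairs involving a
gene with zero variance within a condition have no defined correlation
and are excluded with a log message — the variance filter upstream does
not guarantee per-condition variance.

**Variance filter.** Genes with coefficient of variation (sd/mean) below
0.05 across *all* samples, both conditions pooled, are removed before
network construction. The filter is idempotent and order-preserving;
genes with mean 0, where CV is undefined, are removed rather than
errored.

**Differential expression.** Paired two-tailed t-test on
tumour − normal log2 differences; fold change is `2^(Δ of log2 means)`;
status `up` requires BH p < 0.05 *and* FC > 2, `down` FC < 0.5. Genes
whose paired differences are exactly constant and nonzero have no finite
t and are excluded from calls (flagged `degenerate`); all-zero
differences are the clean null, t = 0, p = 1.

**Greedy search.** The seed's initial score is `α·|t_seed|`: `DC_G` is
defined as 0 on an empty edge set, since the mean over edges is otherwise
undefined. When a node is added, *all* DCN edges between it and the
current members join the subnetwork. The improvement condition is
relative by default (`improvement_mode = "absolute"` switches to an
absolute gain), and when the current score is ≤ 0 — possible only for a
seed with t = 0 — any strict increase is accepted, since the relative
ratio is undefined at 0. Ties between equal-scoring candidates break by
lexicographically smallest gene id, which makes the search fully
deterministic and invariant to input ordering. Hop distances to the seed
are computed once on the full DCN by breadth-first search, not
recomputed on the growing subnetwork.

**When can the greedy grow?** Because `DE_G` and `DC_G` are *means*, an
addition improves the score only if it raises the mean — the new node
needs a larger |t| than the current average, or edges heavier than the
current average weight, by enough to clear the improvement rate. On real
cohorts this heterogeneity is the norm and subnetworks of 5–15 genes
emerge. On perfectly exchangeable synthetic modules (every member the
same expected |t|, every edge the same expected |Δz|) the score is
maximized by the seed plus its single strongest edge, and the search
stops at two nodes no matter how small the improvement rate: recovering
such a module *as a whole* is outside what a mean-based local search can
do, and the package's recovery simulations report exactly that. This is
a property of the score, not a failure of the optimizer; tests verify
the greedy against a brute-force re-implementation step by step.

**Significance tests.** P1 permutes condition labels *within pairs*
(each pair swapped independently with probability ½), preserving the
paired design that the t statistics assume; an unpaired shuffle is
available via `p1_scheme = "free"`. The fixed node and edge sets are
re-scored from raw data in every permutation (t, correlations, Δz all
recomputed). P2 draws the seed plus n − 1 uniform DCN genes and keeps
the top e induced edges by weight (all of them when fewer than e exist —
resampling until e edges exist would bias the null toward dense
regions). Both p-values use the add-one rule, so they are never 0 and
never below `1/(B + 1)`; both are bit-for-bit reproducible from the
configuration seed. Under module-homogeneous synthetic data P2 is
conservative for small subnetworks: a random draw that happens to land
in the same module is nearly as good as the observed one.

**Cross-dataset validation.** Subnetwork topologies stay fixed; node t
statistics and edge weights are recomputed from each validation cohort
(the DCN is reweighted the same way to serve as the P2 null pool), and a
subnetwork is called differential only if both tests pass at 0.05 in
every cohort where all its genes are present. Missing genes make a
subnetwork non-evaluable in that cohort, which is reported, never
silently passed.

**Core modules.** The concrete greedy: start from each gene captured by
≥ `min_capture` subnetworks; repeatedly add the gene maximizing the
joint capture count (number of subnetworks containing *all* members)
subject to the count staying ≥ `min_capture`, ties by smallest gene id;
keep maximal results with ≥ `min_genes` genes and drop subset-duplicates.
An exhaustive subset-enumeration oracle checks this on small inputs.

**Topology.** Local clustering for degree < 2 nodes is defined as 0 and
included in the mean (one of the two standard conventions, fixed for
reproducibility); mean shortest path averages over connected pairs only;
the diameter refers to the largest component. The power-law exponent is
estimated by least squares on (log₁₀ k, log₁₀ P(k)) with zero-frequency
bins excluded — the simple diagnostic fit, not a maximum-likelihood
estimator. Two random baselines: G(n, m) with matched node and edge
counts, and degree-preserving double-edge-swap rewiring (10·|E| swap
attempts); the first answers "is the clustering above chance for this
density", the second "is the structure explained by the degree sequence".

**Activity.** Member genes are z-scored across all samples before
aggregation, so a high-variance gene cannot dominate a subnetwork's mean
profile; this convention is recorded in the activity object. The first
principal component's sign is anchored to correlate non-negatively with
the mean profile. Classification uses lasso-penalized logistic
regression with the penalty chosen by internal cross-validation; AUC is
computed by the rank (Mann–Whitney) formula.

## The synthetic generator: what it does and does not emulate

`generate_cohort()` draws module genes from multivariate normals with
compound-symmetry correlation per condition (`rho_normal`,
`rho_tumour`), adds a log2 mean shift in tumour, and surrounds them with
independent background genes; per-gene baseline means are N(8, 2),
a typical range for quantile-normalized log2 microarray intensities.
The first module gene is the lncRNA hub; a configurable fraction
(default 20%) of background genes is also labelled lncRNA. Everything is
bit-reproducible from the seed.

This emulates the *designed* signal — blocks co-expressed in one
condition and not the other, optionally mean-shifted — and deliberately
not the texture of real data: no heavy-tailed intensities, no
probe/batch effects, no correlated background, no count noise, and
module members are exchangeable. Consequently, passing recovery tests
shows the pipeline detects the planted signal class; it does not certify
performance on real cohorts, where heterogeneity both helps the greedy
(see above) and complicates the nulls. Null-cohort simulations at desk
scale (hundreds of genes) give empty DCNs at the default thresholds in
≥ 95% of runs, which is the relevant specificity check.

## Problem sizes used in the checks

The packaged simulations are sized for a desk machine: null calibration
uses 10⁵ gene pairs at n = 60 per group; recovery runs 20 replicate
cohorts of two 8-gene modules (ρ_N = 0.9, ρ_T = 0, shift 1 log2 unit)
against 300 background genes; permutation calibration uses 150–200
replicates at 49 permutations each; oracle-equivalence fixtures stay at
≤ 30 nodes / ≤ 10 samples where brute force is exact. These sizes were
chosen so every check runs in seconds to a few minutes while keeping
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The greedy search finds locally maximal subnetworks; no global
  optimality is claimed or attempted.
* P1/P2 are raw permutation p-values thresholded at 0.05 per subnetwork;
  there is no FDR control across subnetworks.
* The BH universe for the z-test is a genuine degree of freedom (see
  `bh_universe`); near-threshold edges can differ between the modes.
* Mean-based scores cannot grow subnetworks through regions of uniform
  signal strength (analysis above); sum-based scores would, but change
  the method.
* At 100 permutations the smallest attainable p-value is 1/101 ≈ 0.0099;
  finer significance claims need more permutations.
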