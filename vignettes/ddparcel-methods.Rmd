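---
title: "Parcellating spatial connectivity with ddparcel: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parcellating spatial connectivity with ddparcel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many biological and social systems are measured as an `N x N` matrix `D` of
pairwise connectivities between elements that live on a spatial map: fMRI
correlations between cortical locations, tract counts between grey-matter
voxels, migration flows between counties. A useful summary of such a matrix
is a *parcellation*: a partition of the elements into contiguous parcels
such that the connectivity between any two parcels is approximately
constant. Finding parcels jointly summarises the rows *and* columns of `D`
— the between-parcel block matrix is the compressed picture of the system —
and the spatial-contiguity requirement makes the parcels interpretable as
local units.

`ddparcel` fits such parcellations with a generative Bayesian model rather
than a greedy merge heuristic, learns the number of parcels from the data,
and guarantees contiguity by construction.

## The model

**Prior over partitions.** Each element `i` draws a link `c_i` to itself,
with weight `alpha`, or to one of its spatial neighbours, each with weight
1 (a distance-dependent Chinese restaurant process whose distance function
is the adjacency indicator). Parcels are the connected components of the
undirected link graph. Two properties follow immediately:

* every realizable partition is spatially contiguous, so the sampler
  searches *only* contiguous parcellations — no post-hoc repair;
* the number of parcels is not fixed in advance; even `alpha = 0` yields
  many parcels because links are local.

**Likelihood.** Given a partition `z` with `K` parcels, the connectivities
between parcel `m` and parcel `n` are modelled as i.i.d.
`Normal(A_mn, sigma2_mn)` with a conjugate Normal–Inverse-chi-squared prior
`(A_mn, sigma2_mn) ~ NIchi2(mu0, kappa0, sigma0_sq, nu0)`. Conjugacy lets
the block parameters integrate out, leaving a closed-form marginal per
block that depends on the data only through the block count `L`, mean, and
sum of squared deviations `s`. The collapsed posterior over link states is

    p(c | D) ∝ p(c) * prod over parcel pairs of p(D_block)

with within-parcel blocks included in the product.

**Inference.** Collapsed Gibbs sampling over the links. One step removes
`c_i` (possibly splitting `i`'s parcel into the two components of the link
graph), scores each candidate in `{i} ∪ neighbors(i)` — a candidate that
re-merges two parcels is scored through pooled block statistics using the
identity `s_merged = s1 + s2 + L1*L2/(L1+L2) * (mean1 - mean2)^2`, never by
re-reading the data — and resamples the link. Each pass sweeps all elements
in a fresh uniform random order (the sweep order is otherwise arbitrary; a
fixed order could imprint itself on the parcel boundaries). The state with
the highest log posterior seen anywhere along the trajectory is reported as
the MAP parcellation. There is no burn-in or convergence rule: `passes` is
an explicit budget, and the per-step trace (`record_trace = TRUE`) lets a
user inspect whether the score has plateaued.

## Conventions and numerical choices

* **Normalization.** `D` is standardized to zero mean and unit
  (population) variance over its *included* entries before fitting, so
  `sigma0_sq` values are comparable across datasets of similar size.
* **Diagonal.** Self-connectivity is excluded everywhere (normalization,
  block statistics, variance explained). For correlation data the diagonal
  is identically 1 and uninformative.
* **Symmetric input.** When `D` is symmetric, each unordered element pair
  is counted once (upper triangle): counting both orders would enter every
  observation twice in the likelihood. Blocks are then indexed by unordered
  parcel pairs, and a within-parcel block of size `p` holds
  `p*(p-1)/2` observations. Asymmetric input uses all ordered pairs.
* **Log domain.** All marginals are computed with `lgamma`; no raw Gamma
  evaluations, so large blocks cannot overflow.
* **Empty blocks.** `L = 0` contributes log-marginal 0; splitting a parcel
  never changes the score through blocks that hold no data.
* **The `pi` exponent.** The closed-form NIchi2 marginal carries a factor
  `pi^(-L/2)` whose exponent scales with the number of observations in the
  block, like every other data-dependent factor. The test suite checks this
  closed form against direct 2-D numerical quadrature of the
  Normal × NIchi2 integral to at least six significant digits; the
  quadrature confirms normalization only under this reading.
* **Label canonicalization.** Parcels are numbered by their smallest member
  index, so serialized outputs are deterministic. All element ids — in R
  and in files — are 1-based.

## Hyperparameters

| parameter | meaning | default |
|---|---|---|
| `sigma0_sq` | prior expected within-block variance (units of the standardized matrix) | none — per run |
| `alpha` | self-link weight; larger favours more parcels at the margin | 10 |
| `mu0` | prior block mean | 0 |
| `kappa0` | prior precision on the block mean | 1e-4 |
| `nu0` | prior degrees of freedom on the block variance | 1 |

In practice `sigma0_sq` is the only setting that materially shapes the
solution: it is the scale against which within-block scatter is judged, so
smaller values demand tighter blocks and produce more, smaller parcels.
For the clean synthetic grids we use `0.01`; for the noisy, sparse
synthetic flow matrices — where most of the standardized variance is
observation noise rather than block structure — a value near the total
variance (`1`) is appropriate, mirroring how connectivity applications use
much larger values for noisy real matrices than for clean ones. The
remaining defaults are weakly informative: `kappa0 = 1e-4` makes block
means essentially data-driven, and `nu0 = 1` is one pseudo-observation of
variance.

## Initialization

The default `"ward-auto"` initialization runs spatially constrained Ward
linkage (see below) once, producing a full merge hierarchy; candidate
cluster counts `K ∈ {2, 4, 8, …}` (plus a ±25% refinement around the best
candidate) are scored under the model and the best is kept. For a link
state that realizes a given partition with one spanning tree per parcel,
the prior contributes exactly `K log(alpha)` plus a constant — each parcel
has exactly one self-linked root — so the selection criterion is the
collapsed likelihood plus `K log(alpha)`, evaluated without constructing
links. The links themselves are then drawn as one *uniform* random
spanning tree per parcel (Wilson's loop-erased random-walk algorithm),
oriented towards a root self-link. Uniformity matters only for diversity
across restarts; any spanning tree realizes the same partition.
Alternatives: `"ward-k"` (fixed initial `K`) and `"random"` (every link
uniform over its candidate set); the sampler's result should not depend
much on the choice, at the cost of more passes for `"random"`.

## Baselines

All four comparison methods operate on the connectivity-fingerprint
dissimilarity

    W_ij = sqrt( sum_{a != i,j} (D_ia - D_ja)^2 + sum_{a != i,j} (D_ai - D_aj)^2 )

and are constrained to the spatial graph; all take the target number of
clusters `K` from the model (they cannot infer it).

* **Local similarity** removes spatial edges above a dissimilarity
  threshold and takes connected components: spatially constrained single
  linkage. The component count is a step function of the threshold, so the
  threshold is found by binary search; when `K` falls in a gap the nearest
  achievable solution is repaired by merging the smallest adjacent
  components (with a warning).
* **Normalized cut** uses edge similarity `1/W` (capped at `1e12` for zero
  dissimilarities), a K-way spectral embedding of the normalized affinity,
  and k-means discretization; spatially disconnected clusters are split
  into components and the count repaired back to `K`. The K-way variant is
  used rather than recursive bisection.
* **Region growing** seeds at elements whose worst neighbour dissimilarity
  is a local minimum (ties broken by index; the seed count is data-driven),
  grows regions by attaching the unassigned element with the smallest
  dissimilarity to an adjacent region's seed, then merges grown regions to
  `K` by constrained Ward.
* **Constrained Ward** merges only spatially adjacent clusters under
  Ward's variance-minimizing rule, implemented with the Lance–Williams
  recurrence on squared dissimilarities. Distances are maintained between
  all cluster pairs and only the merge choice is restricted to adjacent
  pairs, so newly adjacent clusters always have an exact Ward distance.
* **Random parcellations** (uniform merges of adjacent clusters down to
  `K`) provide the chance envelope for every comparison.

## Synthetic benchmarks

The grid generator plants a ground-truth parcellation on an 18 × 18
4-neighbour grid, draws `K x K` block means i.i.d. standard normal
(symmetrized for symmetric output), and samples every included entry
`D_ij ~ Normal(A[z_i, z_j], sigma^2)`. Three fixed layouts are provided:
`squares9` (nine equal 6 × 6 squares — the friendly case for methods with
an equal-size bias), `stripes6` (horizontal stripes of heights
6, 4, 3, 2, 2, 1, the two smallest adjacent — unequal sizes with thin
structures), and `nonuniform5` (a large L-shaped region plus rectangles of
sizes 96, 48, 24, 12 — strongly nonuniform). The exact layouts are
versioned constants of this package. A three-spiral geometry
(`spiral_truth`) provides a harder, non-grid adjacency: consecutive points
along each Archimedean arm plus nearest cross-arm neighbours.

The flow generator (`simulate_flow_table`) emulates census-style
origin–destination tables: units on a planar grid with contiguous
administrative groups, planted contiguous communities grown to comparable
sizes from random seeds, log-normal populations, and Poisson mover counts
at the population-chance rate times `effect` within communities. Chance
normalization (`normalize_flows`) divides each count by the flow expected
from population alone, exactly as one would preprocess real flow tables
after merging sub-threshold units (`merge_small_units`, which absorbs the
globally smallest unit into its smallest within-group neighbour, ties by
id, until all units pass the threshold).

What the generators do *not* emulate: spatially smooth noise (real fMRI
noise is strongly autocorrelated), heavy-tailed or log-normal connectivity
magnitudes, missing data, and measurement asymmetries between the two
directions of a truly symmetric quantity. Recovery results on these
benchmarks therefore demonstrate correctness of the inference machinery —
not performance on any particular empirical dataset.

## Problem sizes and test design

The package's tests exercise full recovery runs at the 18 × 18 grid scale
(324 elements, 30 passes, roughly 10,000 Gibbs steps — seconds per run)
and 20-replicate method comparisons at high noise; exhaustive enumeration
oracles (prior normalization, candidate probabilities, posterior
frequencies of a 4-element chain) are used wherever the state space is
small enough to enumerate. Larger problems scale as `O(N)` memory for the
links and `O(N^2)` for the matrix itself; per-step cost is dominated by
the `O(K)` pooled-block updates plus the occasional split refresh.

## Limitations

* The reported parcellation is the best state *visited*, not a posterior
  summary; multimodality is explored only through passes and restarts.
* No convergence diagnostic is built in; inspect the trace.
* The likelihood assumes within-block normality after standardization;
  strongly skewed matrices (raw tract counts, raw flows) should be
  transformed (log, chance normalization) first.
* The dense-matrix implementation targets matrices up to a few thousand
  elements; it does not exploit sparsity.
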