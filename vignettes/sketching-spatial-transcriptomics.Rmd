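---
title: "Sketching designs for spatial transcriptomics: methods and benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketching designs for spatial transcriptomics: methods and benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stsketch)
```

## The problem

Imaging- and array-based spatial transcriptomics (ST) platforms now measure
hundreds of thousands of cells or binned locations per tissue section.
Sketching — selecting a small subset of cells that preserves the structure of
the full dataset — makes exploratory analysis tractable, but sketchers
developed for dissociated single-cell data optimize coverage of the
*expression* manifold only. On tissue, that can concentrate the sample in
transcriptionally variable regions and starve homogeneous ones, distorting
neighbourhood composition, domain boundaries, and any downstream analysis
that relies on spatial context. Coordinate-only sampling has the opposite
failure: even tissue coverage, but no guarantee that rare expression states
survive the cut.

`stsketch` implements the main sketching families over exchangeable input
representations, plus a simple spatially aware design, and wraps them in a
simulation-driven benchmark so the trade-offs can be measured rather than
argued.

## Sketching designs

All designs draw $k = \max(1, \lfloor f \cdot n \rfloor)$ distinct indices
without replacement at sampling fraction $f$; the floor-with-minimum rule is
the usual convention and avoids empty sketches.

**Uniform sampling** (`uniform_sketch`) draws indices with equal
probability. It is the baseline every design must beat.

**Leverage-score sampling.** For a column-orthonormal basis $U$ of the
(normalized) expression matrix, the leverage score of cell $i$ is
$\ell_i = \lVert U_{i\cdot} \rVert^2$ — the $i$-th diagonal entry of the hat
matrix, which measures the cell's influence on the low-rank fit. Scores are
normalized to probabilities and sampled without replacement by sequential
renormalized draws (`probability_sample`), which matches the
without-replacement contract exactly and is reproducible per seed. Two
routes produce $U$:

* *exact* (`leverage_scores_exact`): rows of the left singular vectors of
  the PCA decomposition; for orthonormal $U$ the scores sum to the basis
  rank, an identity the tests exploit;
* *approximate* (`leverage_scores_approx`): project the cell-by-gene matrix
  against a seeded Gaussian test matrix, orthonormalize by QR, and take
  squared row norms — the standard randomized approximation for matrices too
  large to decompose. The QR factor is truncated at its numerical rank so
  exactly low-rank inputs do not pick up noise columns.

**Spatially smoothed leverage (the spatially aware design).** A sparse
row-stochastic spatial weights matrix $W$ averages each cell with its $k$
nearest spatial neighbours. Multiplying the randomized-SVD basis by it,
$\bar{U} = W U$, blends each cell's expression representation with its
tissue neighbourhood; leverage scores are then the raw squared row norms of
$\bar{U}$ (no re-orthonormalization — smoothing deliberately breaks
orthogonality, and the row norms are the quantity of interest). High scores
now require *spatially coherent* transcriptional distinctiveness, which
damps isolated noisy cells and spreads the sample across the tissue while
preserving genuinely distinct domains.

**Minimax / Hausdorff coverage** (`minimax_sketch`). The design objective is
to minimize the directed Hausdorff distance from the data to the sketch —
the largest "hole" in coverage. The implementation is grid covering: a
binary search (30 iterations) over the lattice cell width finds the coarsest
width whose occupied cells still number at least $k$; ties in the occupied
count are then resolved toward the smallest width attaining it, so cells
stay compact and well-separated clusters occupy distinct cells. $k$ occupied
cells are chosen uniformly (all of them when the counts allow) and one
random member is taken from each. If duplicated points leave fewer than $k$
occupied cells at the finest width, the sketch is completed farthest-first.

**Maximin spread** (`maximin_sketch`). Greedy farthest-first traversal from
a uniformly random start: each added point maximizes the minimum distance to
the current sketch, ties broken by lowest index. This greedily maximizes the
minimum pairwise distance of the sketch and is the classical factor-2
approximation of the optimal maximin design — a bound the test suite checks
against exhaustive enumeration on small instances. A random (rather than
extremal) start keeps replicate-to-replicate variability honest.

Every design runs over any of three representations: the 20-component PCA
embedding, the raw spatial coordinates, or the spatially smoothed embedding
$W \cdot \text{PCA}$. Uniform sampling over coordinates is refused: on any
reasonably even point set it is indistinguishable from plain uniform
sampling.

## Preprocessing

Cells with fewer than `min_counts` (default 100) total counts are dropped;
remaining cells are dropped when their total deviates from the mean total by
more than `mad_multiplier` (default 5) times the mean absolute deviation
about the mean, computed on the cells passing the first rule. The
dispersion statistic is read literally as the *mean* absolute deviation and
applied two-sided on raw totals; the low tail is in practice captured by the
count floor. Counts are then library-size scaled to `scale_target` (default
10,000, the prevailing convention) and `log1p`-transformed, preserving
sparsity, and embedded with a seeded randomized SVD (Gaussian range finder,
oversampling 10, QR-stabilized power iterations). For small problems the
sampled subspace spans the full column space, so the decomposition is exact
— which is what lets the tests compare it against dense eigendecomposition
oracles.

## The synthetic tissue generator

The generator emulates the two dominant ST geometries at a target scale of
100,000 locations by 500 genes with six domain classes:

* **grid** layout — a unit-spacing integer lattice with
  $\lceil \sqrt{n} \rceil$ columns, truncated to exactly $n$ points
  (Visium-like binned arrays);
* **random** layout — $n$ points uniform on a square of side $\sqrt{n}$, so
  point density stays ~1 per unit area at every $n$ (Xenium-like segmented
  cells).

Domains follow one of three patterns: `stripes` (equal-width vertical
bands), `radial` (equal-population annuli about the centroid), or `complex`
(a Voronoi mosaic over three random seed points per class, chosen because it
produces the irregular multi-domain patchwork seen in real sections). Every
class is guaranteed non-empty.

Expression follows a zero-inflated negative binomial. Gene $g$ draws a
baseline mean $\mu_g \sim \mathrm{LogNormal}(\log 0.5, 1)$; each class owns
a disjoint block of 25 signal genes whose mean is multiplied by
$e^{\mathrm{logfc}_c}$ in cells of that class, with distinct log fold
changes spanning $\log 2$ to $\log 8$ across the six classes. Counts are
NB with mean $\mu$ and size (dispersion) 2 — variance $\mu + \mu^2/2$, the
mean/size parameterization stated explicitly to avoid shape/rate ambiguity —
then independently zeroed with probability 0.2. These defaults are fixed
package choices for a typical imaging-ST count regime (panel-scale gene
sets, per-gene means below one, strong overdispersion, appreciable
dropout); they are gated by the requirement that the resulting domains be
separable — a 20-component PCA plus graph clustering of a 10,000-cell
dataset must recover the ground-truth labels at ARI at least 0.7, which the
acceptance suite recomputes every run.

What the generator does *not* emulate: within-domain cell-type mixtures,
spatial expression gradients inside a domain, segmentation errors, platform
noise such as probe misassignment, or batch structure. Passing benchmarks on
these simulations therefore demonstrates that a design respects clean,
separable domain architecture — not that it is robust to every failure mode
of real tissue. One consequence documented in the test suite: on perfectly
pure domains, a sketch concentrated in one domain reproduces local label
compositions exactly (the over-sampled patch is locally fully dense), so the
neighbourhood-distortion cost of biased sampling only appears when labels
mix at fine scale, as they do in real tissue; the corresponding test
injects 30% label mixing before over-sampling one class.

## Evaluation framework

**Robust (partial) Hausdorff distance** (`partial_hausdorff`), in both PCA
space and coordinate space: the $q$-quantile (default $q = 0.99$; $q = 1$
recovers the classic maximum) of each full point's distance to its nearest
sketched point. The quantile makes the statistic insensitive to a few
outlying cells; the paper-style "worst-case hole in coverage" reading
survives at $q$ near 1. The default is a package choice, exposed as a
parameter.

**Adjusted Rand index** (`adjusted_rand_index`, `cluster_for_ari`): the
sketch is re-embedded by a fresh PCA of its own normalized counts (not a
row-slice of the full-data scores — the point is to measure what an analyst
working only with the sketch would recover), clustered on a shared-nearest-
neighbour graph ($k = 15$, Jaccard edge weights, weak edges pruned below
1/15) by seeded Louvain modularity optimization, and compared against
ground-truth labels when the dataset has them, else against a full-data
clustering computed once. The resolution parameter trades cluster
granularity; 1 is the default, and coarse structure questions (e.g. "are
these two blobs two clusters?") are asked at lower resolution.

**PCA projection difference** (`pca_projection_difference`): sketch rows
projected onto full-data components versus components learned from the
sketch alone, columns sign-aligned by correlation, mean Euclidean distance
between the aligned projections. Alignment is sign-only by design: rotation
(Procrustes) alignment would absorb exactly the within-subspace drift the
metric is supposed to expose. The flip side, documented here as a
limitation: when eigenvalues tie or nearly tie, the principal axes are only
defined up to rotation, and the metric reports that rotation as drift even
though the subspace is preserved.

**Local neighbourhood distortion** (`neighborhood_mse`): for each sketched
cell, the label-composition vector over its $k = 20$ nearest spatial
neighbours (self excluded) computed in the full population versus within the
sketch; the mean over sketched cells of the mean squared difference across
label categories. Bounded above by 2; zero iff the sketch preserves local
tissue composition exactly at its own locations.

**Overall spatial score** (`rank_sum_score`): at one sampling fraction,
replicate values are averaged, each condition is ranked per metric (rank 1
best: highest ARI, lowest coordinate Hausdorff, lowest neighbourhood MSE;
ties take average ranks), and the three spatial ranks are summed. Lower is
better. Averaging replicates before ranking keeps a single noisy replicate
from deciding a rank.

## The benchmark orchestrator

`run_benchmark` computes preprocessing, PCA, spatial weights, and smoothed
embeddings once per dataset, then runs every (method, representation,
fraction, replicate) cell, with replicate $r$ seeded as `base_seed + r` and
every stochastic stage deriving independent sub-streams from that seed, so a
rerun is bit-identical. Coordinate-representation conditions are skipped
with a warning on lattice layouts, where coordinate sketching collapses to
uniform sampling. Each cell yields all five metric records; the record count
is always (conditions x fractions x replicates x 5), a cardinality the tests
pin down.

## Numerical choices and tie-breaking

* Nearest-neighbour search is exact everywhere: a grid-bucket search with
  ring expansion for 2-D coordinates at large $n$ (the candidate's $k$-th
  distance is compared against the guaranteed-covered ring radius before
  acceptance, so results equal brute force), chunked brute force otherwise.
  Distance ties break by lowest index throughout, which is what makes
  small-instance oracle tests exactly reproducible.
* Spatial weights: $k = 15$ neighbours, uniform kernel, self included, rows
  normalized to sum 1. A Gaussian kernel ($\sigma_i$ = distance to the
  $k$-th neighbour) is available. One smoothing pass is the default;
  `passes` composes $W^p$.
* Randomized solvers (SVD, leverage projection) take explicit seeds and
  restore the caller's RNG state, so library calls never perturb user code.
* Sketch sizes, seeds, and index sets are integer-exact; every sampler
  sorts its result so downstream consumers see deterministic order.
* Degenerate inputs: all-identical points fall back to uniform selection in
  the minimax design; zero-distance neighbours get machine-epsilon
  bandwidths in the Gaussian kernel; `qc_filter` raises an error naming both
  rules' casualties when nothing survives.

## Problem sizes used by the shipped checks

The test suite and acceptance script regenerate everything they measure.
The full-scale design check generates the complete 100,000 x 500 default
dataset once; domain-recovery clustering runs at 10,000 cells; the
rare-class experiment uses 2,000 cells with a 20-cell (1%) rare class whose
marker program has a strong fold change ($\log 80$) over a low baseline —
the regime in which a rare state is transcriptomically extreme, which is
the premise of influence-based sketching; the stripe-ranking experiment
uses 8,000 cells, six conditions, and ten base seeds. These sizes are the
package's choices for a benchmark that is informative yet routinely
re-runnable on a laptop core.

## Known limitations

* The spatial weights construction (kNN averaging) is one of several
  reasonable readings of "spatial weights matrix"; Delaunay or radius graphs
  and Laplacian smoothing are deliberate non-goals.
* The minimax grid search optimizes coverage through occupied cells, not the
  Hausdorff objective directly; it inherits grid anisotropy in very
  elongated embeddings.
* ARI against full-data clusters (label-free datasets) inherits the
  stochasticity of the reference clustering; the reference is computed once
  per benchmark and cached to keep conditions comparable.
* Sign-only alignment in the projection-difference metric conflates
  subspace rotation with drift under (near-)degenerate spectra, as
  discussed above.
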