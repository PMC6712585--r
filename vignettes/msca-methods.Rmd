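---
title: "Multi-view subspace clustering: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view subspace clustering: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msca)
```

## The problem

Tumour samples (or cell lines, patients, strains) profiled by several omics
platforms — expression, copy number, methylation — rarely form groups that any
single platform can resolve. Each data type sees its own projection of the
underlying biology: two subtypes may be indistinguishable in expression yet
cleanly separated in copy number, and vice versa. The aim of this package is
to recover the *integrated* sample partition, including boundaries that no
single view contains.

The package assumes the union-of-subspaces picture of omics data: each sample
group engages its own (small) set of molecular programmes, so its profiles
concentrate near a low-dimensional — possibly curved — subspace of the
feature space. Plain Euclidean distance is a poor guide in this regime
(two samples in the same subspace can be farther apart than two samples in
different ones), which is why the pipeline builds its similarity graph from a
*representation* model rather than from a kernel of distances.

## Stage 1: locality-constrained low-rank representation

For one view with matrix $X \in \mathbb{R}^{h \times n}$ (features × samples)
we solve

$$
\min_{Z, E} \; \|Z\|_* + \lambda \|E\|_{2,1}
\quad \text{s.t.} \quad
X = XZ + E, \qquad Z^\top \mathbf{1} = \mathbf{1}, \qquad
Z_{ij} = 0 \;\; \forall (i,j) \notin \Omega ,
$$

where $\|Z\|_*$ is the nuclear norm (sum of singular values, the convex
surrogate of rank), $\|E\|_{2,1} = \sum_j \|e_j\|_2$ penalises whole outlying
*samples* rather than scattered entries, and $\Omega$ restricts each sample's
representers to its $K$ nearest neighbours in Euclidean distance
(`knn_adjacency()`). Three modelling choices deserve comment:

* **Low rank** drives $Z$ towards a block-diagonal pattern across subspaces:
  samples are most parsimoniously expressed through members of their own
  subspace.
* **Locality** ($\Omega$) is what lets the model track *curved* manifolds: a
  sample on a curved surface is well approximated by an affine combination of
  its neighbours even when the surface as a whole is not linear. We use the
  directed, column-wise K-NN set exactly as the constraint reads; symmetry is
  restored later when the affinity is built. The diagonal is excluded from
  $\Omega$, otherwise $Z = I$ is a feasible (and useless) point.
* **The affine constraint** $Z^\top \mathbf{1} = \mathbf{1}$ makes the
  representation affine rather than linear, which keeps the model correct for
  subspaces and manifolds that do not pass through the origin (and for
  feature-centred data).

### The solver

`solve_lrr()` uses a linearized alternating-direction method with adaptive
penalty. With augmented-Lagrangian penalty $\mu$ and multipliers
$Y_1, Y_2, Y_3$ for the three constraints, each iteration performs

1. $J \leftarrow \mathrm{svt}(Z + Y_3/\mu,\; 1/\mu)$ — singular-value
   thresholding, the closed-form proximal step of the nuclear norm
   (`svt()`);
2. $E \leftarrow \mathrm{shrink}_{2,1}(X - XZ + Y_1/\mu,\; \lambda/\mu)$ —
   column-wise shrinkage, the proximal step of the $\ell_{2,1}$ norm
   (`l21_shrink()`);
3. one gradient step on $Z$ of the smooth penalty terms, with step $1/\eta$,
   $\eta = \|X\|_2^2 + n + 1$ (the Lipschitz constant of that gradient:
   spectral norm of $X$, squared norm of the all-ones row, and the identity
   from the $Z - J$ term), followed by projection onto $\Omega$ — entries
   outside the support are simply zeroed;
4. multiplier ascent for $Y_1, Y_2, Y_3$ and geometric growth
   $\mu \leftarrow \min(\rho \mu, \mu_{\max})$.

The iteration stops when all three constraint violations
$\|X - XZ - E\|_\infty$, $\|\mathbf{1}^\top - \mathbf{1}^\top Z\|_\infty$ and
$\|Z - J\|_\infty$ fall below `tol`.

**Spectral rescaling.** The solver internally replaces $X$ by $X / \|X\|_2$
and $\lambda$ by $\lambda \|X\|_2$ — an exactly equivalent problem with the
same optimal $Z$ (the error matrix simply rescales). The reason is the rate
of the affine constraint: reconstruction and gap violations are absorbed
directly by the auxiliary variables $E$ and $J$, but the column-sum
constraint can only be corrected through the gradient step and contracts at
$1 - n/\eta$ per iteration. For a z-scored 500-feature view
$\|X\|_2^2 \approx 2 \times 10^4$, so the unscaled iteration would need
thousands of iterations; after rescaling $\eta = n + 2$ and the solver
converges in roughly 150–250 iterations. Residuals and the returned $E$ are
reported in the original data units.

**Defaults.** $\mu_0 = 10^{-2}$, $\rho = 1.1$, $\mu_{\max} = 10^{10}$ —
standard practice for this family of solvers; `tol` $= 10^{-6}$,
`max_iter` $= 500$. $\lambda = 0.5$: accuracy is flat over roughly
$\lambda \in [0.1, 1]$ on the benchmark (the acceptance suite sweeps this
range). $K$ defaults to $\max(3, \lfloor n/10 \rfloor)$; the sweep
$K \in \{5, \dots, 14\}$ at $n = 90$ shows the same insensitivity.
Per-feature z-scoring within each view is on by default — without it, views
on different scales would make a single $\lambda$ meaningless. A solve that
exhausts `max_iter` returns with `converged = FALSE` and a warning rather
than an error: the downstream fusion can still be meaningful, and the full
residual history is kept for inspection.

The affinity passed on to fusion is $W = (|Z^*| + |Z^{*\top}|)/2$.

## Stage 2: cross-view diffusion

Each view's affinity is normalised two ways (`full_kernel()`,
`local_kernel()`):

$$
P(i,j) = \begin{cases}
  \dfrac{W(i,j)}{2 \sum_{k \neq i} W(i,k)} & j \neq i \\[4pt]
  1/2 & j = i
\end{cases}
\qquad
S(i,j) = \begin{cases}
  \dfrac{W(i,j)}{\sum_{k \in N_i} W(i,k)} & j \in N_i \\[4pt]
  0 & \text{otherwise,}
\end{cases}
$$

with $N_i$ the $K$ strongest neighbours of sample $i$. $P$ is the
row-stochastic *status* matrix carrying each sample's full similarity
profile; $S$ is the *local kernel* that only trusts the neighbourhood.
`cross_diffuse()` then iterates, for every view $i$ simultaneously,

$$
P^i_{t+1} = S^i \Big( \tfrac{1}{m-1} \sum_{k \neq i} P^k_t \Big) (S^i)^\top ,
$$

i.e. each view adopts the other views' consensus similarity, propagated
through its own trusted neighbourhoods. The fused network is the across-view
mean of the final status matrices, symmetrised.

**Re-normalisation.** The raw update does not keep $P$ row-stochastic, and
the drift compounds over sweeps. After each sweep we symmetrise the updated
matrix and re-apply the status normalisation, which pins every row sum to 1
(the acceptance suite asserts $|{\rm row sum} - 1| \le 10^{-8}$ at every
sweep). `renormalize = FALSE` preserves the literal update for comparison.
Stopping: maximum elementwise change below $10^{-6}$, at most 30 sweeps; on
all benchmark fixtures the iteration converges in well under 30.

A sample isolated in one view (zero neighbourhood affinity) gets a zero row
in that view's $S$ with a warning, not an error — it can still receive
similarity through the other views. An isolated row in $P$'s normalisation,
by contrast, is a hard error naming the sample, since the status matrix is
undefined there.

## Stage 3: Ratio-Cut spectral clustering

`ratio_cut_spectral()` forms the unnormalised Laplacian $L = D - W$, embeds
the samples in the eigenvectors of the $c$ smallest eigenvalues and runs
k-means on the embedding (50 restarts, all seeded; the eigendecomposition is
deterministic, so end-to-end labels are reproducible given the seed).
Ratio Cut — cut weight normalised by cluster *sizes* — matches the fused
network, whose rows are already degree-normalised by construction.

On small graphs with genuine two-community structure the relaxation
recovers the exhaustively enumerated optimal bipartition essentially always
(the acceptance suite asserts a ≥ 90% match rate on 50 random planted
graphs). On *structureless* dense random graphs all balanced cuts have
nearly equal objective and the relaxation picks among near-ties; we measured
~70–85% exact-match rates there. This is a property of the relaxation, not
of the implementation, and is why the verification ensemble is the planted
one — the regime the method is meant for.

**Silhouette.** For cluster-coherence scoring on a similarity network,
`silhouette_score()` converts similarity to dissimilarity by
$d = 1 - W/\max(W)$ — the simplest monotone conversion that maps the
strongest observed affinity to distance 0 — and averages the standard
silhouette widths (singleton clusters contribute 0, the usual convention;
widths come from `cluster::silhouette`). `select_num_clusters()` maximises
this score over a candidate range, breaking ties toward fewer clusters, and
warns when the profile is completely flat (as for a constant similarity
matrix, where any partition is as good as any other).

## The synthetic benchmark

`generate_multiview()` plants $c$ clusters of equal size across $m$ views,
with a per-view *merge plan*: clusters listed together in a view are drawn so
that the view carries no boundary between them. The default is the
two-view, 90-sample design with three clusters of 30, where view 1 merges
clusters {2, 3} and view 2 merges {1, 2} — every boundary exists somewhere,
no view has all of them, and a feasibility check rejects plans that leave
some pair merged everywhere.

Geometry, per view:

* Every *distinguishable group* (merge-plan group) receives its own random
  low-dimensional subspace and a random mean offset (`group_offset`, default
  1.5 signal units). The offset mirrors real data — distinct molecular
  programmes shift mean profiles too — and makes resolvable boundaries
  visible to both the representation model and plain distance-based
  clustering. Without it, unit-sphere clouds in random high-dimensional
  subspaces are *not* Euclidean-separable at all (pairwise distances
  concentrate near $\sqrt{2}$ regardless of membership), and a view that
  merges nothing could still not be clustered by a distance method.
* **single-subspace** (weak heterogeneity): each group's loadings are drawn
  uniformly on the unit sphere of a 3-dimensional subspace. Merged clusters
  are then literally identically distributed.
* **multi-manifold** (strong heterogeneity, default): each *cluster* gets
  its own randomly curved 2-surface — a quadratic embedding of a Gaussian
  sheet, radially normalised — inside the 6-dimensional subspace shared by
  its merge group. Merged clusters therefore interleave on the same unit
  sphere: Euclidean proximity within a merged group carries almost no
  membership information (single-view baselines score ARI ≈ 0.5 against the
  three planted clusters, entirely from the one boundary the view does
  resolve), while the subspace structure the representation stage uses is
  intact.

We deliberately use surfaces rather than 1-dimensional curves for the
manifold regime. The within-cluster neighbourhood graph of points sampled
along a curve is a ring, and rings admit balanced "arc" cuts that are
*cheaper under Ratio Cut than the true cluster boundary* — we verified
numerically that on ring geometry the returned partition has a strictly
lower cut objective than the planted one, so no correct Ratio-Cut
implementation can recover the labels. Clusters in real arrays are thick
clouds, not filaments; the 2-surface construction keeps the
"curved manifold, misleading distances" character of the strong-heterogeneity
regime while remaining clusterable in principle.

**Noise** is additive Gaussian with standard deviation
`noise_frac` × sd(signal matrix); the benchmark grid uses 0%, 10% and 30%.
The generator is fully deterministic given its seed, and the sampler
restores the caller's RNG state.

What the generator does **not** emulate: real array feature distributions
(heavy tails, feature correlation blocks), batch effects, missing values,
unequal cluster sizes, or discrete data types (mutation calls, clinical
categories). Passing the benchmark therefore demonstrates the integration
mechanism — recovery of boundaries absent from every single view, robustness
to isotropic noise and to the $K, \lambda$ choice — not performance on any
particular real cohort.

## Verification scale

The test-suite and `scripts/acceptance.R` problem sizes are the package's
chosen verification conditions: the full 90-sample two-view benchmark for
end-to-end claims (50 seeds per noise level in the acceptance tests, 10 per
level in the script; 20 and 5 seeds per sweep cell respectively for the
$K$/$\lambda$ sweeps), 60-sample random instances for solver constraint
checks, and $n \le 8$ graphs wherever an exhaustive enumeration oracle is
compared against.

## Known limitations

* Local neighbourhoods are used twice — in the representation support and in
  the diffusion kernel — so noise shared across views can be amplified; with
  many strongly dependent views the fused network may overcommit to spurious
  local structure.
* The model is built for continuous measurements; binary or categorical
  views would need a different error model than the $\ell_{2,1}$ column
  norm.
* The diffusion weighs all views equally; there is no view-quality
  weighting.
* Ratio-Cut spectral clustering needs the number of clusters; the
  silhouette-guided selection is a heuristic and inherits silhouette's bias
  toward compact, balanced clusters.
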