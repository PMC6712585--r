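# msca — multi-view subspace clustering of multi-omics sample profiles

`msca` stratifies samples that have been profiled by two or more omics
platforms (expression + copy number, expression + methylation, …) into
integrated subgroups, including subgroups whose boundaries are invisible to
every single platform on its own.

It is aimed at analysts doing integrative clustering of matched omics
matrices — cancer subtyping, cell-line panels, any cohort where each data
type resolves only part of the sample structure — and at methods developers
who need a self-contained multi-view benchmark with planted ground truth.

## The method

Three stages, each exposed as ordinary functions:

1. **Per-view subspace representation.** For each view `X` (features ×
   samples) solve

   ```
   min ||Z||* + λ ||E||_{2,1}   s.t.   X = XZ + E,  Zᵀ1 = 1,  Z_ij = 0 for (i,j) ∉ Ω
   ```

   by a linearized ADMM with adaptive penalty (`solve_lrr()`), where Ω
   restricts each sample's representers to its K nearest neighbours. The
   nuclear norm pushes the coefficient matrix `Z` toward block-diagonal
   structure across sample subspaces; the locality constraint lets it follow
   curved manifolds; the `l2,1` error absorbs whole outlying samples. The
   view's affinity is `W = (|Z*| + |Z*ᵀ|)/2`.

2. **Cross-view diffusion** (`cross_diffuse()`). Affinities are normalised
   into row-stochastic status matrices `P` and K-NN local kernels `S`, then
   iterated as `P_i ← S_i (mean of other views' P) S_iᵀ` until the views
   agree; the fused network is the across-view mean, symmetrised.

3. **Ratio-Cut spectral clustering** (`ratio_cut_spectral()`): k-means on
   the eigenvectors of the `c` smallest eigenvalues of the unnormalised
   Laplacian `L = D − W`.

Evaluation helpers: `adjusted_rand_index()`, `silhouette_score()`,
`select_num_clusters()`, `single_view_ceiling()`; the benchmark generator is
`generate_multiview()` / `synthetic_spec()`. See the methods vignette
(`vignettes/msca-methods.Rmd`) for the full model, defaults and design
rationale.

## Worked example

Two simulated views over the same 90 samples, three planted clusters of 30;
view 1 cannot separate clusters 2 and 3, view 2 cannot separate 1 and 2, and
10% Gaussian noise is added:

```r
library(msca)
ds <- generate_multiview(synthetic_spec(seed = 42, noise_frac = 0.1))
ds
#> <multiview_dataset> 90 samples, 3 planted clusters, 2 views (multi-manifold), noise 10%

fit <- run_msca(ds, num_clusters = 3, seed = 42)
fit
#> <msca_result> 2 views fused over 90 samples
#> <clustering_result> 90 samples in 3 clusters (sizes: 30, 30, 30)

adjusted_rand_index(fit$clustering, ds$true_labels)
#> [1] 1
single_view_ceiling(ds, 1, seed = 42)
#> [1] 0.4949481
single_view_ceiling(ds, 2, seed = 42)
#> [1] 0.5496702

fit$solutions[[1]]
#> <lrr_solution> 90 samples, converged after 180 iterations
#>   final residuals: reconstruction 2.24e-07, affine 9.45e-07, gap 1.14e-08
```

Each view alone plateaus around ARI 0.5 — exactly the one boundary it
carries — while the fused network recovers the full partition (ARI 1). Real
data go in as TSV matrices via `read_view()` or directly through
`run_msca(list("expr.tsv", "cnv.tsv"), ...)`, which reconciles sample order
by identifier and writes labels, the fused network and the resolved
configuration when `out_dir` is given.

A thin command-line wrapper with `run`, `simulate` and `evaluate`
subcommands is installed at `inst/cli/msca.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "msca.R", package = "msca"))')" \
    run --views expr.tsv,cnv.tsv --clusters 3 --seed 0 --out results/
```

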