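# riemconn

Structure–function mapping of brain connectomes under the affine-invariant
Riemannian geometry of symmetric positive definite (SPD) matrices.

## What problem this solves, and for whom

Given a cohort of subjects with a **structural connectome** `S_k` (a
symmetric nonnegative weighted adjacency between `M` brain regions,
typically from diffusion-MRI tractography) and a **functional connectome**
`F_k` (the Pearson correlation matrix of the regions' resting-state
signals), one wants a single mapping `f` minimizing

    L(f) = (1/K) Σ_k d²(f(S_k), F_k).

Full-rank correlation matrices are SPD, and SPD matrices live on a curved
manifold, not in a vector space. `riemconn` does the whole pipeline —
loss, benchmark, model fitting and evaluation — under the affine-invariant
Riemannian distance

    d²(A, B) = Tr log²(A^{-1/2} B A^{-1/2}),

rather than the Frobenius norm. It is aimed at connectomics researchers
benchmarking structure–function models, and more generally at anyone
fitting matrix-valued predictors of covariance/correlation targets.

The package provides:

* **SPD geometry**: the affine-invariant distance, matrix powers/log/exp,
  the iterative Fréchet (Karcher) mean `F̄_{t+1} = F̄^{1/2} exp((1/K) Σ
  log(F̄^{-1/2} F_k F̄^{-1/2})) F̄^{1/2}`, SPD validation/repair.
* **Eigenmode mappings**: the unified family
  `f(S) = Σ_n g(λ_n) h(u_n) + C` with five instantiations — heat kernel
  `e^{-θL}`, affine diffusion `a e^{-αL} + bI`, matrix polynomial
  `Σ a_m S^m`, rotated spectral mapping `R Q g(Σ) Qᵀ Rᵀ`, and the latter
  plus a constant symmetric matrix (degrees of freedom 1, 3, P+1,
  P+1+M(M−1)/2, and +C respectively).
* **Fitting**: block coordinate descent on the cohort Riemannian loss —
  BFGS for the spectral weights, a skew-symmetric retraction for the
  rotation (stays exactly on SO(M)), the symmetric-matrix space for the
  constant — with a compiled inner loss.
* **Prediction**: fitted mappings, the Riemannian/Euclidean mean
  references, and the nearest-structural-neighbors Riemannian mean
  (`nn_mean_predict`, the Fréchet mean of the `P` structurally closest
  training subjects).
* **Evaluation**: pairwise distance matrices under both metrics,
  nearest-neighbor agreement, z-scored structure-vs-function distance
  regression (R²), and leave-one-out cross-validated mean squared
  Riemannian distance (MSD) per model.
* **Synthetic cohorts**: a generator with known ground-truth mapping and
  tangent-space (manifold-respecting) noise, so everything is testable
  without any imaging data.

## Worked example

Generate a synthetic cohort whose functional matrices really are produced
from structure (by a rotated spectral mapping with constant, order 2) plus
tangent-space noise, then ask whether the geometry sees the coupling and
whether fitting the matched family beats the structure-blind mean:

```r
library(riemconn)

sp <- synthetic_spec(M_regions = 10, K_subjects = 10,
                     true_family = "spectral_rotation_constant", order = 2L,
                     noise_sigma = 0.1, subject_jitter = 0.3, seed = 1)
g <- generate_cohort(sp)
g$cohort
#> Connectome cohort: 10 subjects, 10 regions
#>   subjects: sub-01, sub-02, sub-03, sub-04, sub-05 ...

Ds <- pairwise_distances(g$cohort$structurals, "euclidean")
Df <- pairwise_distances(g$cohort$functionals, "riemannian")
De <- pairwise_distances(g$cohort$functionals, "euclidean")
s <- distance_summary(Df)
# pairwise Riemannian distances: 1.58 +/- 0.16 (range 1.26-1.94)
distance_regression(Ds, Df)
#> [1] 0.1845797
nn_agreement(nearest_neighbors(Df), nearest_neighbors(De))   # out of 10
#> [1] 7

fit <- fit_mapping("spectral_rotation_constant", g$cohort, order = 2)
fit
#> Fitted eigenmode mapping 'spectral_rotation_constant'
#>   loss: 2.26415 -> 0.985885 over 3 outer iteration(s)

rep <- loocv_evaluate(list(list(model = "spectral_rotation_constant", order = 2),
                           "euclidean_mean", list(model = "nn_mean", P = 5)),
                      g$cohort)
rep
#> Leave-one-out evaluation: 10 subjects, 10 regions
#> Mean squared Riemannian test distance (MSD) per model:
#>                          model      msd n_folds n_failed
#>  spectral_rotation_constant_P2 1.286690      10        0
#>                riemannian_mean 1.389636      10        0
#>                 euclidean_mean 1.421783      10        0
#>                     nn_mean_P5 1.484937      10        0
```

Reading the output: the between-subject Riemannian distances are tightly
distributed (1.58 ± 0.16); structurally similar subjects have measurably
similar functional matrices (R² ≈ 0.18 on z-scored distance pairs, 45
pairs); the two metrics disagree on 3 of 10 nearest neighbors even on this
small cohort; and in leave-one-out evaluation the matched mapping family
(MSD 1.29) outperforms the Riemannian Fréchet mean (1.39), which in turn
beats the arithmetic mean (1.42) — the in-metric benchmark ordering the
whole package is built around. MSD units are squared Riemannian distances
at this cohort size and are not comparable across `M`.

Real data enters through delimited-text matrices and a YAML manifest
(`load_cohort()`, `pearson_functional()` for raw parcel time series); a
thin command-line front end with `simulate` / `fit` / `predict` /
`evaluate` subcommands is installed at `inst/cli/riemconn`.

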