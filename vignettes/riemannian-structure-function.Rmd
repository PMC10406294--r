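---
title: "Structure-function mapping of connectomes on the SPD manifold"
author: "riemconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function mapping of connectomes on the SPD manifold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riemconn)
```

## The problem

A structural connectome $S_k$ is a weighted graph of white-matter
connections between $M$ brain regions, estimated from diffusion-MRI
tractography; a functional connectome $F_k$ is the matrix of Pearson
correlations between the regions' resting-state BOLD signals.
Structure-function mapping asks for a single function $f$ such that
$f(S_k) \approx F_k$ across a cohort of $K$ subjects:

$$ \mathcal{L}(f) = \frac{1}{K}\sum_{k=1}^{K} d^2\!\big(f(S_k),\, F_k\big). $$

The choice of $d$ matters more than it looks. A full-rank correlation
matrix of $T > M$ linearly independent signals is symmetric positive
definite (SPD), and SPD matrices form a convex half-cone inside the vector
space of symmetric matrices, not a vector space of their own. The
Frobenius distance treats them elementwise and ignores this geometry.
`riemconn` instead works throughout with the affine-invariant Riemannian
distance

$$ d^2(A, B) = \operatorname{Tr}\,\log^2\!\big(A^{-1/2} B A^{-1/2}\big), $$

which is invariant under congruence $A \mapsto XAX^\top$ for any invertible
$X$ and under joint inversion, and which sends matrices with non-positive
eigenvalues infinitely far away -- matching the intuition that they are not
valid functional connectomes.

## Reference model: the Fréchet mean

A mapping is only interesting if it beats a structure-blind predictor. The
natural benchmark in this metric is the Fréchet (Karcher) mean
$\bar F = \arg\min_X \sum_k d^2(X, F_k)$, which is unique on the SPD
manifold. `frechet_mean_riemannian()` computes it with the fixed-point
iteration

$$ \bar F_{t+1} = \bar F_t^{1/2}\,
   \exp\!\Big(\tfrac1K \sum_k \log\big(\bar F_t^{-1/2} F_k \bar F_t^{-1/2}\big)\Big)\,
   \bar F_t^{1/2}, $$

initialized at the arithmetic mean (always SPD for SPD inputs, cheap, and
empirically within a few iterations of the fixed point). The stopping rule
is ours, since the iteration itself does not prescribe one: we stop when
the Frobenius norm of the averaged tangent term -- the Riemannian gradient
of the objective up to a factor -- drops below `tol` (default `1e-8`,
`max_iter = 200`). The arithmetic mean `frechet_mean_euclidean()` is kept
as the Euclidean reference.

## The eigenmode mapping family

All mappings implemented here share the unified eigenmode form

$$ f(S) = \sum_{n=0}^{M-1} g(\lambda_n)\, h(u_n) + C, $$

where $(\lambda_n, u_n)$ are the eigenpairs of the mapping input (the
structural matrix, or its symmetric normalized Laplacian
$L = I - D^{-1/2} S D^{-1/2}$ for the diffusion families), $g$ reweights
eigenvalues, $h(u_n) = R\, u_n u_n^\top R^\top$ optionally rotates the
eigenvector frame, and $C$ is a constant symmetric matrix. The five
concrete families:

| family | form | free parameters |
|---|---|---|
| `heat_kernel` | $e^{-\theta L}$ | 1 |
| `diffusion_affine` | $a e^{-\alpha L} + b I$ | 3 |
| `polynomial` | $\sum_{m=0}^{P} a_m S^m$ | $P+1$ |
| `spectral_rotation` | $R\, Q\, g(\Sigma)\, Q^\top R^\top$ | $P+1+\binom{M}{2}$ |
| `spectral_rotation_constant` | above $+\,C$ | $P+1+\binom{M}{2} + C$ |

Notes on conventions adopted where the family definitions leave slack:

* The heat kernel's rate and time are not separately identifiable, so they
  are merged into a single $\theta$; this matches the single degree of
  freedom of that family.
* Every $g$ is evaluated on the spectrum (through one symmetric
  eigendecomposition) rather than by repeated matrix multiplication:
  identical by the spectral theorem and numerically stabler at order 6.
* The constant $C$ is constrained symmetric. The conventional
  degrees-of-freedom count for that family charges a full $M^2$ block;
  `degrees_of_freedom()` returns that count and attaches the constrained
  count $M(M+1)/2$ as an attribute, since both are defensible.
* Eigenvector signs are fixed (largest-magnitude component positive) so
  that rotation fits are reproducible; the predictions themselves are
  sign-invariant.

## Fitting: block coordinate descent under congruence

The cohort loss with the Riemannian distance,
$\mathcal{L} = \frac1K \sum_k \operatorname{Tr} \log^2\big(F_k^{-1/2} f(S_k) F_k^{-1/2}\big)$,
is minimized by cycling over three parameter blocks
(`fit_mapping()`, default `outer_iterations = 3`):

1. **eigenvalue weights** ($\theta$, $(a,\alpha,b)$, or $a_0 \dots a_P$):
   BFGS (`stats::optim`) with central finite differences (step `1e-6`).
   The analytic gradient through the matrix logarithm is error-prone and
   the block is small, so numerical gradients are the pragmatic choice.
2. **rotation** (spectral families): BFGS over the skew-symmetric
   generator $w$ of the retraction $R \leftarrow R_0 \exp(\mathrm{skew}(w))$,
   which stays exactly on the rotation group; the accumulated product is
   re-projected to its polar factor after each accepted step to remove
   floating-point drift.
3. **constant** (`spectral_rotation_constant`): BFGS over the
   $M(M+1)/2$ free entries of $C$.

A block update is accepted only if it does not increase the loss, so the
loss trajectory is non-increasing by construction; three outer rounds
typically change the loss by well under 1% thereafter, and the `converged`
flag records exactly that. The per-subject congruence
$F_k^{-1/2}(\cdot)F_k^{-1/2}$ and the eigendecomposition of each mapping
input are precomputed once per fit; the inner loss is evaluated in
compiled code since a single fit may require tens of thousands of
evaluations.

Initialization is a nested warm start: weights start at the identity
prediction ($\theta = 1$ for the heat kernel, $(1, 1, 0)$ for the affine
diffusion, $a = (1, 0, \dots)$ for the polynomial families -- i.e.
$g \equiv 1$, $f(S) = QQ^\top = I$, which is always SPD), the rotation at
$I$ and the constant at $0$, so every spectral family begins exactly where
the polynomial family begins.

**Keeping predictions on the manifold.** Nothing constrains an arbitrary
eigenmode prediction to be SPD (the heat kernel always is; the others are
not in general). Rejecting such iterates would make the search
discontinuous, so instead eigenvalues below a relative floor are clipped
to it and the loss is augmented by `spd_penalty` (default `1e3`) times the
average clipped mass. The floor is `1e-10 * trace/M` -- scale-free, so
well-conditioned correlation matrices of any magnitude pass -- with a
small absolute guard for transient iterates with non-positive trace.

## Nearest-structural-neighbors mean

`nn_mean_predict()` implements the geometry-aware predictor suggested by
the observed correlation between structural and functional between-subject
distances: predict a new subject's functional matrix as the Riemannian
Fréchet mean of the $P$ training subjects with the closest structural
connectomes. With $P = K$ it degenerates to the plain Fréchet-mean
reference. Structural connectomes have zero diagonal and are not SPD, so
"closest" defaults to the Frobenius distance; a `"riemannian"` option
applies the affine-invariant distance after a shared diagonal shift of
twice the larger maximum weighted degree (a Gershgorin bound, which makes
both matrices SPD). Neither choice is canonical -- the metric on the
structural side is genuinely an open choice, which is why it is an
exposed option rather than a fixed rule.

## Leave-one-out evaluation

`loocv_evaluate()` scores any set of models -- mapping families, the two
mean references, the NN mean -- by leave-one-out cross-validation: fit on
$K-1$ subjects, predict the held-out functional matrix, record the squared
Riemannian distance to the observation; the per-model mean of these is the
MSD. The Riemannian mean is always included as the benchmark. Fold
failures are recorded per fold rather than aborting the run. No
significance test between model MSDs is computed; the per-fold distances
are in the report so users can apply whichever paired test they prefer.
`distance_regression()` z-scores the $K(K-1)/2$ upper-triangle distance
pairs (sample SD) and returns the squared Pearson correlation; the
z-scoring makes the value invariant to affine rescaling of either
distance.

## The synthetic cohort generator

Real cohorts of paired tractography/fMRI connectomes cannot be bundled, so
`generate_cohort()` builds cohorts with *known* ground truth:

* **Structure.** A group-template weighted graph: Erdős–Rényi support at
  `graph_density` (default 0.3) made connected by a random spanning tree,
  lognormal edge weights, then per-subject lognormal edge jitter of
  log-scale `subject_jitter` before the standard
  symmetrize-and-normalize step. This emulates a homogeneous healthy
  cohort sharing one anatomical backbone.
* **Function.** $F_k = F_0^{1/2} e^{E} F_0^{1/2}$ where
  $F_0 = f^*(S_k)$ is the ground-truth mapping's prediction and $E$ is
  symmetric with i.i.d. $N(0, \sigma^2)$ entries. The perturbation acts in
  the tangent space at $F_0$, so $F_k$ is SPD *by construction* and
  $d(F_k, F_0) = \lVert E \rVert_F$ exactly, giving the closed form
  $\mathbb{E}\,d^2 = \sigma^2 M^2$ that the tests check by Monte Carlo.
  Elementwise noise would leave the cone and require ad-hoc repair,
  breaking the very geometry under test.

Default ground truths: $\theta^* = 0.5$ (heat kernel),
$(a, \alpha, b)^* = (1.2, 0.8, 0.1)$ (affine diffusion), and order-2
spectral weights $(1, 5, 10)$ -- positive over the eigenvalue range of a
unit-mass structural matrix, hence SPD noiseless predictions. Rotation
truths are drawn as $\exp(\mathrm{skew}(w))$, $w \sim N(0, 0.2^2)$, and
constants as small random symmetric matrices ($N(0, 0.05^2)$ entries).
Defaults `noise_sigma = 0.05` and `subject_jitter = 0.1` represent
low-noise conditions under which structure-function coupling is clearly
detectable; the stress conditions used in the coupling analyses are
$\sigma = 0.1$, jitter $= 0.3$.

What the generator does **not** emulate: functional matrices are not
rescaled to unit diagonal (that projection leaves the geodesic framework
and would break exact recovery tests; a correlation-like appearance can be
obtained downstream if needed), there is no hemispheric or modular block
structure, no BOLD autocorrelation, and structural noise is edgewise
lognormal rather than tractography-like. Passing tests therefore
demonstrate correctness of the geometry, the optimizer and the protocol --
not that any family is the right model for real brains.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes that keep every component nontrivial: $M = 10$–$15$ regions
(a rotation manifold of 45–105 dimensions), $K = 10$–$20$ subjects,
order-2 spectral truths, 10-seed medians for stochastic properties.
Metric axioms are exercised on 100 random SPD pairs, Laplacian spectral
bounds on 1000 random connected graphs. Published full-scale analyses of
this kind use hundreds of regions and ~100 subjects; nothing in the
implementation is specific to the small sizes, and the compiled loss keeps
order-6, 200-region fits feasible, but the distances and MSDs reported by
the bundled runs are on the desk scale and not comparable to
full-cohort magnitudes.

Numerical conventions collected in one place: symmetry is validated to a
relative `1e-10`; all matrix functions go through the symmetric
eigendecomposition; nearest-neighbor ties break to the lowest subject
index; the off-diagonal normalization of structural matrices divides by
the *full* off-diagonal sum (both triangles -- the alternative,
each-edge-once, only rescales every matrix by 2 and changes nothing
downstream); degrees for the Laplacian are row sums of the normalized
matrix, since the Laplacian is built from the normalized structural
connectome; no pruning or thresholding of weak connections is applied
anywhere.

## Known limitations

* The rotation block is a local search from the identity; for cohorts
  generated with a large true rotation the fit may land in a local
  optimum. The nesting guarantee (richer families never fit worse, up to
  optimizer tolerance) still holds because of the warm start and
  monotone acceptance.
* Finite-difference gradients make a fit cost $O(\text{params})$ loss
  evaluations per BFGS iteration; at hundreds of regions an analytic or
  adjoint gradient would be the next step.
* A single shared mapping is fitted across subjects; per-subject mappings
  are deliberately out of scope.
* Borderline positive-semidefinite empirical functional matrices (e.g.
  from short or scrubbed time series) must be explicitly repaired
  (`repair = TRUE` in `pearson_functional()` / `assert_spd()`); the
  package will not silently regularize data it reads.
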