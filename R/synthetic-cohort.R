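#' Specification of a synthetic connectome cohort
#'
#' Describes a cohort of paired structural/functional matrices generated
#' from a known ground-truth eigenmode mapping, emulating a resting-state
#' cohort: a shared weighted group graph with per-subject edge-weight
#' jitter stands in for individual tractography-derived connectomes, and
#' the functional matrix of each subject is the ground-truth mapping's
#' prediction perturbed along the SPD manifold (tangent-space noise), so
#' every generated functional matrix is exactly SPD.
#'
#' @param M_regions number of brain regions (matrix side).
#' @param K_subjects number of subjects.
#' @param graph_density edge probability of the group graph support in
#'   `(0, 1]`; connectivity is enforced by adding a random spanning tree.
#' @param true_family ground-truth mapping family from [mapping_families].
#' @param true_params optional explicit [mapping_params()] ground truth;
#'   when `NULL`, family defaults are used (see [true_mapping_params()]).
#' @param order polynomial order of the default ground truth for the
#'   polynomial/spectral families.
#' @param noise_sigma standard deviation of the independent entries of the
#'   symmetric tangent-space noise matrix (dimensionless; the expected
#'   squared Riemannian distance from the noiseless prediction is
#'   `noise_sigma^2 * M_regions^2`).
#' @param subject_jitter log-scale standard deviation of the per-subject
#'   lognormal edge-weight multipliers (between-subject structural
#'   variability).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(M_regions = 15L, K_subjects = 20L,
                           graph_density = 0.3, true_family = "heat_kernel",
                           true_params = NULL, order = 2L,
                           noise_sigma = 0.05, subject_jitter = 0.1,
                           seed = 1L) {
  true_family <- match.arg(true_family, mapping_families)
  stopifnot(M_regions >= 3, K_subjects >= 1,
            graph_density > 0, graph_density <= 1,
            noise_sigma >= 0, subject_jitter >= 0)
  if (!is.null(true_params)) stopifnot(inherits(true_params, "mapping_params"))
  structure(list(M_regions = as.integer(M_regions),
                 K_subjects = as.integer(K_subjects),
                 graph_density = graph_density, true_family = true_family,
                 true_params = true_params, order = as.integer(order),
                 noise_sigma = noise_sigma, subject_jitter = subject_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Ground-truth mapping parameters for a synthetic spec
#'
#' Returns `spec$true_params` when given, otherwise the family defaults:
#' `theta = 0.5` for the heat kernel, `(a, alpha, b) = (1.2, 0.8, 0.1)`
#' for the affine diffusion, and spectral weights `(1, 5, 10)` (order 2)
#' for the polynomial families -- positive over the eigenvalue range of a
#' unit-mass structural connectome, so the noiseless predictions are SPD.
#' For the rotation families the true rotation is drawn as
#' `expm(skew(w))`, `w ~ N(0, 0.2)`, and for the constant family a random
#' symmetric `C` with entries `N(0, 0.05)` is added; both draws consume
#' the current RNG stream ([generate_cohort()] seeds it).
#'
#' @param spec a [synthetic_spec()].
#' @return A [mapping_params()] object.
#' @export
true_mapping_params <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$true_params)) return(spec$true_params)
  M <- spec$M_regions
  fam <- spec$true_family
  if (fam == "heat_kernel") return(mapping_params(fam, 0.5))
  if (fam == "diffusion_affine") return(mapping_params(fam, c(1.2, 0.8, 0.1)))
  weights <- c(1, 5, 10)[seq_len(spec$order + 1)]
  if (spec$order > 2) weights <- c(weights, rep(0, spec$order - 2))
  rot <- NULL; cst <- NULL
  if (.family_has_rotation(fam))
    rot <- .orthogonalize(cpp_expm(.skew_from_vec(
      rnorm(M * (M - 1) / 2, sd = 0.2), M)))
  if (.family_has_constant(fam)) {
    cst <- matrix(rnorm(M * M, sd = 0.05), M, M)
    cst <- (cst + t(cst)) / 2
  }
  mapping_params(fam, weights, order = spec$order, rotation = rot, constant = cst)
}

# Group-template weighted graph plus per-subject jitter; consumes the RNG
# stream.
.generate_structural_impl <- function(spec) {
  M <- spec$M_regions
  n_pairs <- M * (M - 1) / 2
  support <- runif(n_pairs) < spec$graph_density
  # upper-triangle pair index in the same (column-major) order used when
  # scattering weights back into the matrix
  idx <- matrix(0L, M, M)
  idx[upper.tri(idx)] <- seq_len(n_pairs)
  # random spanning tree over a permuted node order guarantees connectivity
  perm <- sample.int(M)
  for (t in 2:M) {
    anchor <- perm[sample.int(t - 1, 1)]
    a <- min(anchor, perm[t]); b <- max(anchor, perm[t])
    support[idx[a, b]] <- TRUE
  }
  w <- numeric(n_pairs)
  w[support] <- rlnorm(sum(support), meanlog = 0, sdlog = 1)
  ut <- upper.tri(matrix(0, M, M))
  lapply(seq_len(spec$K_subjects), function(k) {
    jit <- numeric(n_pairs)
    jit[support] <- rlnorm(sum(support), meanlog = 0, sdlog = spec$subject_jitter)
    Wk <- matrix(0, M, M)
    Wk[ut] <- w * jit
    symmetrize_normalize(Wk)
  })
}

#' Generate the structural connectomes of a synthetic cohort
#'
#' Draws a group-template weighted graph (random connected support at
#' `graph_density` with lognormal edge weights), multiplies each subject's
#' edge weights by independent lognormal jitter of log-scale
#' `subject_jitter`, and normalizes each matrix through
#' [symmetrize_normalize()]. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return List of `K_subjects` structural connectomes.
#' @export
generate_structural <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  .generate_structural_impl(spec)
}

# Tangent-space perturbation at the base prediction; consumes the RNG
# stream.
.perturb_spd <- function(F0, sigma) {
  if (sigma == 0) return(F0)
  M <- nrow(F0)
  E <- matrix(0, M, M)
  E[upper.tri(E)] <- rnorm(M * (M - 1) / 2, sd = sigma)
  E <- E + t(E)
  diag(E) <- rnorm(M, sd = sigma)
  half <- spd_power(F0, 1/2)
  out <- half %*% sym_exp(E) %*% half
  (out + t(out)) / 2
}

#' Generate one synthetic functional matrix
#'
#' The ground-truth mapping's prediction for `S`, perturbed by
#' tangent-space noise: `F = F0^{1/2} exp(E) F0^{1/2}` with `E` a random
#' symmetric matrix whose independent entries (diagonal and off-diagonal)
#' have standard deviation `noise_sigma`. Because the perturbation acts
#' through the matrix exponential at the base point, the output is SPD by
#' construction and `d(F, F0) = ||E||_F` exactly under the
#' affine-invariant distance. Consumes the current RNG stream; seed it
#' yourself or use [generate_cohort()].
#'
#' @param S structural connectome.
#' @param spec a [synthetic_spec()].
#' @param params ground-truth [mapping_params()]; defaults to
#'   [true_mapping_params()] of the spec.
#' @return An SPD functional matrix.
#' @export
generate_functional <- function(S, spec, params = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(params)) params <- true_mapping_params(spec)
  F0 <- apply_mapping(params, mapping_input(S, params$family))
  F0 <- assert_spd(F0, repair = TRUE)
  if (attr(F0, "clipped_mass") > 0.01 * sum(diag(F0)))
    stop("ground-truth prediction is far from SPD; choose tamer true_params",
         call. = FALSE)
  attr(F0, "clipped_mass") <- NULL
  .perturb_spd(F0, spec$noise_sigma)
}

#' Generate a full synthetic cohort with known ground truth
#'
#' Composes [generate_structural()], [true_mapping_params()] and
#' [generate_functional()] under `spec$seed`. Optionally writes the cohort
#' (manifest plus per-subject CSVs) and the ground-truth parameters to
#' `dir`, round-trippable through [load_cohort()] and
#' [read_mapping_params()].
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory.
#' @return A list with `cohort` (a [cohort()]) and `ground_truth` (the
#'   [mapping_params()] used).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  Ss <- generate_structural(spec)           # seeds the stream
  params <- true_mapping_params(spec)
  Fs <- lapply(Ss, generate_functional, spec = spec, params = params)
  ids <- sprintf("sub-%02d", seq_len(spec$K_subjects))
  ch <- cohort(ids, Ss, Fs)
  if (!is.null(dir)) {
    save_cohort(ch, dir)
    write_mapping_params(params, file.path(dir, "ground_truth.yaml"))
  }
  list(cohort = ch, ground_truth = params)
}
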