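#' @useDynLib riemconn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor optim rbinom rlnorm rnorm runif sd
#' @importFrom utils head
NULL

# Relative symmetry tolerance shared by all validators.
.sym_tol <- 1e-10

.check_square <- function(A, arg = "A") {
  if (!is.matrix(A) || !is.numeric(A) || nrow(A) != ncol(A))
    stop(sprintf("'%s' must be a square numeric matrix", arg), call. = FALSE)
  if (anyNA(A)) stop(sprintf("'%s' contains missing values", arg), call. = FALSE)
  invisible(A)
}

.check_symmetric <- function(A, arg = "A") {
  .check_square(A, arg)
  scale <- max(abs(A))
  asym <- max(abs(A - t(A)))
  if (asym > .sym_tol * max(scale, 1e-300))
    stop(sprintf("'%s' is not symmetric: max asymmetry %.3e (scale %.3e)",
                 arg, asym, scale), call. = FALSE)
  invisible(A)
}

#' Relative positivity floor for SPD checks
#'
#' The smallest eigenvalue a matrix may have and still be treated as
#' symmetric positive definite (SPD). The floor is relative to the matrix
#' scale, `1e-10 * trace(A)/M`, so that well-conditioned correlation
#' matrices of any overall magnitude pass, guarded below by a small
#' absolute constant for matrices with non-positive trace.
#'
#' @param A square symmetric numeric matrix.
#' @return A positive scalar floor.
#' @export
spd_floor <- function(A) {
  .check_square(A)
  1e-10 * max(sum(diag(A)) / nrow(A), 1e-8)
}

#' Symmetric eigendecomposition with a fixed sign convention
#'
#' Eigendecomposition of a symmetric matrix with eigenvalues returned in
#' ascending order and each eigenvector's sign fixed so that its
#' largest-magnitude component is positive (first such component on ties).
#' The deterministic sign makes downstream rotation fits reproducible.
#'
#' @param A square symmetric numeric matrix.
#' @return A list with `values` (ascending numeric vector) and `vectors`
#'   (orthonormal matrix, columns matching `values`).
#' @export
sym_eig <- function(A) {
  .check_symmetric(A)
  e <- eigen(A, symmetric = TRUE)
  idx <- rev(seq_len(nrow(A)))              # eigen() returns descending
  vals <- e$values[idx]
  vecs <- e$vectors[, idx, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    v <- vecs[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) vecs[, j] <- -v
  }
  list(values = vals, vectors = vecs)
}

# Apply a scalar function to the spectrum of a symmetric matrix.
.spec_fun <- function(A, f) {
  e <- sym_eig(A)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

.check_spd_values <- function(vals, A, arg = "A") {
  fl <- 1e-10 * max(sum(vals) / length(vals), 1e-8)
  if (min(vals) <= fl)
    stop(sprintf("'%s' is not SPD: smallest eigenvalue %.3e <= floor %.3e",
                 arg, min(vals), fl), call. = FALSE)
  invisible(vals)
}

#' Matrix power of an SPD matrix
#'
#' Computes `A^p` through the symmetric eigendecomposition,
#' `U diag(lambda^p) U^T`. Supplies the `A^{1/2}` and `A^{-1/2}` factors
#' used throughout the affine-invariant geometry.
#'
#' @param A SPD matrix.
#' @param p real exponent.
#' @return A symmetric matrix; SPD whenever `A` is.
#' @export
spd_power <- function(A, p) {
  e <- sym_eig(A)
  .check_spd_values(e$values, A)
  e$vectors %*% (e$values^p * t(e$vectors))
}

#' Matrix logarithm of an SPD matrix
#'
#' @param A SPD matrix.
#' @return The symmetric matrix `log(A)`; inverse of [sym_exp()].
#' @export
spd_log <- function(A) {
  e <- sym_eig(A)
  .check_spd_values(e$values, A)
  e$vectors %*% (log(e$values) * t(e$vectors))
}

#' Matrix exponential of a symmetric matrix
#'
#' @param X symmetric matrix.
#' @return The SPD matrix `exp(X)`; inverse of [spd_log()].
#' @export
sym_exp <- function(X) {
  .spec_fun(X, exp)
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' The geodesic distance `d(A, B) = sqrt(Tr(log^2(A^{-1/2} B A^{-1/2})))`
#' induced by the affine-invariant metric on the SPD manifold. It is
#' invariant under congruence `A -> X A X^T` for any invertible `X`, and
#' under matrix inversion of both arguments.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return Nonnegative scalar distance.
#' @export
riemannian_distance <- function(A, B) {
  .check_square(A, "A"); .check_square(B, "B")
  if (nrow(A) != nrow(B))
    stop("dimension mismatch: ", nrow(A), " vs ", nrow(B), call. = FALSE)
  Aih <- spd_power(A, -1/2)
  e <- sym_eig(Aih %*% B %*% Aih)
  .check_spd_values(e$values, B, "B")
  sqrt(sum(log(e$values)^2))
}

#' Frobenius (Euclidean) distance between symmetric matrices
#'
#' @param A,B symmetric matrices of equal dimension.
#' @return Nonnegative scalar `||A - B||_F`.
#' @export
euclidean_distance <- function(A, B) {
  .check_square(A, "A"); .check_square(B, "B")
  if (nrow(A) != nrow(B))
    stop("dimension mismatch: ", nrow(A), " vs ", nrow(B), call. = FALSE)
  sqrt(sum((A - B)^2))
}

#' Riemannian Frechet (Karcher) mean of SPD matrices
#'
#' Minimizes the sum of squared affine-invariant distances to the given
#' matrices by the fixed-point iteration
#' \deqn{\bar F_{t+1} = \bar F_t^{1/2} \exp\Big(\frac1K \sum_k
#'   \log(\bar F_t^{-1/2} F_k \bar F_t^{-1/2})\Big) \bar F_t^{1/2},}
#' initialized at the arithmetic mean (always SPD for SPD inputs) and
#' stopped when the Frobenius norm of the averaged tangent term -- the
#' Riemannian gradient up to scale -- drops below `tol`.
#'
#' @param Fs list of SPD matrices of a common dimension.
#' @param tol convergence tolerance on the tangent-term Frobenius norm.
#' @param max_iter maximum number of fixed-point iterations.
#' @return The Frechet mean, an SPD matrix, with attributes `iterations`
#'   and `grad_norm` recording the termination state.
#' @export
frechet_mean_riemannian <- function(Fs, tol = 1e-8, max_iter = 200) {
  if (!is.list(Fs) || length(Fs) == 0) stop("'Fs' must be a nonempty list", call. = FALSE)
  K <- length(Fs)
  M <- nrow(Fs[[1]])
  for (k in seq_len(K)) {
    .check_square(Fs[[k]], sprintf("Fs[[%d]]", k))
    if (nrow(Fs[[k]]) != M) stop("matrices in 'Fs' differ in dimension", call. = FALSE)
  }
  Fbar <- frechet_mean_euclidean(Fs)
  gnorm <- Inf
  for (it in seq_len(max_iter)) {
    half <- spd_power(Fbar, 1/2)
    ihalf <- spd_power(Fbar, -1/2)
    Tan <- matrix(0, M, M)
    for (k in seq_len(K)) Tan <- Tan + spd_log(ihalf %*% Fs[[k]] %*% ihalf)
    Tan <- Tan / K
    Tan <- (Tan + t(Tan)) / 2
    gnorm <- sqrt(sum(Tan^2))
    if (gnorm <= tol) {
      attr(Fbar, "iterations") <- it - 1L
      attr(Fbar, "grad_norm") <- gnorm
      return(Fbar)
    }
    Fbar <- half %*% sym_exp(Tan) %*% half
    Fbar <- (Fbar + t(Fbar)) / 2
  }
  stop(sprintf(
    "Frechet mean did not converge after %d iterations (gradient norm %.3e)",
    max_iter, gnorm), call. = FALSE)
}

#' Euclidean (arithmetic) mean of matrices
#'
#' The arithmetic average, which minimizes the summed squared Frobenius
#' distance to the inputs; the reference group average when the Euclidean
#' metric is used.
#'
#' @param Fs nonempty list of matrices of a common dimension.
#' @return The elementwise mean matrix.
#' @export
frechet_mean_euclidean <- function(Fs) {
  if (!is.list(Fs) || length(Fs) == 0) stop("'Fs' must be a nonempty list", call. = FALSE)
  Reduce(`+`, Fs) / length(Fs)
}

#' Validate (and optionally repair) positive definiteness
#'
#' Checks that a symmetric matrix is SPD relative to [spd_floor()]. With
#' `repair = TRUE`, eigenvalues below the floor are clipped to it and the
#' matrix reconstructed; the total clipped eigenvalue mass is attached as
#' attribute `clipped_mass`.
#'
#' @param A symmetric matrix.
#' @param repair clip offending eigenvalues instead of erroring?
#' @return An SPD matrix (the input, unchanged, when already SPD) with
#'   attribute `clipped_mass`.
#' @export
assert_spd <- function(A, repair = FALSE) {
  .check_symmetric(A)
  e <- sym_eig(A)
  fl <- 1e-10 * max(sum(e$values) / length(e$values), 1e-8)
  below <- e$values < fl
  if (!any(below)) {
    attr(A, "clipped_mass") <- 0
    return(A)
  }
  if (!repair)
    stop(sprintf("matrix is not SPD: smallest eigenvalue %.3e <= floor %.3e",
                 min(e$values), fl), call. = FALSE)
  clipped <- sum(fl - e$values[below])
  vals <- pmax(e$values, fl)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  attr(out, "clipped_mass") <- clipped
  out
}
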