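# Random objects used across test files. All draws consume the ambient RNG
# stream; tests seed it explicitly.

rand_sym <- function(M, sd = 1) {
  A <- matrix(rnorm(M * M, sd = sd), M, M)
  (A + t(A)) / 2
}

# Random orthogonal matrix (QR with positive-diagonal correction).
rand_orthogonal <- function(M) {
  qr_ <- qr(matrix(rnorm(M * M), M, M))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))))
}

# Random well-conditioned SPD matrix with eigenvalues in [exp(-spread), exp(spread)].
rand_spd <- function(M, spread = 1) {
  Q <- rand_orthogonal(M)
  Q %*% (exp(runif(M, -spread, spread)) * t(Q))
}

# Random invertible (generally non-orthogonal) matrix.
rand_invertible <- function(M) {
  repeat {
    X <- matrix(rnorm(M * M), M, M)
    if (abs(det(X)) > 1e-3) return(X)
  }
}

# Random proper rotation of a given angular scale.
rand_rotation <- function(M, scale = 0.3) {
  w <- rnorm(M * (M - 1) / 2, sd = scale)
  S <- matrix(0, M, M)
  S[upper.tri(S)] <- w
  S <- S - t(S)
  riemconn:::cpp_expm(S)
}

# Small deterministic cohort for fast fitting tests.
tiny_cohort <- function(M = 8, K = 6, family = "heat_kernel", sigma = 0.05,
                        jitter = 0.1, seed = 42, order = 2L) {
  sp <- synthetic_spec(M_regions = M, K_subjects = K, true_family = family,
                       noise_sigma = sigma, subject_jitter = jitter,
                       seed = seed, order = order)
  generate_cohort(sp)
}
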