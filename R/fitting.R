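#' Configuration for the coordinate-descent fit
#'
#' @param outer_iterations number of outer coordinate-descent rounds over
#'   the weight / rotation / constant blocks. Model performance typically
#'   stabilizes after about three rounds.
#' @param weight_maxit BFGS iteration cap for the eigenvalue-weight block.
#' @param manifold_maxit BFGS iteration cap for the rotation and constant
#'   blocks (optimized through the skew-symmetric retraction and the
#'   symmetric-matrix parameterization respectively).
#' @param fd_step central finite-difference step for numerical gradients.
#' @param reltol relative convergence tolerance passed to the inner BFGS.
#' @param spd_penalty additive penalty weight applied per unit of clipped
#'   eigenvalue mass when a prediction leaves the SPD cone.
#' @param seed integer seed stored with the configuration; the fit itself
#'   is deterministic, the seed is recorded so evaluation runs embedding
#'   stochastic steps stay reproducible.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(outer_iterations = 3L, weight_maxit = 200L,
                       manifold_maxit = 30L, fd_step = 1e-6,
                       reltol = 1e-12, spd_penalty = 1e3, seed = 1L) {
  stopifnot(outer_iterations >= 1, weight_maxit >= 1, manifold_maxit >= 1,
            fd_step > 0, spd_penalty >= 0)
  structure(list(outer_iterations = as.integer(outer_iterations),
                 weight_maxit = as.integer(weight_maxit),
                 manifold_maxit = as.integer(manifold_maxit),
                 fd_step = fd_step, reltol = reltol,
                 spd_penalty = spd_penalty, seed = as.integer(seed)),
            class = "fit_config")
}

# Precomputed per-cohort quantities the loss needs: eigendecomposition of
# each subject's mapping input and F_k^{-1/2}.
.loss_context <- function(ch, family) {
  Qs <- vector("list", ch$K); lams <- vector("list", ch$K)
  Fih <- vector("list", ch$K)
  for (k in seq_len(ch$K)) {
    X <- mapping_input(ch$structurals[[k]], family)
    e <- sym_eig(X)
    Qs[[k]] <- e$vectors; lams[[k]] <- e$values
    Fih[[k]] <- spd_power(ch$functionals[[k]], -1/2)
  }
  list(Qs = Qs, lams = lams, Fih = Fih, M = ch$M,
       code = .family_code(family))
}

.ctx_loss <- function(ctx, weights, rotation, constant, penalty) {
  M <- ctx$M
  R <- if (is.null(rotation)) diag(M) else rotation
  C <- if (is.null(constant)) matrix(0, M, M) else constant
  cpp_cohort_loss(ctx$Qs, ctx$lams, ctx$Fih, ctx$code, weights, R, C, penalty)
}

#' Cohort Riemannian loss of a mapping
#'
#' The mean over subjects of the squared affine-invariant distance between
#' the mapping's prediction and the observed functional matrix,
#' `L(f) = (1/K) sum_k Tr(log^2(F_k^{-1/2} f(S_k) F_k^{-1/2}))`.
#' Predictions with eigenvalues below the SPD floor are clipped to it and
#' the loss augmented by `spd_penalty` times the average clipped mass, so
#' the objective stays finite and continuous during optimization.
#'
#' @param params a [mapping_params()] object.
#' @param ch a [cohort()].
#' @param spd_penalty penalty weight for non-SPD predictions.
#' @return Nonnegative scalar loss.
#' @export
riemannian_loss <- function(params, ch, spd_penalty = 1e3) {
  stopifnot(inherits(params, "mapping_params"), inherits(ch, "cohort"))
  ctx <- .loss_context(ch, params$family)
  .ctx_loss(ctx, params$weights, params$rotation, params$constant, spd_penalty)
}

#' Congruence transform by an SPD matrix
#'
#' Maps `X` to `F^{-1/2} X F^{-1/2}`, the change of coordinates that
#' recentres each subject's term of the Riemannian loss at the identity.
#'
#' @param term symmetric matrix.
#' @param F SPD matrix.
#' @return The transformed symmetric matrix.
#' @export
congruence_transform <- function(term, F) {
  .check_symmetric(term, "term")
  Fih <- spd_power(F, -1/2)
  out <- Fih %*% term %*% Fih
  (out + t(out)) / 2
}

# ---- rotation parameterization -------------------------------------------

.skew_from_vec <- function(w, M) {
  S <- matrix(0, M, M)
  S[upper.tri(S)] <- w
  S - t(S)
}

# Nearest orthogonal matrix (polar factor); guards against drift across
# repeated retractions.
.orthogonalize <- function(R) {
  s <- svd(R)
  out <- s$u %*% t(s$v)
  if (det(out) < 0) out <- s$u %*% diag(c(rep(1, nrow(R) - 1), -1)) %*% t(s$v)
  out
}

.init_weights <- function(family, order) {
  switch(family,
    heat_kernel = 1,
    diffusion_affine = c(1, 1, 0),
    c(1, rep(0, order)))  # g == 1: the identity prediction, SPD-safe
}

#' Fit an eigenmode mapping by block coordinate descent
#'
#' Minimizes the cohort Riemannian loss by cycling, for
#' `config$outer_iterations` rounds, over (i) the eigenvalue-weight block
#' (BFGS with central finite differences), (ii) the rotation block when the
#' family carries one (BFGS over the skew-symmetric generator `w` of the
#' retraction `R <- R0 expm(skew(w))`, which stays exactly on the rotation
#' group), and (iii) the constant block when present (BFGS over the free
#' entries of the symmetric matrix). A block update is accepted only if it
#' does not increase the loss, so the trajectory is non-increasing.
#'
#' @param family one of [mapping_families].
#' @param ch a [cohort()].
#' @param order polynomial order for the polynomial/spectral families.
#' @param config a [fit_config()].
#' @return An object of class `mapping_fit`: `params` (the fitted
#'   [mapping_params()]), `loss_trajectory` (initial loss followed by the
#'   loss after each outer round), `converged`, and a `diagnostics` data
#'   frame of per-block losses and step norms.
#' @export
fit_mapping <- function(family, ch, order = 6L, config = fit_config()) {
  family <- match.arg(family, mapping_families)
  stopifnot(inherits(ch, "cohort"), inherits(config, "fit_config"))
  ctx <- .loss_context(ch, family)
  M <- ch$M
  pen <- config$spd_penalty

  weights <- .init_weights(family, order)
  rotation <- if (.family_has_rotation(family)) diag(M) else NULL
  constant <- if (.family_has_constant(family)) matrix(0, M, M) else NULL

  loss <- .ctx_loss(ctx, weights, rotation, constant, pen)
  trajectory <- loss
  diag_rows <- list()
  note <- function(outer, block, loss, step) {
    diag_rows[[length(diag_rows) + 1L]] <<-
      data.frame(outer = outer, block = block, loss = loss, step_norm = step)
  }

  run_block <- function(par, fn, maxit) {
    ctl <- list(maxit = maxit, reltol = config$reltol,
                ndeps = rep(config$fd_step, length(par)))
    opt <- optim(par, fn, method = "BFGS", control = ctl)
    opt
  }

  for (outer in seq_len(config$outer_iterations)) {
    ## (i) eigenvalue-weight block
    opt <- run_block(weights, function(w)
      .ctx_loss(ctx, w, rotation, constant, pen), config$weight_maxit)
    if (opt$value <= loss) {
      step <- sqrt(sum((opt$par - weights)^2))
      weights <- opt$par; loss <- opt$value
    } else step <- 0
    note(outer, "weights", loss, step)

    ## (ii) rotation block
    if (!is.null(rotation)) {
      R0 <- rotation
      opt <- run_block(rep(0, M * (M - 1) / 2), function(w)
        .ctx_loss(ctx, weights, R0 %*% cpp_expm(.skew_from_vec(w, M)),
                  constant, pen), config$manifold_maxit)
      if (opt$value <= loss) {
        rotation <- .orthogonalize(R0 %*% cpp_expm(.skew_from_vec(opt$par, M)))
        loss <- .ctx_loss(ctx, weights, rotation, constant, pen)
        step <- sqrt(sum(opt$par^2))
      } else step <- 0
      note(outer, "rotation", loss, step)
    }

    ## (iii) constant block
    if (!is.null(constant)) {
      C0 <- constant
      upper <- upper.tri(C0, diag = TRUE)
      to_sym <- function(v) {
        C <- matrix(0, M, M); C[upper] <- v
        C <- C + t(C); diag(C) <- diag(C) / 2
        C
      }
      opt <- run_block(C0[upper], function(v)
        .ctx_loss(ctx, weights, rotation, to_sym(v), pen), config$manifold_maxit)
      if (opt$value <= loss) {
        step <- sqrt(sum((opt$par - C0[upper])^2))
        constant <- to_sym(opt$par); loss <- opt$value
      } else step <- 0
      note(outer, "constant", loss, step)
    }

    trajectory <- c(trajectory, loss)
  }

  n <- length(trajectory)
  rel_change <- abs(trajectory[n] - trajectory[n - 1]) /
    max(trajectory[n - 1], .Machine$double.eps)
  params <- mapping_params(family, weights, order = order,
                           rotation = rotation, constant = constant)
  structure(list(params = params, family = family, order = order,
                 loss_trajectory = trajectory,
                 converged = rel_change <= 1e-3,
                 diagnostics = do.call(rbind, diag_rows),
                 config = config),
            class = "mapping_fit")
}

#' @export
print.mapping_fit <- function(x, ...) {
  n <- length(x$loss_trajectory)
  cat(sprintf("Fitted eigenmode mapping '%s'\n", x$family))
  cat(sprintf("  loss: %.6g -> %.6g over %d outer iteration(s)%s\n",
              x$loss_trajectory[1], x$loss_trajectory[n], n - 1L,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Riemannian nearest-structural-neighbors mean predictor
#'
#' Predicts the functional matrix of a new subject as the Riemannian
#' Frechet mean of the functional matrices of the `P` training subjects
#' whose structural connectomes are closest to the new subject's. The
#' rationale: structurally similar subjects have similar functional
#' connectivity (when similarity is measured with the affine-invariant
#' metric), so averaging only the structural neighbors sharpens the
#' group-mean prediction.
#'
#' Structural connectomes have a zero diagonal and are not SPD, so the
#' default proximity metric is the Frobenius distance. The `"riemannian"`
#' option applies the affine-invariant distance after a diagonal shift
#' `S + eps I` shared by the compared pair, with `eps` twice the larger
#' maximum weighted degree (a Gershgorin bound, guaranteeing positive
#' definiteness of both).
#'
#' @param S_new structural connectome of the new subject.
#' @param ch training [cohort()].
#' @param P number of structural nearest neighbors to average
#'   (`1 <= P <= K`); ties in distance are broken by subject order.
#' @param structural_metric `"euclidean"` (default) or `"riemannian"`.
#' @param tol,max_iter passed to [frechet_mean_riemannian()].
#' @return The predicted SPD functional matrix; the selected neighbor
#'   indices are attached as attribute `neighbors`.
#' @export
nn_mean_predict <- function(S_new, ch, P = 50L,
                            structural_metric = c("euclidean", "riemannian"),
                            tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(ch, "cohort"))
  structural_metric <- match.arg(structural_metric)
  P <- as.integer(P)
  if (P < 1 || P > ch$K)
    stop(sprintf("P must lie in [1, K = %d], got %d", ch$K, P), call. = FALSE)
  d <- vapply(ch$structurals, function(S) {
    if (structural_metric == "euclidean") euclidean_distance(S_new, S)
    else {
      # Gershgorin bound: |eigenvalues of S| <= max row sum, so a shared
      # shift of twice the larger maximum degree makes both matrices SPD
      eps <- 2 * max(max(rowSums(abs(S_new))), max(rowSums(abs(S))))
      riemannian_distance(S_new + diag(eps, nrow(S_new)), S + diag(eps, nrow(S)))
    }
  }, numeric(1))
  idx <- order(d, seq_along(d))[seq_len(P)]
  out <- frechet_mean_riemannian(ch$functionals[idx], tol = tol,
                                 max_iter = max_iter)
  attr(out, "neighbors") <- idx
  out
}
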