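test_that("riemannian_loss matches direct per-subject summation", {
  set.seed(30)
  g <- tiny_cohort(M = 7, K = 5, family = "diffusion_affine", sigma = 0.2, seed = 31)
  ch <- g$cohort
  params <- mapping_params("diffusion_affine", c(0.9, 1.4, 0.2))
  direct <- mean(sapply(seq_len(ch$K), function(k) {
    P <- predict_functional(params, ch$structurals[[k]])
    riemannian_distance(P, ch$functionals[[k]])^2
  }))
  expect_equal(riemannian_loss(params, ch), direct, tolerance = 1e-10)

  # loss is zero when the mapping reproduces every functional matrix
  g0 <- tiny_cohort(M = 7, K = 5, family = "heat_kernel", sigma = 0, seed = 32)
  expect_lt(riemannian_loss(g0$ground_truth, g0$cohort), 1e-16)
})

test_that("congruence transform recentres and round-trips", {
  set.seed(33)
  X <- rand_sym(5)
  F1 <- rand_spd(5)
  expect_equal(congruence_transform(X, diag(5)), X, tolerance = 1e-12)
  # transform of the identity by F gives F^{-1}
  expect_lt(max(abs(congruence_transform(diag(5), F1) - solve(F1))), 1e-8)
  # congruence then inverse congruence restores the term
  Y <- congruence_transform(X, F1)
  back <- spd_power(F1, 1/2) %*% Y %*% spd_power(F1, 1/2)
  expect_lt(max(abs(back - X)), 1e-8)
})

test_that("noiseless parameter recovery: weight families hit the truth", {
  g <- tiny_cohort(M = 10, K = 8, family = "heat_kernel", sigma = 0, jitter = 0.1,
                   seed = 34)
  fit <- fit_mapping("heat_kernel", g$cohort)
  expect_lt(abs(fit$params$weights - 0.5), 1e-3)

  g <- tiny_cohort(M = 10, K = 8, family = "diffusion_affine", sigma = 0,
                   jitter = 0.1, seed = 35)
  fit <- fit_mapping("diffusion_affine", g$cohort)
  expect_lt(max(abs(fit$params$weights - c(1.2, 0.8, 0.1)) / c(1.2, 0.8, 0.1)), 0.01)

  g <- tiny_cohort(M = 10, K = 8, family = "polynomial", sigma = 0, jitter = 0.1,
                   seed = 36, order = 2L)
  fit <- fit_mapping("polynomial", g$cohort, order = 2)
  expect_lt(max(abs(fit$params$weights - c(1, 5, 10)) / c(1, 5, 10)), 0.01)
})

test_that("rotation-family weights are recovered when the truth has no rotation", {
  truth <- mapping_params("spectral_rotation", c(1, 5, 10), order = 2,
                          rotation = diag(9))
  sp <- synthetic_spec(M_regions = 9, K_subjects = 8, true_family = "spectral_rotation",
                       true_params = truth, noise_sigma = 0, subject_jitter = 0.1,
                       seed = 37, order = 2L)
  g <- generate_cohort(sp)
  fit <- fit_mapping("spectral_rotation", g$cohort, order = 2)
  expect_lt(max(abs(fit$params$weights - c(1, 5, 10)) / c(1, 5, 10)), 0.01)
})

test_that("noisy recovery stays within ten percent (median over seeds)", {
  rel_err <- sapply(1:10, function(s) {
    g <- tiny_cohort(M = 10, K = 10, family = "heat_kernel", sigma = 0.05,
                     jitter = 0.1, seed = 400 + s)
    fit <- fit_mapping("heat_kernel", g$cohort)
    abs(fit$params$weights - 0.5) / 0.5
  })
  expect_lt(median(rel_err), 0.1)
})

test_that("coordinate descent never increases the loss across blocks", {
  g <- tiny_cohort(M = 8, K = 6, family = "spectral_rotation_constant",
                   sigma = 0.1, jitter = 0.2, seed = 38, order = 2L)
  for (fam in mapping_families) {
    fit <- fit_mapping(fam, g$cohort, order = 2,
                       config = fit_config(outer_iterations = 2))
    losses <- c(fit$loss_trajectory[1], fit$diagnostics$loss)
    expect_true(all(diff(losses) <= 1e-6), info = fam)
    expect_equal(tail(fit$diagnostics$loss, 1), tail(fit$loss_trajectory, 1))
  }
})

test_that("fitting is deterministic", {
  g <- tiny_cohort(M = 8, K = 5, family = "spectral_rotation", sigma = 0.1,
                   seed = 39, order = 2L)
  cfg <- fit_config(outer_iterations = 2)
  f1 <- fit_mapping("spectral_rotation", g$cohort, order = 2, config = cfg)
  f2 <- fit_mapping("spectral_rotation", g$cohort, order = 2, config = cfg)
  expect_identical(f1$loss_trajectory, f2$loss_trajectory)
  expect_identical(f1$params$weights, f2$params$weights)
  expect_identical(f1$params$rotation, f2$params$rotation)
})

test_that("a single-subject cohort is reproduced through the constant block", {
  # with K = 1 the constant can absorb the residual exactly
  g <- tiny_cohort(M = 6, K = 1, family = "heat_kernel", sigma = 0.3, seed = 40)
  cfg <- fit_config(outer_iterations = 3, manifold_maxit = 300)
  fit <- fit_mapping("spectral_rotation_constant", g$cohort, order = 2, config = cfg)
  expect_lt(tail(fit$loss_trajectory, 1), 1e-4)
  pred <- predict_functional(fit$params, g$cohort$structurals[[1]], repair = TRUE)
  expect_lt(riemannian_distance(pred, g$cohort$functionals[[1]]), 0.02)
})

test_that("fitted rotations stay on the rotation group", {
  g <- tiny_cohort(M = 7, K = 5, family = "spectral_rotation", sigma = 0.1,
                   seed = 41, order = 2L)
  fit <- fit_mapping("spectral_rotation", g$cohort, order = 2)
  R <- fit$params$rotation
  expect_lt(max(abs(crossprod(R) - diag(7))), 1e-8)
  expect_gt(det(R), 0)
})

test_that("richer spectral families never fit worse (nesting)", {
  g <- tiny_cohort(M = 8, K = 6, family = "spectral_rotation_constant",
                   sigma = 0.1, jitter = 0.2, seed = 42, order = 2L)
  final <- sapply(c("polynomial", "spectral_rotation", "spectral_rotation_constant"),
                  function(fam) tail(fit_mapping(fam, g$cohort, order = 2)$loss_trajectory, 1))
  expect_lte(final["spectral_rotation"], final["polynomial"] + 1e-4)
  expect_lte(final["spectral_rotation_constant"], final["spectral_rotation"] + 1e-4)
})

test_that("nearest-neighbors mean predictor ranks and degenerates correctly", {
  set.seed(43)
  g <- tiny_cohort(M = 8, K = 6, sigma = 0.3, jitter = 0.3, seed = 44)
  ch <- g$cohort

  # P = K: the Frechet mean of all training functionals
  pred <- nn_mean_predict(ch$structurals[[1]], ch, P = ch$K)
  full <- frechet_mean_riemannian(ch$functionals)
  expect_lt(max(abs(pred - full)), 1e-8)

  # P = 1 with an exact structural match returns that subject's F
  pred1 <- nn_mean_predict(ch$structurals[[3]], ch, P = 1)
  expect_equal(attr(pred1, "neighbors"), 3L)
  expect_lt(max(abs(pred1 - ch$functionals[[3]])), 1e-10)

  # ranking follows the structural metric
  dvec <- sapply(ch$structurals, function(S) euclidean_distance(ch$structurals[[2]], S))
  expect_equal(sort(attr(nn_mean_predict(ch$structurals[[2]], ch, P = 3), "neighbors")),
               sort(order(dvec)[1:3]))

  expect_error(nn_mean_predict(ch$structurals[[1]], ch, P = 0), "P must lie")
  expect_error(nn_mean_predict(ch$structurals[[1]], ch, P = 99), "P must lie")

  # riemannian structural metric option runs and returns SPD output
  predR <- nn_mean_predict(ch$structurals[[1]], ch, P = 2,
                           structural_metric = "riemannian")
  expect_equal(attr(assert_spd(predR), "clipped_mass"), 0)
})
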