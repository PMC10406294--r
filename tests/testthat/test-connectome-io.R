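test_that("matrix files round-trip through CSV and TSV", {
  d <- withr::local_tempdir()
  expect_true(file.exists(d) || dir.exists(d))

  # plain identity, no labels
  p <- file.path(d, "id.csv")
  writeLines(c("1,0,0", "0,1,0", "0,0,1"), p)
  expect_equal(read_connectome_matrix(p), diag(3), ignore_attr = TRUE)

  set.seed(10)
  A <- rand_sym(7)
  for (ext in c("csv", "tsv")) {
    p <- file.path(d, paste0("m.", ext))
    write_connectome_matrix(A, p)
    expect_lt(max(abs(read_connectome_matrix(p) - A)), 1e-12)
  }

  # labelled matrix keeps its region names
  rownames(A) <- colnames(A) <- sprintf("roi%02d", 1:7)
  p <- file.path(d, "lab.csv")
  write_connectome_matrix(A, p)
  B <- read_connectome_matrix(p)
  expect_equal(rownames(B), rownames(A))
  expect_lt(max(abs(B - A)), 1e-12)
})

test_that("malformed matrix files are rejected", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.csv")
  writeLines(c("1,2,3", "4,5"), p)
  expect_error(read_connectome_matrix(p), "ragged")
  writeLines(c("1,2,3", "4,x,6", "7,8,9"), p)
  expect_error(read_connectome_matrix(p), "non-numeric")
  writeLines(c("1,2,3", "4,5,6"), p)
  expect_error(read_connectome_matrix(p), "non-square")
  expect_error(read_connectome_matrix(file.path(d, "absent.csv")), "not found")
})

test_that("symmetrize_normalize follows the summing + unit-mass convention", {
  # hand computation: symmetrize [[0,2],[0,0]] -> [[0,2],[2,0]], off-diag sum 4
  out <- symmetrize_normalize(matrix(c(0, 0, 2, 0), 2, 2))
  expect_equal(out, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  set.seed(11)
  raw <- matrix(runif(36), 6, 6)           # nonzero diagonal on purpose
  S <- symmetrize_normalize(raw)
  expect_equal(diag(S), rep(0, 6))
  expect_equal(S, t(S))
  expect_true(all(S >= 0))
  expect_equal(sum(S), 1, tolerance = 1e-8)
  # nonzero diagonal is discarded before normalization
  raw2 <- raw; diag(raw2) <- diag(raw2) + 100
  expect_equal(symmetrize_normalize(raw2), S)
  # idempotent up to the unit off-diagonal sum
  expect_lt(max(abs(symmetrize_normalize(S) - S)), 1e-12)

  expect_error(symmetrize_normalize(diag(3)), "degenerate")
  expect_error(symmetrize_normalize(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
})

test_that("normalized Laplacian: closed forms, kernel and spectral bounds", {
  S <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  L <- normalized_laplacian(S)
  expect_equal(L, matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(sort(eigen(L, symmetric = TRUE)$values), c(0, 2), tolerance = 1e-12)

  # complete graph with equal weights: smallest eigenvalue 0
  M <- 7
  Sc <- symmetrize_normalize(matrix(1, M, M) - diag(M))
  ev <- eigen(normalized_laplacian(Sc), symmetric = TRUE)$values
  expect_lt(abs(min(ev)), 1e-10)

  set.seed(12)
  for (i in 1:50) {
    sp <- synthetic_spec(M_regions = 8, K_subjects = 1, graph_density = runif(1, 0.1, 0.9),
                         seed = sample.int(1e6, 1))
    S <- generate_structural(sp)[[1]]
    L <- normalized_laplacian(S)
    ev <- eigen(L, symmetric = TRUE)$values
    expect_true(all(ev >= -1e-8 & ev <= 2 + 1e-8))
    # D^{1/2} 1 spans the kernel for a connected graph
    v <- sqrt(rowSums(S))
    expect_lt(max(abs(L %*% v)), 1e-8)
  }

  S0 <- matrix(0, 3, 3); S0[1, 2] <- S0[2, 1] <- 1
  expect_error(normalized_laplacian(S0 / sum(S0)), "zero degree")
})

test_that("pearson_functional builds valid SPD correlation matrices", {
  set.seed(13)
  M <- 6; Tn <- 400
  ts <- matrix(rnorm(M * Tn), M, Tn)
  Fm <- pearson_functional(ts)
  expect_equal(diag(Fm), rep(1, M), ignore_attr = TRUE)
  expect_true(all(Fm >= -1 & Fm <= 1))
  # independent long rows: off-diagonals near zero
  expect_lt(max(abs(Fm[upper.tri(Fm)])), 4 / sqrt(Tn))
  expect_equal(attr(assert_spd(Fm), "clipped_mass"), 0)

  # F = D D^T for the row-demeaned, row-normalized data matrix
  D <- t(scale(t(ts)))            # demean + unit variance per row
  D <- D / sqrt(Tn - 1)
  expect_lt(max(abs(Fm - D %*% t(D))), 1e-10)

  # duplicated row: correlation exactly 1 between the twins
  ts2 <- rbind(ts, ts[1, ])
  F2 <- suppressWarnings(pearson_functional(ts2, repair = TRUE))
  expect_equal(F2[1, M + 1], 1, tolerance = 1e-8)

  ts3 <- ts; ts3[2, ] <- 5
  expect_error(pearson_functional(ts3), "zero-variance")
  expect_warning(pearson_functional(matrix(rnorm(36), 6, 6), repair = TRUE),
                 "rank-deficient")
})

test_that("cohorts round-trip through a manifest", {
  set.seed(14)
  g <- tiny_cohort(M = 6, K = 3, seed = 99)
  d <- withr::local_tempdir()
  save_cohort(g$cohort, d)
  ch <- load_cohort(file.path(d, "manifest.yaml"))
  expect_equal(ch$K, 3)
  expect_equal(ch$subjects, g$cohort$subjects)
  for (k in 1:3) {
    expect_lt(max(abs(ch$structurals[[k]] - g$cohort$structurals[[k]])), 1e-12)
    expect_lt(max(abs(ch$functionals[[k]] - g$cohort$functionals[[k]])), 1e-12)
  }

  # raw structural flag triggers symmetrize_normalize on load
  man <- yaml::read_yaml(file.path(d, "manifest.yaml"))
  raw <- matrix(c(0, 0, 2, 0, 0, 0, 0, 1, 0), 3, 3)
  write_connectome_matrix(raw, file.path(d, "raw.csv"))
  write_connectome_matrix(diag(3), file.path(d, "f.csv"))
  man2 <- list(raw_structural = TRUE,
               subjects = list(list(id = "a", structural = "raw.csv", functional = "f.csv")))
  yaml::write_yaml(man2, file.path(d, "man2.yaml"))
  ch2 <- load_cohort(file.path(d, "man2.yaml"))
  expect_equal(ch2$structurals[[1]], symmetrize_normalize(raw))
})

test_that("cohort construction enforces its invariants", {
  set.seed(15)
  g <- tiny_cohort(M = 6, K = 3, seed = 7)
  ch <- g$cohort
  expect_error(cohort(c("a", "a", "b"), ch$structurals, ch$functionals),
               "duplicate")
  bad <- ch$structurals; bad[[2]] <- rand_spd(8)
  expect_error(cohort(ch$subjects, bad, ch$functionals), "region count")
  badF <- ch$functionals; badF[[1]] <- diag(c(1, 1, 1, 1, 1, -1))
  expect_error(cohort(ch$subjects, ch$structurals, badF), "not SPD")

  d <- withr::local_tempdir()
  yaml::write_yaml(list(subjects = list()), file.path(d, "empty.yaml"))
  expect_error(load_cohort(file.path(d, "empty.yaml")), "no subjects")

  # mismatched dimensions across subjects
  write_connectome_matrix(symmetrize_normalize(matrix(1, 4, 4) - diag(4)),
                          file.path(d, "s1.csv"))
  write_connectome_matrix(diag(4), file.path(d, "f1.csv"))
  write_connectome_matrix(symmetrize_normalize(matrix(1, 5, 5) - diag(5)),
                          file.path(d, "s2.csv"))
  write_connectome_matrix(diag(5), file.path(d, "f2.csv"))
  man <- list(subjects = list(
    list(id = "a", structural = "s1.csv", functional = "f1.csv"),
    list(id = "b", structural = "s2.csv", functional = "f2.csv")))
  yaml::write_yaml(man, file.path(d, "mix.yaml"))
  expect_error(load_cohort(file.path(d, "mix.yaml")), "region count")
})
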