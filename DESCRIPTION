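Package: riemconn
Title: Riemannian Structure-Function Mapping of Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping structural to functional brain connectomes
    under the affine-invariant Riemannian geometry of symmetric positive
    definite (SPD) matrices. Provides the affine-invariant geodesic distance
    and iterative Frechet (Karcher) mean on the SPD manifold, a unified
    family of eigenmode structure-function mappings (heat kernel, affine
    diffusion, matrix polynomial, and rotated spectral mappings with an
    optional symmetric offset), a manifold-aware block coordinate-descent
    fitting procedure for the cohort Riemannian loss, a nearest-structural-
    neighbors Riemannian-mean predictor, leave-one-out cohort evaluation,
    connectome input/output and preprocessing (symmetrization, off-diagonal
    normalization, normalized graph Laplacian, Pearson functional matrices),
    and a synthetic cohort generator with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
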