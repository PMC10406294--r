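#' Eigenmode mapping families
#'
#' The five structure-function mapping families supported by the package,
#' all instances of the unified eigenmode form
#' `f(S) = sum_n g(lambda_n) h(u_n) + C` over the eigenpairs of the mapping
#' input:
#' \describe{
#'   \item{heat_kernel}{`exp(-theta L)` on the normalized Laplacian; one
#'     parameter (the diffusion rate and time are not separately
#'     identifiable and are merged into `theta`).}
#'   \item{diffusion_affine}{`a exp(-alpha L) + b I`; three parameters.}
#'   \item{polynomial}{`sum_m a_m S^m` up to order `P`; `P + 1` parameters.}
#'   \item{spectral_rotation}{`R Q g(Sigma) Q^T R^T`, a polynomial on the
#'     spectrum with the eigenvectors rotated by an orthogonal `R`.}
#'   \item{spectral_rotation_constant}{the above plus a constant symmetric
#'     matrix `C`.}
#' }
#' @export
mapping_families <- c("heat_kernel", "diffusion_affine", "polynomial",
                      "spectral_rotation", "spectral_rotation_constant")

.family_code <- function(family) match(family, mapping_families)

.family_has_rotation <- function(family)
  family %in% c("spectral_rotation", "spectral_rotation_constant")

.family_has_constant <- function(family) family == "spectral_rotation_constant"

#' Kind of structural input a family consumes
#'
#' The diffusion families act on the normalized graph Laplacian of the
#' structural matrix; the polynomial and spectral families act on the
#' structural matrix itself.
#'
#' @param family one of [mapping_families].
#' @return `"laplacian"` or `"structural"`.
#' @export
mapping_input_kind <- function(family) {
  family <- match.arg(family, mapping_families)
  if (family %in% c("heat_kernel", "diffusion_affine")) "laplacian" else "structural"
}

#' Parameters of one eigenmode mapping
#'
#' @param family one of [mapping_families].
#' @param weights eigenvalue-weight coefficients: `theta` for
#'   `heat_kernel`; `(a, alpha, b)` for `diffusion_affine`; `a_0 ... a_P`
#'   for the polynomial and spectral families.
#' @param order polynomial order `P` (polynomial and spectral families
#'   only; default 6).
#' @param rotation orthogonal matrix with determinant +1, for the spectral
#'   rotation families.
#' @param constant symmetric matrix `C`, for `spectral_rotation_constant`.
#' @return An object of class `mapping_params`.
#' @export
mapping_params <- function(family, weights, order = 6L,
                           rotation = NULL, constant = NULL) {
  family <- match.arg(family, mapping_families)
  weights <- as.numeric(weights)
  nw <- switch(family, heat_kernel = 1L, diffusion_affine = 3L,
               as.integer(order) + 1L)
  if (length(weights) != nw)
    stop(sprintf("family '%s' (order %d) expects %d weight(s), got %d",
                 family, order, nw, length(weights)), call. = FALSE)
  if (.family_has_rotation(family)) {
    if (is.null(rotation))
      stop("family '", family, "' requires a rotation matrix", call. = FALSE)
    .check_square(rotation, "rotation")
    orth <- max(abs(crossprod(rotation) - diag(nrow(rotation))))
    if (orth > 1e-8)
      stop(sprintf("rotation is not orthogonal: max |R'R - I| = %.3e", orth),
           call. = FALSE)
    if (det(rotation) <= 0)
      stop("rotation must have determinant +1", call. = FALSE)
  } else if (!is.null(rotation)) {
    stop("family '", family, "' carries no rotation", call. = FALSE)
  }
  if (.family_has_constant(family)) {
    if (is.null(constant))
      stop("family '", family, "' requires a constant symmetric matrix", call. = FALSE)
    .check_symmetric(constant, "constant")
  } else if (!is.null(constant)) {
    stop("family '", family, "' carries no constant term", call. = FALSE)
  }
  structure(list(family = family, weights = weights,
                 order = if (family %in% c("heat_kernel", "diffusion_affine"))
                   NA_integer_ else as.integer(order),
                 rotation = rotation, constant = constant,
                 input_kind = mapping_input_kind(family)),
            class = "mapping_params")
}

#' @export
print.mapping_params <- function(x, ...) {
  cat(sprintf("Eigenmode mapping '%s' (input: %s)\n", x$family, x$input_kind))
  cat("  weights:", paste(signif(x$weights, 6), collapse = ", "), "\n")
  if (!is.null(x$rotation))
    cat(sprintf("  rotation: %d x %d orthogonal matrix\n",
                nrow(x$rotation), ncol(x$rotation)))
  if (!is.null(x$constant))
    cat(sprintf("  constant: %d x %d symmetric matrix\n",
                nrow(x$constant), ncol(x$constant)))
  invisible(x)
}

#' Mapping input for a structural connectome
#'
#' Returns the matrix a mapping family actually consumes: the normalized
#' Laplacian for the diffusion families, the structural matrix itself for
#' the polynomial/spectral families.
#'
#' @param S structural connectome.
#' @param family one of [mapping_families].
#' @return A symmetric matrix.
#' @export
mapping_input <- function(S, family) {
  if (mapping_input_kind(family) == "laplacian") normalized_laplacian(S) else S
}

# Spectral weights g(lambda) for a family.
.g_of_lambda <- function(family, weights, lambda) {
  switch(family,
    heat_kernel = exp(-weights[1] * lambda),
    diffusion_affine = weights[1] * exp(-weights[2] * lambda) + weights[3],
    # polynomial families: Horner on sum_m a_m lambda^m
    {
      v <- rep(0, length(lambda))
      for (m in rev(seq_along(weights))) v <- v * lambda + weights[m]
      v
    })
}

#' Apply an eigenmode mapping to its input matrix
#'
#' Evaluates `f(X) = R Q g(Sigma) Q^T R^T + C` through the symmetric
#' eigendecomposition `X = Q Sigma Q^T` (rotation and constant only for
#' the families that carry them). Matrix exponentials and polynomials are
#' evaluated on the spectrum, so all families share the same eigenmode
#' form. The output is symmetric but not guaranteed SPD; callers decide
#' whether to repair or penalize.
#'
#' @param params a [mapping_params()] object.
#' @param X the family-appropriate input (see [mapping_input()]).
#' @return The predicted functional matrix (symmetric).
#' @export
apply_mapping <- function(params, X) {
  stopifnot(inherits(params, "mapping_params"))
  .check_symmetric(X, "X")
  if (!is.null(params$rotation) && nrow(params$rotation) != nrow(X))
    stop("rotation dimension does not match input", call. = FALSE)
  e <- sym_eig(X)
  g <- .g_of_lambda(params$family, params$weights, e$values)
  V <- if (is.null(params$rotation)) e$vectors else params$rotation %*% e$vectors
  P <- V %*% (g * t(V))
  if (!is.null(params$constant)) P <- P + params$constant
  (P + t(P)) / 2
}

#' Predict a functional matrix from a structural connectome
#'
#' Convenience wrapper composing [mapping_input()] and [apply_mapping()].
#'
#' @inheritParams mapping_input
#' @param params a [mapping_params()] object.
#' @param repair repair non-SPD predictions via [assert_spd()]?
#' @return The predicted functional matrix.
#' @export
predict_functional <- function(params, S, repair = FALSE) {
  P <- apply_mapping(params, mapping_input(S, params$family))
  if (repair) P <- assert_spd(P, repair = TRUE)
  P
}

#' Degrees of freedom of a mapping family
#'
#' The free-parameter counts of the five families: 1 (heat kernel),
#' 3 (affine diffusion), `P + 1` (polynomial), `P + 1 + (M^2 - M)/2`
#' (spectral rotation), and the latter plus the constant term for
#' `spectral_rotation_constant`. The constant is conventionally counted
#' as a full `M^2` block; since `C` is constrained symmetric its free
#' dimension is `M(M + 1)/2`, and both counts are returned for that
#' family (`dof` uses the conventional count, `dof_symmetric_constant`
#' the constrained one).
#'
#' @param family one of [mapping_families], or a [mapping_params()] object.
#' @param M_regions number of brain regions.
#' @param order polynomial order `P` (ignored for the diffusion families).
#' @return Integer degrees of freedom; for `spectral_rotation_constant`
#'   the value carries attribute `dof_symmetric_constant`.
#' @export
degrees_of_freedom <- function(family, M_regions = NULL, order = 6L) {
  if (inherits(family, "mapping_params")) {
    params <- family
    family <- params$family
    if (!is.na(params$order)) order <- params$order
    if (is.null(M_regions) && !is.null(params$rotation))
      M_regions <- nrow(params$rotation)
  }
  family <- match.arg(family, mapping_families)
  order <- as.integer(order)
  rot_dof <- function(M) M * (M - 1L) / 2L
  out <- switch(family,
    heat_kernel = 1L,
    diffusion_affine = 3L,
    polynomial = order + 1L,
    spectral_rotation = {
      stopifnot(!is.null(M_regions))
      order + 1L + rot_dof(as.integer(M_regions))
    },
    spectral_rotation_constant = {
      stopifnot(!is.null(M_regions))
      M <- as.integer(M_regions)
      v <- order + 1L + rot_dof(M) + M * M
      attr(v, "dof_symmetric_constant") <- order + 1L + rot_dof(M) + M * (M + 1L) / 2L
      v
    })
  out
}

#' Serialize mapping parameters to a text file
#'
#' Coefficients are stored inline and the rotation/constant blocks as
#' embedded row lists, in YAML.
#'
#' @param params a [mapping_params()] object.
#' @param path destination file.
#' @export
write_mapping_params <- function(params, path) {
  stopifnot(inherits(params, "mapping_params"))
  obj <- list(family = params$family, weights = params$weights)
  if (!is.na(params$order)) obj$order <- params$order
  if (!is.null(params$rotation))
    obj$rotation <- apply(params$rotation, 1, identity, simplify = FALSE)
  if (!is.null(params$constant))
    obj$constant <- apply(params$constant, 1, identity, simplify = FALSE)
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' Read mapping parameters from a text file
#'
#' @param path file written by [write_mapping_params()].
#' @return A [mapping_params()] object.
#' @export
read_mapping_params <- function(path) {
  obj <- yaml::read_yaml(path)
  rot <- if (!is.null(obj$rotation)) do.call(rbind, obj$rotation)
  cst <- if (!is.null(obj$constant)) do.call(rbind, obj$constant)
  if (!is.null(cst)) cst <- (cst + t(cst)) / 2
  mapping_params(obj$family, obj$weights,
                 order = if (is.null(obj$order)) 6L else obj$order,
                 rotation = rot, constant = cst)
}
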