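#' Read a connectivity matrix from delimited text
#'
#' Reads a square numeric matrix from a CSV or TSV file, with an optional
#' single header row plus leading label column of region names. The
#' delimiter is taken from the file extension (`.tsv`/`.txt` are
#' tab-separated, anything else comma-separated) unless given explicitly.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) infers it from the extension.
#' @param check_symmetric validate symmetry on load?
#' @return A numeric matrix, with region labels as dimnames when the file
#'   carries a header.
#' @export
read_connectome_matrix <- function(path, sep = NULL, check_symmetric = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty matrix file: ", path, call. = FALSE)
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1)
    stop("ragged rows in ", path, ": widths ", paste(unique(widths), collapse = ", "),
         call. = FALSE)
  first <- suppressWarnings(as.numeric(cells[[1]]))
  has_header <- anyNA(first)
  labels <- NULL
  if (has_header) {
    labels <- trimws(cells[[1]][-1])
    cells <- lapply(cells[-1], `[`, -1)
  }
  num <- suppressWarnings(lapply(cells, as.numeric))
  if (any(vapply(num, anyNA, logical(1))))
    stop("non-numeric cells in ", path, call. = FALSE)
  A <- do.call(rbind, num)
  if (nrow(A) != ncol(A))
    stop(sprintf("non-square grid in %s: %d x %d", path, nrow(A), ncol(A)),
         call. = FALSE)
  if (!is.null(labels)) dimnames(A) <- list(labels, labels)
  if (check_symmetric) .check_symmetric(A, path)
  A
}

#' Write a connectivity matrix to delimited text
#'
#' Values are written with 17 significant digits so that a save/load round
#' trip reproduces the matrix to double precision.
#'
#' @param A numeric matrix.
#' @param path destination; extension selects the delimiter as in
#'   [read_connectome_matrix()].
#' @param sep field separator; `NULL` infers from the extension.
#' @export
write_connectome_matrix <- function(A, path, sep = NULL) {
  .check_square(A)
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  rows <- apply(A, 1, function(r) paste(formatC(r, digits = 17, format = "g"),
                                        collapse = sep))
  if (!is.null(rownames(A))) {
    header <- paste(c("region", colnames(A)), collapse = sep)
    rows <- paste(rownames(A), rows, sep = sep)
    rows <- c(header, rows)
  }
  writeLines(rows, path)
  invisible(path)
}

#' Symmetrize and normalize a raw structural connectome
#'
#' Raw streamline-weight matrices are made symmetric by summing the
#' `(i, j)` and `(j, i)` entries, the diagonal is set to zero, and the
#' result is divided by the sum of its off-diagonal entries (both
#' triangles), giving a dimensionless weighted adjacency with unit
#' off-diagonal mass. No pruning or thresholding is applied, so weak
#' connections are kept.
#'
#' @param raw square matrix with nonnegative entries.
#' @return The normalized structural connectome: symmetric, nonnegative,
#'   zero diagonal, off-diagonal entries summing to one.
#' @export
symmetrize_normalize <- function(raw) {
  .check_square(raw, "raw")
  if (min(raw) < 0)
    stop("structural connectome entries must be nonnegative", call. = FALSE)
  W <- raw + t(raw)
  diag(W) <- 0
  s <- sum(W)
  if (s <= 0)
    stop("degenerate graph: all off-diagonal entries are zero", call. = FALSE)
  W / s
}

#' Symmetric normalized graph Laplacian
#'
#' `L = I - D^{-1/2} S D^{-1/2}` with `D` the diagonal matrix of row sums
#' of the (normalized) structural matrix. Symmetric, with spectrum in
#' `[0, 2]` and smallest eigenvalue 0 for a connected graph. The input of
#' the diffusion mapping families.
#'
#' @param S structural connectome (symmetric, nonnegative, zero diagonal).
#' @return The Laplacian matrix.
#' @export
normalized_laplacian <- function(S) {
  .check_symmetric(S, "S")
  deg <- rowSums(S)
  if (any(deg <= 0)) {
    bad <- which(deg <= 0)
    stop("isolated node(s) with zero degree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dih <- 1 / sqrt(deg)
  L <- diag(nrow(S)) - (dih * S) * rep(dih, each = nrow(S))
  (L + t(L)) / 2
}

#' Functional connectivity by Pearson correlation
#'
#' Builds the functional matrix from an `M x T` table of parcel time
#' series, one row per region, as the pairwise Pearson correlation between
#' rows. Negative correlations are preserved: the full-rank correlation
#' matrix of `T > M` linearly independent signals is SPD, and zeroing
#' negative entries would destroy that structure. Equivalently the result
#' is `D D^T` with `D` the row-demeaned, row-normalized data matrix.
#'
#' @param timeseries numeric matrix, regions in rows, time points in columns.
#' @param repair passed to [assert_spd()] for borderline rank-deficient
#'   matrices (e.g. fewer time points than regions).
#' @return SPD correlation matrix with unit diagonal.
#' @export
pearson_functional <- function(timeseries, repair = FALSE) {
  if (!is.matrix(timeseries) || !is.numeric(timeseries))
    stop("'timeseries' must be a numeric matrix (regions x time)", call. = FALSE)
  M <- nrow(timeseries); Tn <- ncol(timeseries)
  v <- apply(timeseries, 1, sd)
  if (any(v == 0))
    stop("zero-variance (constant) time series in row(s): ",
         paste(which(v == 0), collapse = ", "), call. = FALSE)
  if (Tn <= M)
    warning(sprintf("T = %d <= M = %d: correlation matrix is rank-deficient", Tn, M))
  Fm <- cor(t(timeseries))
  Fm <- (Fm + t(Fm)) / 2
  diag(Fm) <- 1
  out <- assert_spd(Fm, repair = repair)
  diag(out) <- 1
  out
}

#' Construct a cohort of paired connectomes
#'
#' @param subjects character vector of unique subject identifiers.
#' @param structurals list of structural connectomes (one per subject).
#' @param functionals list of SPD functional matrices (one per subject).
#' @param validate check invariants (dimensions, SPD functionals)?
#' @return An object of class `cohort` with elements `subjects`,
#'   `structurals`, `functionals`, `M` (regions) and `K` (subjects).
#' @export
cohort <- function(subjects, structurals, functionals, validate = TRUE) {
  subjects <- as.character(subjects)
  K <- length(subjects)
  if (length(structurals) != K || length(functionals) != K)
    stop("subjects, structurals and functionals must have equal length", call. = FALSE)
  if (K == 0) stop("empty cohort", call. = FALSE)
  if (anyDuplicated(subjects))
    stop("duplicate subject identifiers: ",
         paste(unique(subjects[duplicated(subjects)]), collapse = ", "), call. = FALSE)
  M <- nrow(structurals[[1]])
  if (validate) {
    for (k in seq_len(K)) {
      .check_symmetric(structurals[[k]], sprintf("structurals[[%d]]", k))
      .check_symmetric(functionals[[k]], sprintf("functionals[[%d]]", k))
      if (nrow(structurals[[k]]) != M || nrow(functionals[[k]]) != M)
        stop("all matrices must share the region count M = ", M, call. = FALSE)
      assert_spd(functionals[[k]])
    }
  }
  structure(list(subjects = subjects, structurals = structurals,
                 functionals = functionals, M = M, K = K),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Connectome cohort: %d subjects, %d regions\n", x$K, x$M))
  cat("  subjects:", paste(head(x$subjects, 5), collapse = ", "),
      if (x$K > 5) "..." else "", "\n")
  invisible(x)
}

#' Load a cohort from a manifest file
#'
#' The manifest is a YAML file listing subjects with per-subject structural
#' and functional matrix paths (relative to the manifest location):
#'
#' ```yaml
#' raw_structural: false
#' subjects:
#'   - id: sub-01
#'     structural: sub-01_struct.csv
#'     functional: sub-01_func.csv
#' ```
#'
#' With `raw_structural: true` the structural matrices are passed through
#' [symmetrize_normalize()] on load.
#'
#' @param manifest_path path to the manifest.
#' @return A [cohort()] object.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$subjects) || length(man$subjects) == 0)
    stop("manifest lists no subjects: ", manifest_path, call. = FALSE)
  base <- dirname(manifest_path)
  raw <- isTRUE(man$raw_structural)
  ids <- character(0); Ss <- list(); Fs <- list()
  for (entry in man$subjects) {
    if (is.null(entry$id) || is.null(entry$structural) || is.null(entry$functional))
      stop("each manifest subject needs id, structural and functional fields",
           call. = FALSE)
    S <- read_connectome_matrix(file.path(base, entry$structural),
                                check_symmetric = !raw)
    if (raw) S <- symmetrize_normalize(S)
    Fm <- read_connectome_matrix(file.path(base, entry$functional))
    ids <- c(ids, entry$id)
    Ss <- c(Ss, list(S)); Fs <- c(Fs, list(Fm))
  }
  cohort(ids, Ss, Fs)
}

#' Save a cohort to disk with a manifest
#'
#' Writes one structural and one functional CSV per subject plus a
#' `manifest.yaml` round-trippable through [load_cohort()].
#'
#' @param ch a [cohort()] object.
#' @param dir destination directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
save_cohort <- function(ch, dir) {
  stopifnot(inherits(ch, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", ch$K)
  for (k in seq_len(ch$K)) {
    sfile <- sprintf("%s_struct.csv", ch$subjects[k])
    ffile <- sprintf("%s_func.csv", ch$subjects[k])
    write_connectome_matrix(ch$structurals[[k]], file.path(dir, sfile))
    write_connectome_matrix(ch$functionals[[k]], file.path(dir, ffile))
    entries[[k]] <- list(id = ch$subjects[k], structural = sfile, functional = ffile)
  }
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(raw_structural = FALSE, subjects = entries), manifest)
  invisible(manifest)
}
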