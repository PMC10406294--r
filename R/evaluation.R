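#' Pairwise distance matrix over a set of connectivity matrices
#'
#' @param mats list of at least two matrices of a common dimension; the
#'   Riemannian metric requires SPD members.
#' @param metric `"euclidean"` (Frobenius) or `"riemannian"`
#'   (affine-invariant).
#' @return A `K x K` symmetric nonnegative matrix with zero diagonal, with
#'   attribute `metric_tag` set to the metric used.
#' @export
pairwise_distances <- function(mats, metric = c("euclidean", "riemannian")) {
  metric <- match.arg(metric)
  K <- length(mats)
  if (K < 2) stop("need at least two matrices", call. = FALSE)
  dfun <- if (metric == "euclidean") euclidean_distance else riemannian_distance
  D <- matrix(0, K, K)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    D[i, j] <- D[j, i] <- dfun(mats[[i]], mats[[j]])
  }
  if (!is.null(names(mats))) dimnames(D) <- list(names(mats), names(mats))
  attr(D, "metric_tag") <- metric
  D
}

#' Nearest neighbor of each subject under a distance matrix
#'
#' For each row, the index of the closest *other* subject (the diagonal is
#' excluded); ties resolve to the lowest index.
#'
#' @param D square symmetric distance matrix.
#' @return Integer vector of neighbor indices.
#' @export
nearest_neighbors <- function(D) {
  .check_square(D, "D")
  K <- nrow(D)
  if (K < 2) stop("need at least two subjects", call. = FALSE)
  vapply(seq_len(K), function(i) {
    d <- D[i, ]; d[i] <- Inf
    which.min(d)
  }, integer(1))
}

#' Agreement between two nearest-neighbor assignments
#'
#' @param nn_a,nn_b integer vectors as returned by [nearest_neighbors()].
#' @return The number of subjects whose nearest neighbor coincides.
#' @export
nn_agreement <- function(nn_a, nn_b) {
  stopifnot(length(nn_a) == length(nn_b))
  sum(nn_a == nn_b)
}

#' Summary statistics of a pairwise distance distribution
#'
#' Mean, sample standard deviation and range of the off-diagonal
#' (upper-triangle) distances.
#'
#' @param D distance matrix.
#' @return Named list with `mean`, `sd`, `min`, `max` and `n_pairs`.
#' @export
distance_summary <- function(D) {
  v <- D[upper.tri(D)]
  list(mean = mean(v), sd = sd(v), min = min(v), max = max(v),
       n_pairs = length(v))
}

#' Structure-function distance regression
#'
#' Relates between-subject structural distances to between-subject
#' functional distances: the `K(K-1)/2` upper-triangle pairs of each
#' matrix are z-scored (sample standard deviation) and the squared Pearson
#' correlation between the two vectors is returned. A high value means
#' structurally similar subjects also have similar functional
#' connectivity under the chosen functional metric.
#'
#' @param D_struct,D_func distance matrices over the same subjects.
#' @return The coefficient of determination, in `[0, 1]`.
#' @export
distance_regression <- function(D_struct, D_func) {
  .check_square(D_struct, "D_struct"); .check_square(D_func, "D_func")
  if (nrow(D_struct) != nrow(D_func))
    stop("distance matrices differ in size", call. = FALSE)
  if (nrow(D_struct) < 3) stop("need at least 3 subjects", call. = FALSE)
  x <- D_struct[upper.tri(D_struct)]
  y <- D_func[upper.tri(D_func)]
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero-variance distance vector: R^2 undefined", call. = FALSE)
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  cor(zx, zy)^2
}

# Normalize a model spec (string or list) to list(name, model, order, P).
.parse_model_spec <- function(spec) {
  if (is.character(spec)) spec <- list(model = spec)
  stopifnot(is.list(spec), !is.null(spec$model))
  model <- spec$model
  if (model %in% mapping_families) {
    order <- if (is.null(spec$order)) 6L else as.integer(spec$order)
    name <- if (is.null(spec$name)) {
      if (model %in% c("heat_kernel", "diffusion_affine")) model
      else sprintf("%s_P%d", model, order)
    } else spec$name
    list(name = name, model = model, order = order, P = NA_integer_)
  } else if (model == "nn_mean") {
    P <- if (is.null(spec$P)) 50L else as.integer(spec$P)
    list(name = if (is.null(spec$name)) sprintf("nn_mean_P%d", P) else spec$name,
         model = model, order = NA_integer_, P = P)
  } else if (model %in% c("riemannian_mean", "euclidean_mean")) {
    list(name = if (is.null(spec$name)) model else spec$name,
         model = model, order = NA_integer_, P = NA_integer_)
  } else stop("unknown model spec: ", model, call. = FALSE)
}

#' Leave-one-out cross-validated model comparison
#'
#' For every subject in turn, each model is trained on the remaining
#' `K - 1` subjects (mapping families are fitted by [fit_mapping()]; the
#' mean references and the nearest-neighbors mean are computed directly),
#' the held-out functional matrix is predicted from the held-out
#' structural matrix, and the squared affine-invariant Riemannian distance
#' between prediction and observation is recorded. The mean of these
#' squared distances over subjects is the model's MSD. The Riemannian
#' Frechet mean reference is always evaluated, as the structure-blind
#' benchmark any mapping must beat.
#'
#' @param model_specs list of model specifications: a family name from
#'   [mapping_families] or `list(model = family, order = P)`,
#'   `"riemannian_mean"`, `"euclidean_mean"`, or
#'   `list(model = "nn_mean", P = p)`.
#' @param ch a [cohort()] with at least two subjects.
#' @param config a [fit_config()] used for every mapping-family fold.
#' @param mean_tol convergence tolerance for Frechet means inside folds.
#' @return An object of class `evaluation_report`: `per_subject` (data
#'   frame with model, subject, squared distance, fold status), `msd`
#'   (data frame of per-model MSD over successful folds), `K`, `M`.
#' @export
loocv_evaluate <- function(model_specs, ch, config = fit_config(),
                           mean_tol = 1e-10) {
  stopifnot(inherits(ch, "cohort"))
  if (ch$K < 2) stop("LOOCV needs at least two subjects", call. = FALSE)
  specs <- lapply(model_specs, .parse_model_spec)
  if (!any(vapply(specs, function(s) s$model == "riemannian_mean", logical(1))))
    specs <- c(specs, list(.parse_model_spec("riemannian_mean")))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs)))
    stop("duplicate model names in model_specs", call. = FALSE)

  rows <- list()
  for (k in seq_len(ch$K)) {
    train_idx <- setdiff(seq_len(ch$K), k)
    train <- cohort(ch$subjects[train_idx], ch$structurals[train_idx],
                    ch$functionals[train_idx], validate = FALSE)
    S_test <- ch$structurals[[k]]
    F_test <- ch$functionals[[k]]
    for (s in specs) {
      res <- tryCatch({
        pred <- switch(s$model,
          riemannian_mean = frechet_mean_riemannian(train$functionals,
                                                    tol = mean_tol),
          euclidean_mean = frechet_mean_euclidean(train$functionals),
          nn_mean = nn_mean_predict(S_test, train, P = min(s$P, train$K),
                                    tol = mean_tol),
          {
            fit <- fit_mapping(s$model, train, order = s$order, config = config)
            predict_functional(fit$params, S_test, repair = TRUE)
          })
        list(d2 = riemannian_distance(pred, F_test)^2, ok = TRUE, msg = NA_character_)
      }, error = function(e) list(d2 = NA_real_, ok = FALSE, msg = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- data.frame(
        model = s$name, subject = ch$subjects[k], sq_distance = res$d2,
        ok = res$ok, message = res$msg, stringsAsFactors = FALSE)
    }
  }
  per_subject <- do.call(rbind, rows)
  msd <- do.call(rbind, lapply(split(per_subject, per_subject$model), function(df) {
    data.frame(model = df$model[1],
               msd = mean(df$sq_distance[df$ok]),
               n_folds = sum(df$ok), n_failed = sum(!df$ok),
               stringsAsFactors = FALSE)
  }))
  msd <- msd[order(msd$msd), , drop = FALSE]
  rownames(msd) <- NULL
  structure(list(per_subject = per_subject, msd = msd, K = ch$K, M = ch$M),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Leave-one-out evaluation: %d subjects, %d regions\n", x$K, x$M))
  cat("Mean squared Riemannian test distance (MSD) per model:\n")
  print(x$msd, row.names = FALSE)
  invisible(x)
}

#' Per-model MSD of an evaluation report
#'
#' @param report an `evaluation_report`.
#' @param model model name; `NULL` returns the full MSD table.
#' @return A scalar MSD, or the MSD data frame.
#' @export
report_msd <- function(report, model = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (is.null(model)) return(report$msd)
  i <- match(model, report$msd$model)
  if (is.na(i)) stop("model not in report: ", model, call. = FALSE)
  report$msd$msd[i]
}
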