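# Standardization, PCA and symmetric gridding of the score space.

#' Fit column standardization (mean-centre, unit variance)
#'
#' @param X Numeric matrix (n x p, n >= 2). Columns should be named.
#' @return Object of class `scaling_model` with `means` and `sds`
#'   (sample sd, n-1 denominator).
#' @export
fit_scaling <- function(X) {
  X <- as.matrix(X)
  check_that(is.numeric(X) && nrow(X) >= 2, "validation",
             "need a numeric matrix with at least two rows")
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  const <- which(sds == 0 | !is.finite(sds))
  if (length(const) > 0L) {
    nm <- colnames(X)[const] %||% as.character(const)
    mcl_stop("validation",
             sprintf("constant column(s) cannot be scaled: %s",
                     paste(nm, collapse = ", ")), variables = nm)
  }
  structure(list(means = means, sds = sds), class = "scaling_model")
}

#' Apply a fitted standardization
#'
#' @param X Numeric matrix with the same columns the model was fit on.
#' @param model A `scaling_model`.
#' @return Standardized matrix `Z`.
#' @export
apply_scaling <- function(X, model) {
  stopifnot(inherits(model, "scaling_model"))
  X <- as.matrix(X)
  check_that(ncol(X) == length(model$means), "validation",
             "column count does not match the scaling model")
  sweep(sweep(X, 2, model$means, "-"), 2, model$sds, "/")
}

#' Fit PCA on a standardized matrix
#'
#' Computed by singular value decomposition. Deterministic sign
#' convention: within each component the largest-magnitude loading entry
#' is made positive, so results are platform-independent.
#'
#' @param Z Standardized numeric matrix (n x p).
#' @param k Number of components to retain (k <= rank(Z)).
#' @return Object of class `pca_model`: `loadings` (p x k, orthonormal
#'   columns), `explained_variance` (k, non-increasing),
#'   `explained_ratio` (k, shares of TOTAL variance over all p
#'   components).
#' @export
fit_pca <- function(Z, k) {
  Z <- as.matrix(Z)
  check_that(is_count(k) && k <= ncol(Z), "config",
             sprintf("k must be a positive integer <= %d", ncol(Z)))
  n <- nrow(Z)
  check_that(n >= 2, "validation", "need at least two rows")
  sv <- svd(Z)
  tol <- max(dim(Z)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  check_that(k <= rank, "validation",
             sprintf("k = %d exceeds matrix rank %d", k, rank))
  ev_all <- sv$d^2 / (n - 1)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest |loading| per component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- colnames(Z)
  colnames(loadings) <- paste0("pc", seq_len(k))
  structure(list(loadings = loadings,
                 explained_variance = ev_all[seq_len(k)],
                 explained_ratio = ev_all[seq_len(k)] / sum(ev_all),
                 total_variance = sum(ev_all)),
            class = "pca_model")
}

#' Project a standardized matrix onto PCA components
#'
#' @param Z Standardized matrix with the columns the model was fit on.
#' @param model A `pca_model`.
#' @return Score matrix (n x k), columns `pc1..pck`.
#' @export
project_scores <- function(Z, model) {
  stopifnot(inherits(model, "pca_model"))
  Z <- as.matrix(Z)
  check_that(ncol(Z) == nrow(model$loadings), "validation",
             "column count does not match the PCA model")
  S <- Z %*% model$loadings
  colnames(S) <- colnames(model$loadings)
  S
}

#' Build a symmetric grid over the score space
#'
#' "Symmetric" means the same number of equal-width bins on every
#' retained score axis, spanning the observed score range per axis.
#'
#' @param scores Score matrix (n x k).
#' @param bins_per_axis Positive integer, identical for every axis.
#' @return Object of class `grid_spec`: `k`, `bins_per_axis`, and
#'   `edges` (list of k strictly increasing numeric vectors of length
#'   `bins_per_axis + 1`).
#' @export
build_grid <- function(scores, bins_per_axis = 20L) {
  scores <- as.matrix(scores)
  check_that(nrow(scores) >= 1, "validation", "scores must be non-empty")
  check_that(is_count(bins_per_axis), "config",
             "bins_per_axis must be a positive integer")
  edges <- lapply(seq_len(ncol(scores)), function(j) {
    lo <- min(scores[, j]); hi <- max(scores[, j])
    if (hi <= lo) { lo <- lo - 0.5; hi <- hi + 0.5 }  # degenerate axis
    seq(lo, hi, length.out = bins_per_axis + 1L)
  })
  names(edges) <- colnames(scores)
  structure(list(k = ncol(scores), bins_per_axis = as.integer(bins_per_axis),
                 edges = edges), class = "grid_spec")
}

#' Assign score rows to grid cells
#'
#' Bin convention: interior edges belong to the higher-ordinal bin; the
#' maximum edge belongs to the last bin. Scores outside the grid range
#' (new data) are clamped to the nearest boundary bin and counted on the
#' `"clamped"` attribute.
#'
#' @param scores Score matrix or single row (n x k).
#' @param grid A `grid_spec`.
#' @return Integer matrix (n x k) of 0-based bin ordinals, with attribute
#'   `clamped` = number of coordinates that fell outside the grid.
#' @export
assign_cell <- function(scores, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  scores <- if (is.null(dim(scores))) matrix(scores, nrow = 1)
            else as.matrix(scores)
  check_that(ncol(scores) == grid$k, "validation",
             sprintf("scores have %d axes, grid expects %d",
                     ncol(scores), grid$k))
  nb <- grid$bins_per_axis
  out <- matrix(0L, nrow(scores), grid$k)
  clamped <- 0L
  for (j in seq_len(grid$k)) {
    e <- grid$edges[[j]]
    # findInterval: e[i] <= x < e[i+1] -> i, so an interior edge already
    # lands in the higher bin; the max edge returns nb+1 and is clamped
    # into the last bin by design (not counted as out-of-range).
    idx <- findInterval(scores[, j], e)
    below <- idx < 1L; above <- scores[, j] > e[length(e)]
    clamped <- clamped + sum(below) + sum(above)
    idx[idx > nb] <- nb
    idx[below] <- 1L
    out[, j] <- idx - 1L
  }
  if (clamped > 0L) {
    mcl_log("warn", "%d score coordinate(s) outside grid range; clamped",
            clamped)
  }
  colnames(out) <- names(grid$edges)
  attr(out, "clamped") <- clamped
  out
}

#' Flatten cell ordinals to a single sortable key
#'
#' @param cells Integer matrix of 0-based ordinals from [assign_cell()].
#' @return Character vector like `"03:17:04"`, which sorts
#'   lexicographically in cell-index order.
#' @export
cell_key <- function(cells) {
  cells <- if (is.null(dim(cells))) matrix(cells, nrow = 1) else cells
  apply(cells, 1, function(r) paste(sprintf("%03d", r), collapse = ":"))
}

#' Centre point of a grid cell
#' @param cell Integer vector of 0-based ordinals.
#' @param grid A `grid_spec`.
#' @return Numeric vector of length `k`.
#' @export
cell_centroid <- function(cell, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  vapply(seq_len(grid$k), function(j) {
    e <- grid$edges[[j]]
    (e[cell[j] + 1L] + e[cell[j] + 2L]) / 2
  }, numeric(1))
}

# ---- model serialization ----------------------------------------------

#' Write the fitted chemical-space model to a single JSON document
#'
#' Stores means, sds, loadings, explained variance/ratio and grid edges,
#' enough to reproduce scaling, projection and cell assignment.
#'
#' @param path Output file path.
#' @param scaling A `scaling_model`.
#' @param pca A `pca_model`.
#' @param grid A `grid_spec`.
#' @export
write_chemspace_model <- function(path, scaling, pca, grid) {
  stopifnot(inherits(scaling, "scaling_model"), inherits(pca, "pca_model"),
            inherits(grid, "grid_spec"))
  doc <- list(
    variables = names(scaling$means),
    means = unname(scaling$means), sds = unname(scaling$sds),
    loadings = unname(pca$loadings),
    explained_variance = pca$explained_variance,
    explained_ratio = pca$explained_ratio,
    total_variance = pca$total_variance,
    grid = list(k = grid$k, bins_per_axis = grid$bins_per_axis,
                edges = grid$edges)
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a chemical-space model written by [write_chemspace_model()]
#'
#' @param path JSON file path.
#' @return List with `scaling`, `pca` and `grid` components.
#' @export
read_chemspace_model <- function(path) {
  check_that(file.exists(path), "config",
             sprintf("model file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaling <- structure(list(
    means = stats::setNames(doc$means, doc$variables),
    sds = stats::setNames(doc$sds, doc$variables)), class = "scaling_model")
  loadings <- as.matrix(doc$loadings)
  rownames(loadings) <- doc$variables
  colnames(loadings) <- paste0("pc", seq_len(ncol(loadings)))
  pca <- structure(list(loadings = loadings,
                        explained_variance = doc$explained_variance,
                        explained_ratio = doc$explained_ratio,
                        total_variance = doc$total_variance),
                   class = "pca_model")
  edges <- lapply(doc$grid$edges, as.numeric)
  grid <- structure(list(k = as.integer(doc$grid$k),
                         bins_per_axis = as.integer(doc$grid$bins_per_axis),
                         edges = edges), class = "grid_spec")
  list(scaling = scaling, pca = pca, grid = grid)
}
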