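# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (set arithmetic, eigendecomposition, all-pairs
# loops) and never call the code paths they check.

# set-arithmetic Jaccard distance
brute_jaccard <- function(a, b) {
  sa <- which(as.logical(a)); sb <- which(as.logical(b))
  1 - length(intersect(sa, sb)) / length(union(sa, sb))
}

# continuous Tanimoto from the definition, scalar arithmetic
brute_tanimoto <- function(x, y) {
  dot <- sum(x * y)
  1 - dot / (sum(x^2) + sum(y^2) - dot)
}

# PCA via eigendecomposition of the sample covariance matrix
brute_pca <- function(Z, k) {
  C <- stats::cov(Z)
  e <- eigen(C, symmetric = TRUE)
  load <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  list(loadings = load, explained_variance = e$values[seq_len(k)],
       total = sum(e$values))
}

# all-pairs distance matrix (naive double loop)
brute_all_pairs <- function(V, metric = c("tanimoto", "jaccard")) {
  metric <- match.arg(metric)
  f <- if (metric == "tanimoto") brute_tanimoto else brute_jaccard
  n <- nrow(V)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) D[i, j] <- D[j, i] <- f(V[i, ], V[j, ])
  }
  D
}

# frozen independent descriptor values (computed once with RDKit
# 2024.09.2 on the embedded SMILES library; see descriptors-expected.csv)
descriptor_expected <- function() {
  utils::read.csv(test_path("descriptors-expected.csv"),
                  stringsAsFactors = FALSE)
}

# standardized fixture matrix + derived spaces, shared by sampler tests
make_space <- function(n = 500, seed = 7, ...) {
  gen <- generate_feature_table(fixture_spec(n, seed = seed, ...))
  X <- as.matrix(gen$features[, -1])
  rownames(X) <- gen$features$id
  sc <- fit_scaling(X)
  Z <- apply_scaling(X, sc)
  pca <- fit_pca(Z, 3)
  S <- project_scores(Z, pca)
  rownames(S) <- gen$features$id
  grid <- build_grid(S, 10)
  list(gen = gen, X = X, Z = Z, pca = pca, S = S, grid = grid)
}
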