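# Standardization, PCA and the symmetric score-space grid.

test_that("fit/apply scaling standardizes to mean 0, sd 1", {
  set.seed(5)
  X <- matrix(rnorm(40 * 13, mean = 3, sd = 4), 40, 13,
              dimnames = list(NULL, paste0("v", 1:13)))
  Z <- apply_scaling(X, fit_scaling(X))
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-8))
  # idempotence: standardizing a standardized matrix is the identity
  Z2 <- apply_scaling(Z, fit_scaling(Z))
  expect_equal(Z2, Z, tolerance = 1e-8)
})

test_that("two-row scaling gives the closed-form +-1/sqrt(2)", {
  X <- matrix(c(1, 3, 10, -10), 2, 2)
  Z <- apply_scaling(X, fit_scaling(X))
  expect_equal(abs(unname(Z)),
               matrix(1 / sqrt(2), 2, 2), tolerance = 1e-12)
  expect_equal(sign(Z[, 1]), c(-1, 1))
})

test_that("constant columns are rejected by name", {
  X <- cbind(a = rnorm(10), b = rep(5, 10))
  err <- expect_error(fit_scaling(X), class = "mcl_validation_error")
  expect_match(conditionMessage(err), "b")
})

test_that("PCA matches the eigendecomposition oracle on small matrices", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    Z <- scale(matrix(rnorm(n * 4), n, 4))
    attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
    k <- min(3, n - 1)
    fit <- fit_pca(Z, k)
    ora <- brute_pca(Z, k)
    expect_equal(fit$explained_variance, ora$explained_variance[1:k],
                 tolerance = 1e-8)
    expect_equal(fit$loadings, ora$loadings, tolerance = 1e-8,
                 ignore_attr = TRUE)
    # score variance equals explained variance
    S <- project_scores(Z, fit)
    expect_equal(unname(apply(S, 2, var)), fit$explained_variance,
                 tolerance = 1e-8)
  }
})

test_that("explained ratios sum to 1 over all components", {
  set.seed(29)
  Z <- scale(matrix(rnorm(50 * 13), 50, 13))
  fit <- fit_pca(Z, 13)
  expect_equal(sum(fit$explained_ratio), 1, tolerance = 1e-8)
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
  # orthonormal loadings
  expect_equal(crossprod(fit$loadings), diag(13), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full reconstruction round-trip
  S <- project_scores(Z, fit)
  expect_equal(S %*% t(fit$loadings), unclass(Z), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a dominant planted direction captures >99% variance", {
  set.seed(41)
  t <- rnorm(200)
  dir <- rnorm(13); dir <- dir / sqrt(sum(dir^2))
  Z <- t %*% t(dir) + matrix(rnorm(200 * 13, sd = 0.01), 200, 13)
  fit <- fit_pca(Z, 2)
  expect_gt(fit$explained_ratio[1], 0.99)
})

test_that("k above the matrix rank is an error", {
  Z <- matrix(rnorm(6), 3, 2)
  Z <- cbind(Z, Z[, 1] + Z[, 2])   # rank 2
  Z <- scale(Z)
  expect_error(fit_pca(Z, 3), class = "mcl_validation_error")
})

test_that("grid bin conventions: single cell, edges to the higher bin", {
  S <- matrix(c(0, 1, 0.4, 2, 1, 3), ncol = 2)
  g1 <- build_grid(S, 1)
  expect_true(all(assign_cell(S, g1) == 0L))

  g <- build_grid(matrix(seq(0, 10, length.out = 11), ncol = 1), 10)
  # interior edge value 3 belongs to bin ordinal 3 (bins are [i, i+1))
  expect_equal(as.vector(assign_cell(matrix(3), g)), 3L)
  # the max edge belongs to the last bin
  expect_equal(as.vector(assign_cell(matrix(10), g)), 9L)
  # out-of-range points clamp with a counter
  res <- assign_cell(matrix(c(-5, 15), ncol = 1), g)
  expect_equal(as.vector(res), c(0L, 9L))
  expect_equal(attr(res, "clamped"), 2L)
})

test_that("1000 random points land inside their assigned cell bounds", {
  set.seed(59)
  S <- matrix(runif(1000 * 2, -3, 7), ncol = 2)
  grid <- build_grid(S, 10)
  cells <- assign_cell(S, grid)
  for (j in 1:2) {
    e <- grid$edges[[j]]
    lo <- e[cells[, j] + 1L]; hi <- e[cells[, j] + 2L]
    last <- cells[, j] == grid$bins_per_axis - 1L
    inside <- S[, j] >= lo & (S[, j] < hi | (last & S[, j] <= hi))
    expect_true(all(inside))
  }
  # the cell assignment partitions the dataset
  expect_equal(sum(table(cell_key(cells))), nrow(S))
})

test_that("the chemspace model round-trips through JSON", {
  sp <- make_space(n = 80, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_chemspace_model(path, fit_scaling(sp$X), sp$pca, sp$grid)
  m <- read_chemspace_model(path)
  expect_equal(m$scaling$means, fit_scaling(sp$X)$means)
  expect_equal(unname(m$pca$loadings), unname(sp$pca$loadings),
               tolerance = 1e-12)
  expect_equal(m$grid$bins_per_axis, sp$grid$bins_per_axis)
  expect_equal(m$grid$edges, sp$grid$edges, tolerance = 1e-12,
               ignore_attr = TRUE)
  # projections through the reloaded model agree
  Z <- apply_scaling(sp$X, m$scaling)
  expect_equal(unname(project_scores(Z, m$pca)), unname(sp$S),
               tolerance = 1e-10)
})
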