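# Coverage diagnostics, RI/mass regression, availability adapter.

test_that("coverage is 1 for the full set, 0 for the empty list", {
  sp <- make_space(n = 200, seed = 37)
  full <- coverage_metrics(rownames(sp$S), sp$S, sp$grid)
  expect_equal(full$coverage_fraction, 1)
  expect_equal(full$cells_hit_by_list, full$occupied_cells_total)
  empty <- coverage_metrics(character(), sp$S, sp$grid)
  expect_equal(empty$cells_hit_by_list, 0L)
  expect_equal(empty$coverage_fraction, 0)
  expect_error(coverage_metrics("ghost", sp$S, sp$grid),
               class = "mcl_validation_error")
})

test_that("a constructed 7-of-10-cells fixture gives fraction 0.7", {
  # 10 points on a line, 10 bins -> one point per cell
  S <- matrix(seq(0.5, 9.5, by = 1), ncol = 1,
              dimnames = list(sprintf("p%02d", 1:10), "pc1"))
  grid <- build_grid(S, 10)
  rep <- coverage_metrics(sprintf("p%02d", 1:7), S, grid)
  expect_equal(rep$occupied_cells_total, 10L)
  expect_equal(rep$cells_hit_by_list, 7L)
  expect_equal(rep$coverage_fraction, 0.7)
})

test_that("coverage carries class counts, mass and RI summaries", {
  sp <- make_space(n = 150, seed = 43)
  ids <- rownames(sp$S)[1:40]
  ri <- setNames(runif(150, 0, 1000), rownames(sp$S))
  rep <- coverage_metrics(ids, sp$S, sp$grid,
                          features = sp$gen$features, ri = ri)
  expect_equal(sum(rep$per_class_counts), 40L)
  expect_true(rep$mass_range[1] <= rep$mass_range[2])
  expect_equal(sum(rep$rplc_counts), 40L)
})

test_that("compare_lists matches brute-force set arithmetic", {
  sp <- make_space(n = 200, seed = 47)
  ids <- rownames(sp$S)
  a <- ids[1:60]; b <- ids[41:120]
  cmp <- compare_lists(a, b, sp$S, sp$grid)
  keys <- cell_key(assign_cell(sp$S, sp$grid))
  ca <- unique(keys[match(a, ids)]); cb <- unique(keys[match(b, ids)])
  expect_setequal(cmp$cells_a_not_b, setdiff(ca, cb))
  expect_setequal(cmp$cells_b_not_a, setdiff(cb, ca))
  # identical lists differ in zero cells
  same <- compare_lists(a, a, sp$S, sp$grid)
  expect_equal(same$n_a_not_b, 0L)
  expect_equal(same$n_b_not_a, 0L)
})

test_that("coverage fraction is monotone under list union", {
  sp <- make_space(n = 200, seed = 53)
  ids <- rownames(sp$S)
  a <- sample(ids, 30); b <- sample(ids, 30)
  fa <- coverage_metrics(a, sp$S, sp$grid)$coverage_fraction
  fu <- coverage_metrics(union(a, b), sp$S, sp$grid)$coverage_fraction
  expect_gte(fu, fa)
})

test_that("ri_mass_regression: collinear, closed form, degenerate", {
  m <- c(100, 200, 300, 400)
  expect_equal(ri_mass_regression(m, 2 * m + 5)$r_squared, 1,
               tolerance = 1e-12)

  # closed-form normal equations on 5 hand points
  mass <- c(110, 230, 370, 540, 820)
  ri <- c(120, 300, 260, 510, 700)
  fit <- ri_mass_regression(mass, ri)
  sxx <- sum((mass - mean(mass))^2)
  sxy <- sum((mass - mean(mass)) * (ri - mean(ri)))
  slope <- sxy / sxx
  intercept <- mean(ri) - slope * mean(mass)
  expect_equal(fit$slope, slope, tolerance = 1e-10)
  expect_equal(fit$intercept, intercept, tolerance = 1e-10)
  r2 <- sxy^2 / (sxx * sum((ri - mean(ri))^2))
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)

  expect_error(ri_mass_regression(c(1, 2), c(1, 2)),
               class = "mcl_validation_error")
  expect_error(ri_mass_regression(rep(5, 10), rnorm(10)),
               class = "mcl_validation_error")
})

test_that("availability: file adapter, fraction, unknown ids", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(id = sprintf("a%02d", 1:10),
                   patent_count = c(3, 0, 1, 0, 2, 0, 5, 1, 0, 4),
                   literature_count = c(0, 0, 0, 2, 0, 0, 1, 0, 0, 0))
  write.csv(df, path, row.names = FALSE)
  ad <- file_availability_adapter(path)
  res <- availability_counts(df$id, ad)
  # 7 of 10 have any record
  expect_equal(sum(res$available), 7L)
  expect_equal(attr(res, "fraction_available"), 0.7)
  expect_true(res$available[1])    # (3, 0) -> available
  expect_false(res$available[2])   # (0, 0) -> not

  # unresolved ids become unknown and do not stop the run
  res2 <- availability_counts(c("a01", "ghost"), ad)
  expect_true(is.na(res2$available[2]))
  expect_equal(attr(res2, "fraction_available"), 1)
})
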