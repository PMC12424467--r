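# The selection cascade.

test_that("grid_sample conserves, caps by centroid distance, determinism", {
  sp <- make_space(n = 300, seed = 13)
  out <- grid_sample(sp$S, sp$grid, Inf)
  # cap unlimited: a permutation of all inputs grouped by cell
  expect_setequal(out$id, rownames(sp$S))
  expect_false(is.unsorted(out$cell_index))

  # cap = 1: the survivor of each cell is the one nearest its centroid
  capped <- grid_sample(sp$S, sp$grid, 1)
  cells <- assign_cell(sp$S, sp$grid)
  keys <- cell_key(cells)
  expect_equal(nrow(capped), length(unique(keys)))
  for (i in seq_len(nrow(capped))) {
    key <- capped$cell_index[i]
    members <- rownames(sp$S)[keys == key]
    cen <- cell_centroid(cells[match(members[1], rownames(sp$S)), ],
                         sp$grid)
    d <- sqrt(colSums((t(sp$S[members, , drop = FALSE]) - cen)^2))
    expect_equal(unname(d[capped$id[i]]), min(d), tolerance = 1e-12)
  }

  # determinism
  expect_identical(out, grid_sample(sp$S, sp$grid, Inf))
  # empty input
  e <- grid_sample(matrix(numeric(), 0, 3), sp$grid)
  expect_equal(nrow(e), 0L)
})

test_that("dissimilarity filter: degenerate and trivial cases", {
  V <- matrix(1, 5, 3, dimnames = list(paste0("c", 1:5), NULL))
  kept <- dissimilarity_filter(rownames(V), V, 0.15)
  expect_equal(as.character(kept), "c1")   # all identical -> 1 retained

  set.seed(71)
  W <- diag(6) * 5
  rownames(W) <- paste0("d", 1:6)
  kept2 <- dissimilarity_filter(rownames(W), W, 0.15)
  expect_length(kept2, 6L)                 # orthogonal: all retained

  # all-zero vector skipped with a warning count
  V0 <- rbind(V, z = 0)
  kept3 <- dissimilarity_filter(rownames(V0), V0, 0.15)
  expect_equal(attr(kept3, "skipped"), 1L)
  expect_false("z" %in% kept3)
})

test_that("greedy retention passes the all-pairs + maximality oracle", {
  set.seed(83)
  for (rep in 1:5) {
    V <- matrix(rnorm(60 * 5), 60, 5)
    rownames(V) <- sprintf("v%02d", 1:60)
    thr <- 0.4
    kept <- dissimilarity_filter(rownames(V), V, thr)
    D <- brute_all_pairs(V, "tanimoto")
    ki <- match(kept, rownames(V))
    if (length(ki) > 1) {
      expect_true(all(D[ki, ki][upper.tri(D[ki, ki])] > thr))
    }
    rejected <- setdiff(rownames(V), kept)
    for (r in rejected) {
      expect_true(any(D[match(r, rownames(V)), ki] <= thr), info = r)
    }
  }
})

test_that("greedy prefix property: lower threshold keeps early survivors", {
  set.seed(89)
  V <- matrix(rnorm(80 * 5), 80, 5)
  rownames(V) <- sprintf("v%02d", 1:80)
  hi <- dissimilarity_filter(rownames(V), V, 0.5)
  lo <- dissimilarity_filter(rownames(V), V, 0.2)
  # the scan head is threshold-independent
  expect_identical(hi[1], lo[1])
  # the set retained at the higher threshold stays eligible at the
  # lower one: all its pairwise distances still exceed it
  hv <- V[as.character(hi), , drop = FALSE]
  D <- brute_all_pairs(hv, "tanimoto")
  expect_true(all(D[upper.tri(D)] > 0.2))
  # a weaker constraint never empties the list relative to a stronger one
  expect_gte(length(lo), length(hi))
})

test_that("esi_filter applies strict LogIE bounds and the donor rule", {
  cand <- data.frame(
    id = c("a", "b", "c", "d", "e", "f"),
    log_ie = c(3.5, 3.5001, 1.2, 1.2, 1.5, NA),
    hbd = c(1, 0, 0, 2, 3, 1),
    mobility_class = 1)
  cfg <- selection_config()
  pos <- esi_filter(cand, "positive", cfg)
  expect_equal(pos$id, "b")              # 3.5 exactly is excluded
  neg <- esi_filter(cand, "negative", cfg)
  expect_equal(neg$id, "d")              # 1.5 exactly and hbd=0 excluded
  expect_equal(attr(neg, "dropped_missing"), 1L)
})

test_that("rank_and_select groups by class, ranks by descending LogIE", {
  set.seed(101)
  f <- data.frame(id = sprintf("r%03d", 1:180),
                  mobility_class = rep(1:3, each = 60),
                  log_ie = runif(180, 3.6, 6))
  sel <- rank_and_select(f, "positive", 50)
  expect_equal(nrow(sel), 150L)
  expect_equal(sel$rank, 1:150)
  expect_equal(sel$mobility_class, rep(1:3, each = 50))
  for (cls in 1:3) {
    sub <- sel[sel$mobility_class == cls, ]
    expect_true(all(diff(sub$log_ie) <= 0))
    # the selected are the top-50 of their class
    top <- sort(f$log_ie[f$mobility_class == cls],
                decreasing = TRUE)[1:50]
    expect_equal(sort(sub$log_ie, decreasing = TRUE), top)
  }
  # descending tie broken by id, lexicographic
  t2 <- data.frame(id = c("zz", "aa"), mobility_class = 1,
                   log_ie = c(4.4, 4.4))
  expect_equal(rank_and_select(t2, "positive", 2)$id, c("aa", "zz"))
  # 4.8 before 4.2
  t3 <- data.frame(id = c("x", "y"), mobility_class = 2,
                   log_ie = c(4.2, 4.8))
  expect_equal(rank_and_select(t3, "positive", 2)$id, c("y", "x"))
})

test_that("shortfall classes contribute all members with a warning", {
  f <- data.frame(id = sprintf("s%02d", 1:10), mobility_class = 1,
                  log_ie = runif(10, 4, 5))
  sel <- rank_and_select(f, "positive", 50)
  expect_equal(nrow(sel), 10L)
  expect_equal(unname(attr(sel, "shortfall")), c(40L, 50L, 50L))
})

test_that("build_mcl composes the cascade and keeps polarities disjoint", {
  sp <- make_space(n = 800, seed = 17)
  cfg <- selection_config(per_class_n = 10)
  res <- build_mcl(NULL, sp$gen$features, sp$S, sp$grid, cfg,
                   scaled = sp$Z)
  expect_equal(nrow(res$positive), 30L)
  expect_equal(nrow(res$negative), 30L)
  expect_length(intersect(res$positive$id, res$negative$id), 0L)
  # every entry id exists in the input and is unique within polarity
  expect_true(all(res$positive$id %in% sp$gen$features$id))
  expect_false(anyDuplicated(res$positive$id) > 0)
  # entries satisfy their polarity's filter
  expect_true(all(res$positive$log_ie > cfg$logie_pos_min))
  expect_true(all(res$negative$log_ie < cfg$logie_neg_max))
  hbd <- sp$gen$features$hbd[match(res$negative$id, sp$gen$features$id)]
  expect_true(all(hbd >= 1))
  # all-pairs distance criterion holds post-hoc on each emitted MCL
  for (mcl in list(res$positive, res$negative)) {
    V <- sp$Z[mcl$id, , drop = FALSE]
    D <- brute_all_pairs(V, "tanimoto")
    expect_true(all(D[upper.tri(D)] > cfg$distance_threshold))
  }
  # empty input gives two empty lists without error
  e <- build_mcl(NULL, sp$gen$features[0, ],
                 sp$S[0, , drop = FALSE], sp$grid, cfg)
  expect_equal(nrow(e$positive), 0L)
  expect_equal(nrow(e$negative), 0L)
})

test_that("build_mcl agrees with a brute-force cascade reimplementation", {
  sp <- make_space(n = 250, seed = 19)
  cfg <- selection_config(per_class_n = 5)
  res <- build_mcl(NULL, sp$gen$features, sp$S, sp$grid, cfg,
                   scaled = sp$Z)

  # independent reimplementation: sort ids by (cell key, centroid
  # distance, id); greedy all-pairs scan; inequality filters; per-class
  # top-n by log_ie
  cells <- assign_cell(sp$S, sp$grid)
  keys <- cell_key(cells)
  cen_d <- vapply(seq_len(nrow(sp$S)), function(i) {
    sqrt(sum((sp$S[i, ] - cell_centroid(cells[i, ], sp$grid))^2))
  }, numeric(1))
  ord <- order(keys, cen_d, rownames(sp$S), method = "radix")
  ids <- rownames(sp$S)[ord]
  kept <- character()
  for (id in ids) {
    x <- sp$Z[id, ]
    ok <- TRUE
    for (kid in kept) {
      if (brute_tanimoto(x, sp$Z[kid, ]) <= cfg$distance_threshold) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, id)
  }
  feats <- sp$gen$features[match(kept, sp$gen$features$id), ]
  pick <- function(sub) {
    out <- character()
    for (cls in 1:3) {
      s <- sub[sub$mobility_class == cls, ]
      s <- s[order(-s$log_ie, s$id, method = "radix"), ]
      out <- c(out, head(s$id, cfg$per_class_n))
    }
    out
  }
  exp_pos <- pick(feats[feats$log_ie > cfg$logie_pos_min, ])
  exp_neg <- pick(feats[feats$log_ie < cfg$logie_neg_max &
                          feats$hbd >= cfg$hbd_min_neg, ])
  expect_identical(res$positive$id, exp_pos)
  expect_identical(res$negative$id, exp_neg)
})

test_that("raising logie_pos_min never adds a positive candidate", {
  sp <- make_space(n = 400, seed = 23)
  lo <- build_mcl(NULL, sp$gen$features, sp$S, sp$grid,
                  selection_config(logie_pos_min = 3.5, per_class_n = 20),
                  scaled = sp$Z)
  hi <- build_mcl(NULL, sp$gen$features, sp$S, sp$grid,
                  selection_config(logie_pos_min = 4.5, per_class_n = 20),
                  scaled = sp$Z)
  # the stricter filter's eligible pool is a subset of the looser one's
  pool_lo <- sp$gen$features$id[sp$gen$features$log_ie > 3.5]
  expect_true(all(hi$positive$id %in% pool_lo))
  expect_true(all(hi$positive$log_ie > 4.5))
})

test_that("MCL files are byte-identical across repeated runs", {
  sp <- make_space(n = 400, seed = 29)
  cfg <- selection_config(per_class_n = 10)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  for (p in c(p1, p2)) {
    res <- build_mcl(NULL, sp$gen$features, sp$S, sp$grid, cfg,
                     scaled = sp$Z)
    write_mcl(p, res$positive)
  }
  expect_identical(readLines(p1), readLines(p2))
})
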