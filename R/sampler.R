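# The selection cascade: grid sampling -> dissimilarity filter -> ESI
# eligibility filters -> mobility grouping -> ranked MCL assembly.

#' Selection configuration
#'
#' Thresholds follow the published criteria: retain structures with
#' pairwise distance > 0.15; ESI(+) requires LogIE > 3.5; ESI(-) requires
#' LogIE < 1.5 and at least one H-bond donor. All inequalities are strict
#' on LogIE.
#'
#' @param per_cell_cap Max candidates taken per occupied grid cell
#'   (`Inf` = unlimited, the default).
#' @param distance_threshold Dissimilarity threshold (default 0.15).
#' @param distance_metric `"continuous_tanimoto_on_features"` (default;
#'   distances on the scaled 13-variable vectors) or
#'   `"jaccard_on_fingerprints"`.
#' @param logie_pos_min ESI(+) lower LogIE bound (default 3.5, strict).
#' @param logie_neg_max ESI(-) upper LogIE bound (default 1.5, strict).
#' @param hbd_min_neg Minimum H-bond donor count for ESI(-) (default 1).
#' @param per_class_n Candidates selected per mobility class (default 50,
#'   giving 150-entry lists over the three classes).
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(per_cell_cap = Inf,
                             distance_threshold = 0.15,
                             distance_metric = c(
                               "continuous_tanimoto_on_features",
                               "jaccard_on_fingerprints"),
                             logie_pos_min = 3.5,
                             logie_neg_max = 1.5,
                             hbd_min_neg = 1L,
                             per_class_n = 50L) {
  distance_metric <- match.arg(distance_metric)
  check_that(is.numeric(per_cell_cap) && length(per_cell_cap) == 1L &&
               (is.infinite(per_cell_cap) || is_count(per_cell_cap)),
             "config", "per_cell_cap must be a positive integer or Inf")
  check_that(is.finite(distance_threshold) && is.finite(logie_pos_min) &&
               is.finite(logie_neg_max), "config",
             "thresholds must be finite")
  check_that(is_count(per_class_n), "config", "per_class_n must be >= 1")
  structure(list(per_cell_cap = per_cell_cap,
                 distance_threshold = distance_threshold,
                 distance_metric = distance_metric,
                 logie_pos_min = logie_pos_min,
                 logie_neg_max = logie_neg_max,
                 hbd_min_neg = as.integer(hbd_min_neg),
                 per_class_n = as.integer(per_class_n)),
            class = "selection_config")
}

# deterministic C-locale ordering for id tie-breaks
.lex_order <- function(...) order(..., method = "radix")

#' Sample candidates from the score-space grid
#'
#' From each occupied cell, up to `per_cell_cap` members are chosen by
#' ascending Euclidean distance to the cell centroid (ties by id,
#' lexicographic). The global candidate order is cell index
#' (lexicographic) then within-cell order, making the downstream greedy
#' filter deterministic.
#'
#' @param scores Score matrix (n x k) with compound ids as rownames.
#' @param grid A `grid_spec` built on the same scores.
#' @param per_cell_cap Positive integer or `Inf`.
#' @return Data frame `id`, `cell_index` (string key), in selection
#'   order. Empty input gives an empty frame.
#' @export
grid_sample <- function(scores, grid, per_cell_cap = Inf) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) {
    return(data.frame(id = character(), cell_index = character()))
  }
  check_that(!is.null(rownames(scores)), "validation",
             "scores must carry compound ids as rownames")
  cells <- assign_cell(scores, grid)
  keys <- cell_key(cells)
  ids <- rownames(scores)
  pieces <- list()
  for (key in sort(unique(keys))) {
    sel <- which(keys == key)
    cen <- cell_centroid(cells[sel[1], ], grid)
    d <- sqrt(colSums((t(scores[sel, , drop = FALSE]) - cen)^2))
    ord <- .lex_order(d, ids[sel])
    take <- utils::head(ord, if (is.finite(per_cell_cap)) per_cell_cap
                             else length(ord))
    pieces[[key]] <- data.frame(id = ids[sel][take], cell_index = key,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Greedy dissimilarity filter
#'
#' Scans candidates in their given (deterministic) order, keeping each
#' one iff its distance to EVERY previously kept candidate exceeds the
#' threshold. The retained set therefore satisfies the all-pairs
#' criterion, and every rejected candidate lies within the threshold of
#' at least one retained candidate (maximality).
#'
#' @param candidate_ids Ordered character vector of candidate ids.
#' @param vectors Numeric matrix, rows named by id: scaled feature
#'   vectors (continuous Tanimoto) or fingerprint bits (Jaccard).
#' @param threshold Distance threshold (retain iff distance > threshold).
#' @param metric `"continuous_tanimoto"` or `"jaccard"`.
#' @return Character vector of retained ids (in scan order), with
#'   attribute `skipped` = count of candidates with undefined distance
#'   (degenerate all-zero vectors).
#' @export
dissimilarity_filter <- function(candidate_ids, vectors, threshold = 0.15,
                                 metric = c("continuous_tanimoto",
                                            "jaccard")) {
  metric <- match.arg(metric)
  check_that(all(candidate_ids %in% rownames(vectors)), "validation",
             "every candidate id needs a row in `vectors`")
  V <- as.matrix(vectors)[candidate_ids, , drop = FALSE]
  if (metric == "jaccard") V <- (V != 0) * 1
  sq <- rowSums(V^2)
  kept <- integer(0)
  skipped <- 0L
  for (i in seq_along(candidate_ids)) {
    if (sq[i] == 0) {            # degenerate: distance undefined
      skipped <- skipped + 1L
      next
    }
    ok <- if (length(kept) == 0L) TRUE else {
      dots <- as.numeric(V[kept, , drop = FALSE] %*% V[i, ])
      d <- if (metric == "jaccard") {
        un <- sq[kept] + sq[i] - dots
        1 - dots / un
      } else {
        1 - dots / (sq[kept] + sq[i] - dots)
      }
      all(d > threshold)
    }
    if (ok) kept <- c(kept, i)
  }
  if (skipped > 0L) {
    mcl_log("warn", "%d candidate(s) skipped: undefined distance", skipped)
  }
  structure(candidate_ids[kept], skipped = skipped)
}

#' ESI ionization-compatibility filter
#'
#' ESI(+): keep iff `log_ie > logie_pos_min`. ESI(-): keep iff
#' `log_ie < logie_neg_max` and `hbd >= hbd_min_neg`. Inequalities on
#' LogIE are strict, so boundary values are excluded.
#'
#' @param candidates Data frame with at least `id`, `log_ie` and (for
#'   negative mode) `hbd` columns.
#' @param polarity `"positive"` or `"negative"`.
#' @param config A `selection_config`.
#' @return The filtered data frame (row order preserved), with attribute
#'   `dropped_missing` = count of candidates lacking a finite `log_ie`.
#' @export
esi_filter <- function(candidates, polarity = c("positive", "negative"),
                       config = selection_config()) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(config, "selection_config"))
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0L) {
    return(structure(candidates, dropped_missing = 0L))
  }
  lie <- candidates$log_ie
  missing <- is.na(lie) | !is.finite(lie)
  n_missing <- sum(missing)
  if (n_missing > 0L) {
    mcl_log("warn", "%d candidate(s) dropped: missing log_ie", n_missing)
  }
  keep <- if (polarity == "positive") {
    !missing & lie > config$logie_pos_min
  } else {
    check_that("hbd" %in% names(candidates), "validation",
               "negative-mode filtering needs an hbd column")
    !missing & lie < config$logie_neg_max &
      candidates$hbd >= config$hbd_min_neg
  }
  structure(candidates[keep, , drop = FALSE], dropped_missing = n_missing)
}

#' Group by mobility class and rank by LogIE
#'
#' Within each of the three mobility classes candidates are sorted by
#' LogIE descending (ties by id, lexicographic) and the top
#' `per_class_n` taken. Final ranks are 1-based and contiguous within
#' the polarity: classes concatenated in order 1, 2, 3, then within-class
#' order. Classes with fewer than `per_class_n` eligible members
#' contribute all of them (a shortfall warning is logged and recorded).
#'
#' @param filtered Data frame with `id`, `mobility_class`, `log_ie` (and
#'   any extra columns, carried through).
#' @param polarity `"positive"` or `"negative"`.
#' @param per_class_n Candidates per mobility class.
#' @return MCL data frame with `polarity` and 1-based `rank` columns,
#'   attribute `shortfall` = named integer vector of per-class deficits.
#' @export
rank_and_select <- function(filtered, polarity = c("positive", "negative"),
                            per_class_n = 50L) {
  polarity <- match.arg(polarity)
  check_that(is_count(per_class_n), "config", "per_class_n must be >= 1")
  filtered <- as.data.frame(filtered)
  pieces <- list()
  shortfall <- stats::setNames(integer(3), as.character(1:3))
  for (cls in 1:3) {
    sub <- filtered[filtered$mobility_class == cls, , drop = FALSE]
    if (nrow(sub) > 0L) {
      ord <- .lex_order(-sub$log_ie, sub$id)
      sub <- sub[utils::head(ord, per_class_n), , drop = FALSE]
    }
    if (nrow(sub) < per_class_n) {
      shortfall[as.character(cls)] <- per_class_n - nrow(sub)
      mcl_log("warn",
              "mobility class %d: only %d of %d requested candidates",
              cls, nrow(sub), per_class_n)
    }
    pieces[[cls]] <- sub
  }
  out <- do.call(rbind, pieces)
  out$polarity <- rep(polarity, nrow(out))
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, shortfall = shortfall)
}

#' Run the full MCL selection cascade
#'
#' Composes [grid_sample()] -> [dissimilarity_filter()] ->
#' [esi_filter()] (per polarity) -> [rank_and_select()] and assembles the
#' final entries (id, smiles, polarity, mobility class, LogIE, predicted
#' RI, RPLC class, cell index, rank). Under the default thresholds
#' (3.5 > 1.5) the positive and negative filters are mutually exclusive,
#' so the two lists are disjoint; this is asserted.
#'
#' @param records List of `compound_record`s (provides SMILES; may be
#'   `NULL`, in which case the smiles column is empty).
#' @param features Feature table from [featurize_table()] (or the
#'   synthetic generator): `id` + the 13 model variables.
#' @param scores Score matrix (n x k) with ids as rownames.
#' @param grid A `grid_spec` built on these scores.
#' @param config A `selection_config`.
#' @param scaled Optional matrix used by the dissimilarity metric; by
#'   default the standardized 13-variable matrix is computed internally.
#' @param ri Optional named numeric vector of predicted retention
#'   indices (NA where unknown).
#' @param rplc_bounds RPLC classification bounds for [classify_rplc()].
#' @return List with `positive` and `negative` MCL data frames and
#'   `report` (per-stage counts and warnings).
#' @export
build_mcl <- function(records, features, scores, grid,
                      config = selection_config(), scaled = NULL,
                      ri = NULL, rplc_bounds = c(0, 50, 950, 1000)) {
  stopifnot(inherits(grid, "grid_spec"), inherits(config, "selection_config"))
  features <- as.data.frame(features)
  if (nrow(features) == 0L) {
    empty <- .empty_mcl()
    return(list(positive = empty, negative = empty,
                report = list(n_input = 0L)))
  }
  check_that(!anyDuplicated(features$id), "validation",
             "duplicate ids in the feature table")
  check_that(all(rownames(scores) %in% features$id), "validation",
             "scores and feature table are inconsistent by id")
  fmat <- as.matrix(features[, setdiff(names(features), "id"),
                             drop = FALSE])
  rownames(fmat) <- features$id

  # stage 1: grid sampling
  sampled <- grid_sample(scores, grid, config$per_cell_cap)

  # stage 2: structural dissimilarity
  metric <- if (config$distance_metric == "jaccard_on_fingerprints")
    "jaccard" else "continuous_tanimoto"
  if (is.null(scaled)) {
    scaled <- apply_scaling(fmat, fit_scaling(fmat))
  }
  retained <- withCallingHandlers(
    dissimilarity_filter(sampled$id, scaled, config$distance_threshold,
                         metric),
    error = function(e) mcl_stop("validation", paste0(
      "stage dissimilarity_filter: ", conditionMessage(e))))
  cand <- features[match(retained, features$id), , drop = FALSE]
  cand$cell_index <- sampled$cell_index[match(retained, sampled$id)]

  # stages 3-4 per polarity: ESI filter, then group + rank
  smiles_of <- if (is.null(records)) function(ids) rep("", length(ids))
  else {
    tab <- vapply(records, function(r) r$smiles, character(1))
    names(tab) <- vapply(records, function(r) r$id, character(1))
    function(ids) unname(tab[ids])
  }
  ri_of <- function(ids) {
    if (is.null(ri)) rep(NA_real_, length(ids)) else unname(ri[ids])
  }
  one_polarity <- function(pol) {
    f <- esi_filter(cand, pol, config)
    sel <- rank_and_select(f, pol, config$per_class_n)
    if (nrow(sel) == 0L) return(structure(.empty_mcl(),
                                          shortfall = attr(sel, "shortfall")))
    pri <- ri_of(sel$id)
    out <- data.frame(
      id = sel$id, smiles = smiles_of(sel$id), polarity = sel$polarity,
      mobility_class = as.integer(sel$mobility_class),
      log_ie = sel$log_ie, predicted_ri = pri,
      rplc_class = ifelse(is.na(pri), NA_integer_,
                          classify_rplc(ifelse(is.na(pri), 0, pri),
                                        rplc_bounds)),
      cell_index = sel$cell_index, rank = sel$rank,
      stringsAsFactors = FALSE)
    structure(out, shortfall = attr(sel, "shortfall"))
  }
  pos <- one_polarity("positive")
  neg <- one_polarity("negative")

  if (config$logie_pos_min > config$logie_neg_max) {
    stopifnot(length(intersect(pos$id, neg$id)) == 0L)
  }
  report <- list(
    n_input = nrow(features),
    n_sampled = nrow(sampled),
    n_after_dissimilarity = length(retained),
    n_skipped_degenerate = attr(retained, "skipped"),
    n_positive = nrow(pos), n_negative = nrow(neg),
    shortfall_positive = as.list(attr(pos, "shortfall")),
    shortfall_negative = as.list(attr(neg, "shortfall"))
  )
  list(positive = pos, negative = neg, report = report)
}

.empty_mcl <- function() {
  data.frame(id = character(), smiles = character(), polarity = character(),
             mobility_class = integer(), log_ie = numeric(),
             predicted_ri = numeric(), rplc_class = integer(),
             cell_index = character(), rank = integer(),
             stringsAsFactors = FALSE)
}
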