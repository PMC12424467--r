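# Coverage and applicability diagnostics.

#' Grid-cell coverage of a compound list
#'
#' Coverage is operationalized as the fraction of occupied grid cells
#' (cells holding at least one compound of the full scored dataset) that
#' are hit by the list. Computed on the SAME grid used for sampling.
#'
#' @param list_ids Character vector of compound ids (subset of the
#'   scored table).
#' @param scores Score matrix with ids as rownames (the full dataset).
#' @param grid A `grid_spec`.
#' @param features Optional feature table (id + 13 variables) enabling
#'   per-class counts and the mass range.
#' @param ri Optional named RI vector enabling the RI range and RPLC
#'   class counts.
#' @param rplc_bounds Bounds for [classify_rplc()].
#' @return List of class `coverage_report`: `occupied_cells_total`,
#'   `cells_hit_by_list`, `coverage_fraction`, `cells_hit` (keys), and
#'   when inputs allow: `per_class_counts`, `mass_range`, `ri_range`,
#'   `rplc_counts`.
#' @export
coverage_metrics <- function(list_ids, scores, grid, features = NULL,
                             ri = NULL, rplc_bounds = c(0, 50, 950, 1000)) {
  stopifnot(inherits(grid, "grid_spec"))
  scores <- as.matrix(scores)
  unknown <- setdiff(list_ids, rownames(scores))
  if (length(unknown) > 0L) {
    mcl_stop("validation", sprintf("unknown id(s) not in scored table: %s",
                                   paste(utils::head(unknown, 5),
                                         collapse = ", ")),
             ids = unknown)
  }
  keys_all <- cell_key(assign_cell(scores, grid))
  occupied <- unique(keys_all)
  hit <- unique(keys_all[match(list_ids, rownames(scores))])
  rep <- list(
    occupied_cells_total = length(occupied),
    cells_hit_by_list = length(hit),
    coverage_fraction = if (length(occupied) == 0L) 0
                        else length(hit) / length(occupied),
    cells_hit = sort(hit)
  )
  if (!is.null(features)) {
    features <- as.data.frame(features)
    sub <- features[match(list_ids, features$id), , drop = FALSE]
    rep$per_class_counts <- stats::setNames(
      as.integer(table(factor(sub$mobility_class, levels = 1:3))),
      c("1", "2", "3"))
    if ("mw" %in% names(sub) && nrow(sub) > 0L) {
      rep$mass_range <- range(sub$mw, na.rm = TRUE)
    }
  }
  if (!is.null(ri)) {
    rv <- ri[list_ids]
    rv <- rv[is.finite(rv)]
    if (length(rv) > 0L) {
      rep$ri_range <- range(rv)
      cls <- classify_rplc(rv, rplc_bounds)
      rep$rplc_counts <- stats::setNames(
        as.integer(table(factor(cls, levels = c(-1, 0, 1)))),
        c("-1", "0", "1"))
    }
  }
  structure(rep, class = "coverage_report")
}

#' Compare grid-cell coverage of two compound lists
#'
#' @param list_a,list_b Character vectors of compound ids.
#' @inheritParams coverage_metrics
#' @return List with coverage reports `a` and `b`, the cell keys
#'   `cells_a_not_b` / `cells_b_not_a`, and their counts.
#' @export
compare_lists <- function(list_a, list_b, scores, grid, ...) {
  ra <- coverage_metrics(list_a, scores, grid, ...)
  rb <- coverage_metrics(list_b, scores, grid, ...)
  anb <- setdiff(ra$cells_hit, rb$cells_hit)
  bna <- setdiff(rb$cells_hit, ra$cells_hit)
  list(a = ra, b = rb,
       cells_a_not_b = sort(anb), cells_b_not_a = sort(bna),
       n_a_not_b = length(anb), n_b_not_a = length(bna))
}

#' Ordinary least squares of retention index on monoisotopic mass
#'
#' Quantifies how weakly retention depends on mass within an MCL (a weak
#' trend means the list is not confounding retention with size).
#'
#' @param mass Numeric vector of monoisotopic masses (Da).
#' @param ri Numeric vector of retention indices, same length.
#' @return List with `slope`, `intercept`, `r_squared` (in `[0, 1]`).
#' @export
ri_mass_regression <- function(mass, ri) {
  ok <- is.finite(mass) & is.finite(ri)
  mass <- mass[ok]; ri <- ri[ok]
  check_that(length(mass) >= 3L, "validation",
             "need at least 3 points with finite mass and RI")
  check_that(stats::var(mass) > 0, "validation",
             "zero variance in mass; regression undefined")
  fit <- stats::lm(ri ~ mass)
  co <- stats::coef(fit)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((ri - mean(ri))^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  list(slope = unname(co[["mass"]]), intercept = unname(co[["(Intercept)"]]),
       r_squared = min(max(r2, 0), 1))
}

#' Offline availability adapter backed by a counts file
#'
#' @param path Delimited file with columns `id`, `patent_count`,
#'   `literature_count`.
#' @return Adapter function `ids -> data.frame(id, patent_count,
#'   literature_count)` for [availability_counts()].
#' @export
file_availability_adapter <- function(path) {
  check_that(file.exists(path), "config",
             sprintf("availability fixture not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = detect_delimiter(path),
                           stringsAsFactors = FALSE)
  check_that(all(c("id", "patent_count", "literature_count") %in% names(tab)),
             "config", "adapter file needs id, patent_count, literature_count")
  function(ids) tab[match(ids, tab$id), , drop = FALSE]
}

#' Patent/literature availability of selected structures
#'
#' A structure is considered potentially available as a purchasable
#' standard when it has any patent or literature record. Ids the adapter
#' cannot resolve get `available = NA` ("unknown") and the run continues.
#'
#' @param ids Character vector of compound ids.
#' @param adapter Adapter function `ids -> data.frame(id, patent_count,
#'   literature_count)`, e.g. from [file_availability_adapter()].
#' @return Data frame `id`, `patent_count`, `literature_count`,
#'   `available` (logical, NA when unknown), plus attribute
#'   `fraction_available` over the resolved ids.
#' @export
availability_counts <- function(ids, adapter) {
  check_that(is.function(adapter), "config",
             "adapter must be a function of ids")
  res <- tryCatch(adapter(ids), error = function(e) NULL)
  if (is.null(res)) {
    out <- data.frame(id = ids, patent_count = NA_integer_,
                      literature_count = NA_integer_, available = NA)
    attr(out, "fraction_available") <- NA_real_
    return(out)
  }
  res <- res[match(ids, res$id), , drop = FALSE]
  out <- data.frame(
    id = ids,
    patent_count = res$patent_count,
    literature_count = res$literature_count,
    available = res$patent_count > 0 | res$literature_count > 0)
  known <- !is.na(out$available)
  attr(out, "fraction_available") <-
    if (any(known)) mean(out$available[known]) else NA_real_
  out
}
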