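# Pluggable mobility / LogIE / retention-index predictors.
#
# The published mobility, ionization-efficiency and retention-index models
# are external packages; this module accepts their outputs as precomputed
# columns ("passthrough", the primary mode) and additionally ships crude
# deterministic baseline surrogates so the pipeline runs end-to-end
# without them. Surrogate outputs are labelled "surrogate" everywhere.

.mobility_labels <- c("Non-mobile", "Mobile", "Very mobile")

#' Mobility class coding
#'
#' Fixed bijection: 1 = "Non-mobile", 2 = "Mobile", 3 = "Very mobile".
#'
#' @param x Integer code in `{1,2,3}` or one of the three labels.
#' @return List of class `mobility_class` with `code` and `label`.
#' @examples
#' mobility_class(3)$label
#' mobility_class("Mobile")$code
#' @export
mobility_class <- function(x) {
  if (is.character(x)) {
    code <- match(x, .mobility_labels)
    check_that(!is.na(code), "validation",
               sprintf("unknown mobility label %s", dQuote(x)))
  } else {
    check_that(length(x) == 1L && x %in% 1:3, "validation",
               "mobility code must be 1, 2 or 3")
    code <- as.integer(x)
  }
  structure(list(code = code, label = .mobility_labels[code]),
            class = "mobility_class")
}

#' Predictor specification
#'
#' @param kind `"passthrough"` (use the precomputed column; the primary
#'   mode) or `"baseline"` (bundled deterministic surrogate).
#' @param parameters Named list of surrogate parameters; missing entries
#'   take the documented defaults.
#' @return List of class `predictor_spec`.
#' @export
predictor_spec <- function(kind = c("passthrough", "baseline"),
                           parameters = list()) {
  kind <- match.arg(kind)
  check_that(is.list(parameters), "config", "parameters must be a list")
  structure(list(kind = kind, parameters = parameters),
            class = "predictor_spec")
}

#' Predict the environmental mobility class
#'
#' Passthrough returns the stored code unchanged. The baseline surrogate
#' maps XLogP through two cutpoints (defaults: XLogP < 0 -> Very mobile;
#' 0 <= XLogP < 3 -> Mobile; >= 3 -> Non-mobile), reflecting that
#' hydrophilic chemicals travel furthest in the aquatic environment.
#'
#' @param record A `compound_record`.
#' @param physchem A `physchem` block (needs `xlogp` for the baseline).
#' @param spec A `predictor_spec`.
#' @return A `mobility_class`.
#' @export
predict_mobility <- function(record, physchem,
                             spec = predictor_spec("passthrough")) {
  stopifnot(inherits(spec, "predictor_spec"))
  if (spec$kind == "passthrough") {
    mc <- record$precomputed$mobility_class
    if (is.null(mc) || is.na(mc)) {
      mcl_stop("predictor",
               sprintf("no precomputed mobility_class for id %s", record$id),
               id = record$id)
    }
    return(mobility_class(as.integer(mc)))
  }
  cut <- spec$parameters$xlogp_cutpoints %||% c(0, 3)
  check_that(length(cut) == 2L && cut[1] < cut[2], "config",
             "xlogp_cutpoints must be two increasing values")
  x <- physchem$xlogp
  check_that(is.finite(x), "predictor",
             sprintf("baseline mobility needs finite xlogp (id %s)",
                     record$id), id = record$id)
  code <- if (x < cut[1]) 3L else if (x < cut[2]) 2L else 1L
  mobility_class(code)
}

#' Predict log10 electrospray ionization efficiency (LogIE)
#'
#' Passthrough returns the stored value. The baseline surrogate is a
#' documented linear form over (xlogp, tpsa, hbd, hba):
#' `intercept + b_xlogp*xlogp + b_tpsa*tpsa + b_hbd*hbd + b_hba*hba`,
#' with defaults (2.5, 0.5, -0.01, -0.2, 0.05) on the methyl-benzoate
#' anchored ESI(+) scale: ionization efficiency rises with hydrophobicity
#' and falls with polar surface and donor count.
#'
#' @inheritParams predict_mobility
#' @return A single numeric LogIE value.
#' @export
predict_log_ie <- function(record, physchem,
                           spec = predictor_spec("passthrough")) {
  stopifnot(inherits(spec, "predictor_spec"))
  if (spec$kind == "passthrough") {
    v <- record$precomputed$log_ie
    if (is.null(v) || is.na(v)) {
      mcl_stop("predictor",
               sprintf("no precomputed log_ie for id %s", record$id),
               id = record$id)
    }
    return(as.numeric(v))
  }
  p <- spec$parameters
  co <- c(intercept = p$intercept %||% 2.5, xlogp = p$xlogp %||% 0.5,
          tpsa = p$tpsa %||% -0.01, hbd = p$hbd %||% -0.2,
          hba = p$hba %||% 0.05)
  vals <- c(physchem$xlogp, physchem$tpsa, physchem$hbd, physchem$hba)
  check_that(all(is.finite(vals)), "predictor",
             sprintf("baseline log_ie needs xlogp/tpsa/hbd/hba (id %s)",
                     record$id), id = record$id)
  unname(co["intercept"] + sum(co[-1] * vals))
}

#' Predict the retention index (cocamide scale)
#'
#' Passthrough returns the stored value. The baseline surrogate is linear
#' in XLogP (`intercept + slope * xlogp`, defaults 300 and 80): retention
#' in reversed phase increases with hydrophobicity. A surrogate only;
#' not a substitute for a trained retention model.
#'
#' @inheritParams predict_mobility
#' @return A single numeric retention index.
#' @export
predict_ri <- function(record, physchem,
                       spec = predictor_spec("passthrough")) {
  stopifnot(inherits(spec, "predictor_spec"))
  if (spec$kind == "passthrough") {
    v <- record$precomputed$ri
    if (is.null(v) || is.na(v)) {
      mcl_stop("predictor",
               sprintf("no precomputed ri for id %s", record$id),
               id = record$id)
    }
    return(as.numeric(v))
  }
  p <- spec$parameters
  x <- physchem$xlogp
  check_that(is.finite(x), "predictor",
             sprintf("baseline ri needs finite xlogp (id %s)", record$id),
             id = record$id)
  unname((p$intercept %||% 300) + (p$slope %||% 80) * x)
}

#' Classify a retention index against the RPLC domain
#'
#' Three-way classification of whether a compound is retainable in the
#' reversed-phase LC domain: `-1` = outside, `0` = maybe (inside the
#' domain but within the margin bands), `1` = inside.
#'
#' @param ri Numeric retention index (vectorised).
#' @param bounds Four strictly increasing values
#'   `(lo, lo_margin, hi_margin, hi)`; default `c(0, 50, 950, 1000)` on
#'   the cocamide scale.
#' @return Integer vector in `{-1, 0, 1}`: `ri < lo` or `ri > hi` -> -1;
#'   `[lo, lo_margin)` or `(hi_margin, hi]` -> 0; otherwise 1.
#' @examples
#' classify_rplc(c(-10, 25, 500, 975, 1200))
#' @export
classify_rplc <- function(ri, bounds = c(0, 50, 950, 1000)) {
  check_that(is.numeric(bounds) && length(bounds) == 4L &&
               all(diff(bounds) > 0), "config",
             "bounds must be four strictly increasing values")
  check_that(is.numeric(ri) && all(is.finite(ri)), "validation",
             "ri must be finite")
  out <- integer(length(ri))
  out[ri < bounds[1] | ri > bounds[4]] <- -1L
  maybe <- (ri >= bounds[1] & ri < bounds[2]) |
           (ri > bounds[3] & ri <= bounds[4])
  out[maybe] <- 0L
  out[ri >= bounds[2] & ri <= bounds[3]] <- 1L
  out
}
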