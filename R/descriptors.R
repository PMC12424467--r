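# Physicochemical descriptors, elemental mass defects (EMDs) and the
# 13-variable feature vector.

# ---- TPSA -------------------------------------------------------------
# Ertl fragment contributions for N and O atom types (the convention also
# used as the default in mainstream toolkits: sulfur/phosphorus excluded).
# Each row: element, aromatic, charge, nH, nSingle, nDouble, nTriple,
# nAromatic, in3ring, contribution (A^2).
.tpsa_table <- local({
  r <- function(el, ar, ch, h, s, d, t, a, r3, val)
    data.frame(el = el, ar = ar, ch = ch, h = h, s = s, d = d, t = t,
               a = a, r3 = r3, val = val)
  rbind(
    r("N", FALSE, 0L, 0L, 3L, 0L, 0L, 0L, FALSE, 3.24),
    r("N", FALSE, 0L, 0L, 1L, 1L, 0L, 0L, FALSE, 12.36),
    r("N", FALSE, 0L, 0L, 0L, 0L, 1L, 0L, FALSE, 23.79),
    r("N", FALSE, 0L, 0L, 1L, 2L, 0L, 0L, FALSE, 11.68),
    r("N", FALSE, 0L, 0L, 0L, 1L, 1L, 0L, FALSE, 13.60),
    r("N", FALSE, 0L, 0L, 3L, 0L, 0L, 0L, TRUE,  3.01),
    r("N", FALSE, 0L, 1L, 2L, 0L, 0L, 0L, FALSE, 12.03),
    r("N", FALSE, 0L, 1L, 2L, 0L, 0L, 0L, TRUE,  21.94),
    r("N", FALSE, 0L, 1L, 0L, 1L, 0L, 0L, FALSE, 23.85),
    r("N", FALSE, 0L, 2L, 1L, 0L, 0L, 0L, FALSE, 26.02),
    r("N", FALSE, 1L, 0L, 4L, 0L, 0L, 0L, FALSE, 0.00),
    r("N", FALSE, 1L, 0L, 2L, 1L, 0L, 0L, FALSE, 3.01),
    r("N", FALSE, 1L, 0L, 1L, 0L, 1L, 0L, FALSE, 4.36),
    r("N", FALSE, 1L, 1L, 3L, 0L, 0L, 0L, FALSE, 4.44),
    r("N", FALSE, 1L, 1L, 1L, 1L, 0L, 0L, FALSE, 13.97),
    r("N", FALSE, 1L, 2L, 2L, 0L, 0L, 0L, FALSE, 16.61),
    r("N", FALSE, 1L, 2L, 0L, 1L, 0L, 0L, FALSE, 25.59),
    r("N", FALSE, 1L, 3L, 1L, 0L, 0L, 0L, FALSE, 27.64),
    r("N", TRUE,  0L, 0L, 0L, 0L, 0L, 2L, FALSE, 12.89),
    r("N", TRUE,  0L, 0L, 0L, 0L, 0L, 3L, FALSE, 4.41),
    r("N", TRUE,  0L, 0L, 1L, 0L, 0L, 2L, FALSE, 4.93),
    r("N", TRUE,  0L, 0L, 0L, 1L, 0L, 2L, FALSE, 8.39),
    r("N", TRUE,  0L, 1L, 0L, 0L, 0L, 2L, FALSE, 15.79),
    r("N", TRUE,  1L, 0L, 0L, 0L, 0L, 3L, FALSE, 4.10),
    r("N", TRUE,  1L, 0L, 1L, 0L, 0L, 2L, FALSE, 3.88),
    r("N", TRUE,  1L, 1L, 0L, 0L, 0L, 2L, FALSE, 14.14),
    r("O", FALSE, 0L, 0L, 2L, 0L, 0L, 0L, FALSE, 9.23),
    r("O", FALSE, 0L, 0L, 2L, 0L, 0L, 0L, TRUE,  12.53),
    r("O", FALSE, 0L, 0L, 0L, 1L, 0L, 0L, FALSE, 17.07),
    r("O", FALSE, 0L, 1L, 1L, 0L, 0L, 0L, FALSE, 20.23),
    r("O", FALSE, -1L, 0L, 1L, 0L, 0L, 0L, FALSE, 23.06),
    r("O", TRUE,  0L, 0L, 0L, 0L, 0L, 2L, FALSE, 13.14)
  )
})

# Topological polar surface area from the parsed graph (N/O contributions).
mol_tpsa <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  idx <- which(a$element %in% c("N", "O"))
  if (length(idx) == 0L) return(0)
  tot <- 0
  for (at in idx) {
    sel <- b$a1 == at | b$a2 == at
    ba <- b[sel, , drop = FALSE]
    na <- sum(ba$aromatic)
    ns <- sum(!ba$aromatic & ba$order == 1)
    nd <- sum(!ba$aromatic & ba$order == 2)
    nt <- sum(!ba$aromatic & ba$order == 3)
    tt <- .tpsa_table
    hit <- tt$el == a$element[at] & tt$ar == a$aromatic[at] &
      tt$ch == a$charge[at] & tt$h == a$h[at] & tt$s == ns &
      tt$d == nd & tt$t == nt & tt$a == na &
      (tt$r3 == a$in_ring3[at] | !any(tt$r3[tt$el == a$element[at]]))
    # prefer exact 3-ring match, fall back to the non-ring row
    cand <- tt[hit, , drop = FALSE]
    if (nrow(cand) > 1L) cand <- cand[cand$r3 == a$in_ring3[at], , drop = FALSE]
    if (nrow(cand) == 1L) {
      tot <- tot + cand$val
    } else {
      # generic fallback (same functional form as mainstream toolkits)
      deg <- na + ns + nd + nt
      f <- if (a$element[at] == "N") 30.5 - deg * 8.2 + a$h[at] * 1.5
           else 28.5 - deg * 8.6 + a$h[at] * 1.5
      tot <- tot + max(0, f)
    }
  }
  round(tot, 10)
}

# Crude atom-contribution logP surrogate; only used when no precomputed
# XLogP is supplied, and flagged "surrogate" in provenance. Contributions
# are coarse hydrophobicity increments, not a fit to PubChem XLogP.
.logp_contrib <- c(C = 0.36, N = -0.60, O = -0.55, S = 0.25, P = -0.40,
                   F = 0.22, Cl = 0.65, Br = 0.85, I = 1.10, B = 0.10)
mol_surrogate_logp <- function(mol) {
  a <- mol$atoms
  contrib <- .logp_contrib[a$element]
  contrib[is.na(contrib)] <- 0
  # polar hydrogens (on N/O) penalise, aromatic atoms gain slightly
  polar_h <- sum(a$h[a$element %in% c("N", "O")])
  unname(sum(contrib) + 0.10 * sum(a$aromatic) - 0.30 * polar_h)
}

# ---- physicochemical descriptor set -----------------------------------

#' Compute the physicochemical descriptor block for one compound
#'
#' Precomputed values on the record (from e.g. PubChem) take precedence
#' field-by-field; only missing fields are computed from the SMILES.
#' When `xlogp` is absent a crude internal surrogate is used and flagged.
#'
#' @param record A `compound_record` (see [compound_record()]).
#' @return A list of class `physchem` with fields `mw` (monoisotopic, Da),
#'   `xlogp`, `tpsa` (A^2), `hbd`, `hba`, plus a `provenance` character
#'   vector marking each field `"precomputed"`, `"computed"` or
#'   `"surrogate"`.
#' @examples
#' compute_physchem(compound_record("w1", "O"))
#' @export
compute_physchem <- function(record) {
  stopifnot(inherits(record, "compound_record"))
  pre <- record$precomputed
  fields <- c("mw", "xlogp", "tpsa", "hbd", "hba")
  need <- fields[!vapply(fields, function(f)
    !is.null(pre[[f]]) && is.finite(pre[[f]]), logical(1))]
  out <- lapply(fields, function(f) pre[[f]])
  names(out) <- fields
  prov <- stats::setNames(rep("precomputed", 5L), fields)
  if (length(need) > 0L) {
    mol <- parse_smiles(record$smiles, id = record$id)
    a <- mol$atoms
    comp <- list(
      mw = mol_monoisotopic_mass(mol),
      xlogp = mol_surrogate_logp(mol),
      tpsa = mol_tpsa(mol),
      hbd = sum(a$element %in% c("N", "O") & a$h >= 1),
      hba = sum(a$element %in% c("N", "O"))
    )
    for (f in need) {
      out[[f]] <- comp[[f]]
      prov[[f]] <- if (f == "xlogp") "surrogate" else "computed"
    }
  }
  check_that(out$mw > 0, "validation",
             sprintf("mw must be positive for id %s", record$id),
             id = record$id)
  structure(c(out, list(provenance = prov)), class = "physchem")
}

# ---- elemental mass defects -------------------------------------------

#' Define an elemental mass-defect base unit
#'
#' @param label Unit label; a formula over the embedded element table,
#'   e.g. `"CH2"`, `"CO"`, `"CCl"`.
#' @return List of class `emd_unit` with `label`, `exact_mass` (Da) and
#'   `nominal_mass` (integer).
#' @examples
#' emd_unit("CH2")
#' @export
emd_unit <- function(label) {
  check_that(is.character(label) && length(label) == 1L && nzchar(label),
             "config", "EMD unit label must be a non-empty string")
  parts <- regmatches(label, gregexpr("[A-Z][a-z]?[0-9]*", label))[[1]]
  check_that(sum(nchar(parts)) == nchar(label), "config",
             sprintf("cannot read element formula from EMD label %s",
                     dQuote(label)))
  els <- sub("[0-9]+$", "", parts)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
  counts <- tapply(cnt, els, sum)
  tab <- atomic_mass_table()
  idx <- match(names(counts), tab$element)
  check_that(!anyNA(idx), "config",
             sprintf("unknown element in EMD unit %s", dQuote(label)))
  structure(list(label = label,
                 exact_mass = sum(tab$exact[idx] * as.numeric(counts)),
                 nominal_mass = as.integer(sum(tab$nominal[idx] * counts))),
            class = "emd_unit")
}

#' Default EMD base units
#'
#' Six Kendrick-style base units: CH2, CO, CCl, CN, CF2, CS. The set is
#' fully configurable; these defaults cover homologue series common in
#' environmental chemistry (alkyl, oxygenated, chlorinated, nitrogenous,
#' perfluorinated, sulfur-containing).
#'
#' @return A named list of six `emd_unit` objects.
#' @export
default_emd_units <- function() {
  labs <- c("CH2", "CO", "CCl", "CN", "CF2", "CS")
  stats::setNames(lapply(labs, emd_unit), labs)
}

#' Kendrick-style elemental mass defect
#'
#' The exact mass is rescaled so the base unit has integer mass
#' (`mass * nominal/exact`), and the defect is the signed distance of the
#' rescaled mass to the nearest integer: `round(scaled) - scaled`, which
#' lies in (-0.5, 0.5]. Members of a homologous series differing by whole
#' base units share the same defect.
#'
#' @param mass Monoisotopic mass in Da (positive; vectorised).
#' @param unit An `emd_unit`.
#' @return Numeric defect(s) in (-0.5, 0.5].
#' @examples
#' elemental_mass_defect(86.10955, emd_unit("CH2"))  # hexane
#' @export
elemental_mass_defect <- function(mass, unit) {
  stopifnot(inherits(unit, "emd_unit"))
  check_that(is.numeric(mass) && all(is.finite(mass)) && all(mass > 0),
             "domain", "mass must be positive and finite")
  scaled <- mass * unit$nominal_mass / unit$exact_mass
  d <- round(scaled) - scaled
  # round() is round-half-even; force the half case onto +0.5
  d[d == -0.5] <- 0.5
  d
}

# ---- 13-variable feature vector ---------------------------------------

#' Names of the 13 model variables, in canonical order
#'
#' Slot order is fixed in one place: five physicochemical descriptors,
#' six elemental mass defects, the coded mobility class and LogIE.
#'
#' @param emd_labels Labels of the six EMD units (default the built-ins).
#' @return Character vector of 13 names.
#' @export
feature_names <- function(emd_labels = names(default_emd_units())) {
  check_that(length(emd_labels) == 6L, "config",
             "exactly six EMD units are required")
  c("mw", "xlogp", "tpsa", "hbd", "hba",
    paste0("emd_", emd_labels), "mobility_class", "log_ie")
}

#' Assemble the 13-variable feature vector for one compound
#'
#' @param record A `compound_record` (used for the id on errors).
#' @param physchem A `physchem` from [compute_physchem()].
#' @param emds Named numeric vector of six mass defects (names = unit
#'   labels).
#' @param mobility_class Integer code 1 (Non-mobile), 2 (Mobile) or
#'   3 (Very mobile).
#' @param log_ie Predicted log10 ionization efficiency.
#' @return Named numeric vector of length 13 in canonical slot order.
#' @export
assemble_features <- function(record, physchem, emds, mobility_class,
                              log_ie) {
  id <- if (inherits(record, "compound_record")) record$id
        else as.character(record)
  check_that(inherits(physchem, "physchem"), "assembly",
             sprintf("physchem block missing for id %s", id), id = id)
  check_that(length(emds) == 6L && !is.null(names(emds)), "assembly",
             sprintf("six named EMD values required for id %s", id),
             id = id)
  for (f in c("mw", "xlogp", "tpsa", "hbd", "hba")) {
    check_that(is.finite(physchem[[f]] %||% NA_real_), "assembly",
               sprintf("slot %s missing or non-finite for id %s", f, id),
               id = id)
  }
  check_that(all(is.finite(emds)), "assembly",
             sprintf("slot emd missing or non-finite for id %s", id),
             id = id)
  check_that(is.finite(log_ie), "assembly",
             sprintf("slot log_ie missing or non-finite for id %s", id),
             id = id)
  check_that(length(mobility_class) == 1L && mobility_class %in% 1:3,
             "assembly",
             sprintf("slot mobility_class invalid for id %s", id), id = id)
  # canonical EMD slot order: the default unit order when the labels are
  # the default set (in any input order), otherwise the order supplied
  canon <- names(default_emd_units())
  ord <- if (setequal(names(emds), canon)) canon else names(emds)
  v <- c(physchem$mw, physchem$xlogp, physchem$tpsa, physchem$hbd,
         physchem$hba, unname(emds[ord]),
         as.numeric(mobility_class), log_ie)
  names(v) <- feature_names(ord)
  v
}

#' Build the full feature table for a list of compound records
#'
#' Runs [compute_physchem()], the six EMDs, and the configured mobility
#' and LogIE predictors for every record, returning a data frame with the
#' id column plus the 13 model variables.
#'
#' @param records List of `compound_record`s.
#' @param emd_units Named list of six `emd_unit`s.
#' @param mobility_spec,logie_spec Predictor specifications
#'   (see [predictor_spec()]).
#' @param strict If `FALSE` (default), records whose SMILES fail to parse
#'   are dropped and reported once with a count; if `TRUE` they are fatal.
#' @return Data frame: `id` + the 13 feature columns, one row per record
#'   (input order preserved).
#' @export
featurize_table <- function(records,
                            emd_units = default_emd_units(),
                            mobility_spec = predictor_spec("passthrough"),
                            logie_spec = predictor_spec("passthrough"),
                            strict = FALSE) {
  check_that(length(emd_units) == 6L, "config",
             "exactly six EMD units are required")
  rows <- vector("list", length(records))
  failed <- character()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    row <- tryCatch({
      pc <- compute_physchem(rec)
      emds <- vapply(emd_units, function(u)
        elemental_mass_defect(pc$mw, u), numeric(1))
      names(emds) <- vapply(emd_units, `[[`, character(1), "label")
      mob <- predict_mobility(rec, pc, mobility_spec)
      lie <- predict_log_ie(rec, pc, logie_spec)
      c(assemble_features(rec, pc, emds, mob$code, lie))
    }, mcl_parse_error = function(e) {
      if (strict) stop(e)
      failed <<- c(failed, rec$id)
      NULL
    })
    rows[[i]] <- row
  }
  if (length(failed) > 0L) {
    warning(sprintf(
      "%d record(s) dropped: unparseable SMILES (ids: %s%s)",
      length(failed), paste(utils::head(failed, 5L), collapse = ", "),
      if (length(failed) > 5L) ", ..." else ""), call. = FALSE)
  }
  keep <- !vapply(rows, is.null, logical(1))
  ids <- vapply(records, function(r) r$id, character(1))[keep]
  mat <- do.call(rbind, rows[keep])
  out <- data.frame(id = ids, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
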