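# Non-hashed binary fingerprints and the dissimilarity measures used by
# the selection filter.
#
# The default scheme ("mclkeys") is a documented, fully deterministic
# substructure-key set computed on the parsed molecular graph. It is the
# concatenation of six key blocks (element presence, element counts,
# functional groups, rings/aromaticity, charge/unsaturation, size), each
# of which is also registered as a scheme of its own. Keys are positional:
# bit i of a scheme always means the same structural feature.

.fp_registry <- new.env(parent = emptyenv())

#' Register a fingerprint scheme
#'
#' @param name Scheme label.
#' @param fn Function `mcl_mol -> integer 0/1 vector` of fixed length.
#' @param nbits Fixed bit length of the scheme.
#' @param bit_names Character vector naming each bit.
#' @export
register_fingerprint_scheme <- function(name, fn, nbits, bit_names = NULL) {
  check_that(is.function(fn) && is_count(nbits), "config",
             "scheme needs a function and a positive bit length")
  assign(name, list(fn = fn, nbits = as.integer(nbits),
                    bit_names = bit_names), envir = .fp_registry)
  invisible(name)
}

#' List registered fingerprint schemes
#' @return Character vector of scheme names.
#' @export
fingerprint_schemes <- function() sort(ls(.fp_registry))

# ---- key blocks -------------------------------------------------------

.halogens <- c("F", "Cl", "Br", "I")

.keys_elements <- function(mol) {
  e <- mol$atoms$element
  as.integer(c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B") %in% e)
}
.keys_element_counts <- function(mol) {
  e <- mol$atoms$element
  nhal <- sum(e %in% .halogens)
  as.integer(c(sum(e == "C") >= 4, sum(e == "C") >= 8, sum(e == "C") >= 12,
               sum(e == "N") >= 2, sum(e == "O") >= 2, sum(e == "O") >= 4,
               nhal >= 1, nhal >= 2, sum(e == "F") >= 4, sum(e == "S") >= 2))
}
.keys_functional <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  nbrs <- function(at) {
    k <- which(b$a1 == at | b$a2 == at)
    data.frame(other = ifelse(b$a1[k] == at, b$a2[k], b$a1[k]),
               order = b$order[k], aromatic = b$aromatic[k])
  }
  el <- a$element
  hydroxyl <- carbonyl <- carboxyl <- ester <- amide <- FALSE
  prim_amine <- sub_amine <- nitro <- sulfonyl <- ether <- FALSE
  nitrile <- phenol <- FALSE
  for (at in seq_len(nrow(a))) {
    nb <- nbrs(at)
    if (el[at] == "O" && a$h[at] >= 1 && nrow(nb) == 1 &&
        !nb$aromatic[1] && nb$order[1] == 1 && el[nb$other[1]] == "C") {
      hydroxyl <- TRUE
      if (a$aromatic[nb$other[1]]) phenol <- TRUE
    }
    if (el[at] == "O" && a$h[at] == 0 && a$charge[at] == 0 &&
        nrow(nb) == 2 && all(nb$order == 1 & !nb$aromatic) &&
        all(el[nb$other] == "C")) ether <- TRUE
    if (el[at] == "C") {
      dbl_o <- nb$other[nb$order == 2 & !nb$aromatic & el[nb$other] == "O"]
      sng_o <- nb$other[nb$order == 1 & !nb$aromatic & el[nb$other] == "O"]
      sng_n <- nb$other[nb$order == 1 & el[nb$other] == "N"]
      if (length(dbl_o) > 0) {
        carbonyl <- TRUE
        if (any(a$h[sng_o] >= 1)) carboxyl <- TRUE
        for (o in sng_o) {
          onb <- nbrs(o)
          if (a$h[o] == 0 && any(el[onb$other] == "C" & onb$other != at))
            ester <- TRUE
        }
        if (length(sng_n) > 0) amide <- TRUE
      }
      if (any(nb$order == 3 & el[nb$other] == "N")) nitrile <- TRUE
    }
    if (el[at] == "N" && !a$aromatic[at]) {
      o_nb <- sum(el[nb$other] == "O")
      if (o_nb >= 2) nitro <- TRUE
      c_sng <- sum(el[nb$other] == "C" & nb$order == 1)
      if (a$h[at] == 2 && c_sng == 1) prim_amine <- TRUE
      if (a$h[at] <= 1 && c_sng >= 2) sub_amine <- TRUE
    }
    if (el[at] == "S" &&
        sum(nb$order == 2 & el[nb$other] == "O") >= 2) sulfonyl <- TRUE
  }
  as.integer(c(hydroxyl, carbonyl, carboxyl, ester, amide, prim_amine,
               sub_amine, nitro, sulfonyl, ether, nitrile, phenol))
}
.keys_rings <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  n_ring_bonds <- sum(a$in_ring[b$a1] & a$in_ring[b$a2])
  n_cycles <- max(0L, nrow(b) - nrow(a) + .n_components(nrow(a), b))
  as.integer(c(any(a$in_ring), n_cycles >= 2, any(a$aromatic),
               any(a$aromatic & a$element == "N"),
               any(a$aromatic & a$element %in% c("O", "S")),
               any(a$in_ring3),
               any(a$in_ring & !a$aromatic),
               n_ring_bonds >= 10))
}
.keys_charge_unsat <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  dbl <- any(!b$aromatic & b$order == 2)
  as.integer(c(any(a$charge > 0), any(a$charge < 0),
               any(a$charge > 0) && any(a$charge < 0),
               dbl, any(b$order == 3),
               any(!b$aromatic & b$order == 2 &
                     a$element[b$a1] == "C" & a$element[b$a2] == "C")))
}
.keys_size <- function(mol) {
  a <- mol$atoms
  deg <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = nrow(a))
  as.integer(c(nrow(a) >= 5, nrow(a) >= 10, nrow(a) >= 20, nrow(a) >= 35,
               sum(a$h) >= 10, any(deg >= 4)))
}

.n_components <- function(n, bonds) {
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(bonds))) {
    ra <- find(bonds$a1[k]); rb <- find(bonds$a2[k])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# register the six blocks and the composite at load time
.register_default_schemes <- function() {
  register_fingerprint_scheme("elements", .keys_elements, 10L)
  register_fingerprint_scheme("element_counts", .keys_element_counts, 10L)
  register_fingerprint_scheme("functional_groups", .keys_functional, 12L)
  register_fingerprint_scheme("rings_aromaticity", .keys_rings, 8L)
  register_fingerprint_scheme("charge_unsaturation", .keys_charge_unsat, 6L)
  register_fingerprint_scheme("size", .keys_size, 6L)
  register_fingerprint_scheme("mclkeys", function(mol) {
    c(.keys_elements(mol), .keys_element_counts(mol), .keys_functional(mol),
      .keys_rings(mol), .keys_charge_unsat(mol), .keys_size(mol))
  }, 52L)
}

#' Compute a non-hashed binary fingerprint
#'
#' @param record A `compound_record` (or a bare SMILES string).
#' @param scheme Registered scheme name; default the 52-bit composite
#'   `"mclkeys"`.
#' @return Object of class `fingerprint`: list with integer `bits` (0/1)
#'   and `scheme`.
#' @examples
#' fp <- compute_fingerprint(compound_record("e1", "CCO"))
#' sum(fp$bits)
#' @export
compute_fingerprint <- function(record, scheme = "mclkeys") {
  if (!exists(scheme, envir = .fp_registry, inherits = FALSE)) {
    mcl_stop("config", sprintf("unknown fingerprint scheme %s; registered: %s",
                               dQuote(scheme),
                               paste(fingerprint_schemes(), collapse = ", ")))
  }
  smiles <- if (inherits(record, "compound_record")) record$smiles else record
  id <- if (inherits(record, "compound_record")) record$id else NULL
  mol <- parse_smiles(smiles, id = id)
  sch <- get(scheme, envir = .fp_registry)
  bits <- as.integer(sch$fn(mol))
  check_that(length(bits) == sch$nbits, "config",
             sprintf("scheme %s returned %d bits, expected %d",
                     scheme, length(bits), sch$nbits))
  structure(list(bits = bits, scheme = scheme), class = "fingerprint")
}

# ---- distances --------------------------------------------------------

#' Jaccard distance between two binary vectors
#'
#' `1 - |a AND b| / |a OR b|`; 0 iff the set supports are identical,
#' 1 for disjoint non-empty supports.
#'
#' @param a,b Binary vectors (0/1 or logical) of equal length.
#' @return Distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  check_that(length(a) == length(b), "domain",
             "binary vectors must have equal length")
  un <- sum(a | b)
  if (un == 0L) {
    mcl_stop("domain", "Jaccard distance undefined: both vectors all-zero")
  }
  1 - sum(a & b) / un
}

#' Continuous Tanimoto distance between two real vectors
#'
#' `1 - (x.y) / (||x||^2 + ||y||^2 - x.y)`, the continuous generalisation
#' of the Tanimoto/Jaccard coefficient; 0 iff `x == y`, symmetric.
#'
#' @param x,y Numeric vectors of equal length, not both all-zero.
#' @return Distance (0 for identical vectors).
#' @export
continuous_tanimoto_distance <- function(x, y) {
  check_that(length(x) == length(y), "domain",
             "vectors must have equal length")
  dot <- sum(x * y); nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 && ny == 0) {
    mcl_stop("domain", "Tanimoto distance undefined: both vectors all-zero")
  }
  1 - dot / (nx + ny - dot)
}
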