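# Embedded monoisotopic atomic-mass table (most abundant isotope).
# Masses in Da from the IUPAC/CODATA atomic mass evaluation; mass numbers
# are the integer nominal masses used for Kendrick-style rescaling.

.atomic_masses <- data.frame(
  element = c("H",  "B",  "C",  "N",  "O",  "F",  "Na", "Mg", "Si", "P",
              "S",  "Cl", "K",  "Ca", "Fe", "Zn", "Se", "Br", "I"),
  exact   = c(1.00782503207, 11.0093054, 12.0, 14.0030740048, 15.9949146196,
              18.99840322, 22.9897692809, 23.985041700, 27.9769265325,
              30.97376163, 31.97207100, 34.96885268, 38.96370668,
              39.96259098, 55.9349375, 63.9291422, 79.9165213,
              78.9183371, 126.904473),
  nominal = c(1L, 11L, 12L, 14L, 16L, 19L, 23L, 24L, 28L, 31L,
              32L, 35L, 39L, 40L, 56L, 64L, 80L, 79L, 127L),
  stringsAsFactors = FALSE
)

#' Monoisotopic atomic masses
#'
#' The embedded table of monoisotopic (most abundant isotope) atomic
#' masses used for all mass computations in the package.
#'
#' @return A data frame with columns `element`, `exact` (Da) and
#'   `nominal` (integer mass number).
#' @examples
#' atomic_mass_table()[1:3, ]
#' @export
atomic_mass_table <- function() .atomic_masses

#' Look up monoisotopic masses for element symbols
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of monoisotopic masses in Da.
#' @keywords internal
atomic_mass <- function(elements) {
  idx <- match(elements, .atomic_masses$element)
  if (anyNA(idx)) {
    mcl_stop("domain", sprintf("no monoisotopic mass for element(s): %s",
                               paste(unique(elements[is.na(idx)]),
                                     collapse = ", ")))
  }
  .atomic_masses$exact[idx]
}

#' Monoisotopic mass of a molecular formula given as element counts
#'
#' @param counts Named integer vector, e.g. `c(C = 6, H = 14)`.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass(c(C = 6, H = 14))  # hexane
#' @export
formula_mass <- function(counts) {
  if (length(counts) == 0L) return(0)
  check_that(!is.null(names(counts)) && all(nzchar(names(counts))),
             "domain", "formula counts must be named by element symbol")
  sum(atomic_mass(names(counts)) * as.numeric(counts))
}
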