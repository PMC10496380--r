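#' Monoisotopic masses of the supported elements
#'
#' Returns the table of most-abundant-isotope masses used by
#' [monoisotopic_mass()]. The built-in set covers the elements found in
#' typical plant secondary metabolites (C, H, N, O, S, P). Further elements
#' can be supplied per call (e.g. halogenated synthetic compounds) without
#' touching the package defaults.
#'
#' Masses are CODATA/IUPAC values to 7 decimal places; carbon-12 is exact by
#' definition.
#'
#' @param extra optional named numeric vector of additional element masses
#'   (Da), e.g. `c(Cl = 34.9688527)`. Entries with names already present
#'   override the defaults.
#' @return named numeric vector, element symbol to monoisotopic mass in Da.
#' @export
#' @examples
#' isotope_masses()
#' isotope_masses(extra = c(Cl = 34.9688527))
isotope_masses <- function(extra = NULL) {
  masses <- c(
    C = 12,
    H = 1.00782503,
    N = 14.0030740,
    O = 15.9949146,
    S = 31.9720707,
    P = 30.9737615
  )
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))) || any(extra <= 0)) {
      stop("'extra' must be a named numeric vector of positive masses", call. = FALSE)
    }
    masses[names(extra)] <- extra
  }
  masses
}

#' Mass of the proton, in Da
#'
#' Used to convert a neutral monoisotopic mass to the m/z of the protonated
#' molecular ion \eqn{[M+H]^+}. This is the proton mass, not the
#' hydrogen-atom mass: protonation adds a bare proton, and using 1.00727646
#' Da reproduces library-grade theoretical m/z values at 4 decimal places.
#' @keywords internal
PROTON_MASS <- 1.00727646

#' Parse a molecular formula into an element composition
#'
#' Accepts plain Hill-style formulas (`"C15H10O7"`) as well as the
#' underscore-decorated dialect common in typeset supplementary tables
#' (`"C_15_H_10_O_7_"`). Underscores, whitespace and dots are stripped before
#' parsing, so a dotted adduct written out in full (`"C14H20O7.NH3"`) is
#' summed element-wise. Adduct *annotations in names* ("+ NH3", "loss H2O")
#' are not interpreted; callers supply the effective formula.
#'
#' @param formula_text a single non-empty formula string.
#' @param elements named numeric vector of supported element masses, as
#'   returned by [isotope_masses()]; only its names are consulted here.
#' @return named integer vector mapping element symbols to counts
#'   (all counts >= 1).
#' @export
#' @examples
#' parse_formula("C15H10O7")
#' parse_formula("C_18_H_16_O_7_")
parse_formula <- function(formula_text, elements = isotope_masses()) {
  if (!is.character(formula_text) || length(formula_text) != 1L || is.na(formula_text)) {
    stop("'formula_text' must be a single character string", call. = FALSE)
  }
  clean <- gsub("[ _.]", "", formula_text)
  if (!nzchar(clean)) {
    stop("cannot parse an empty molecular formula", call. = FALSE)
  }
  tokens <- regmatches(clean, gregexpr("[A-Z][a-z]?[0-9]*", clean))[[1L]]
  if (paste(tokens, collapse = "") != clean) {
    stop(sprintf("malformed molecular formula: '%s'", formula_text), call. = FALSE)
  }
  symbols <- gsub("[0-9]", "", tokens)
  counts <- suppressWarnings(as.integer(gsub("[^0-9]", "", tokens)))
  counts[is.na(counts)] <- 1L
  unknown <- setdiff(symbols, names(elements))
  if (length(unknown)) {
    stop(sprintf(
      "unknown element symbol%s in '%s': %s",
      if (length(unknown) > 1L) "s" else "", formula_text,
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  if (any(counts < 1L)) {
    stop(sprintf("element count of zero in '%s'", formula_text), call. = FALSE)
  }
  out <- vapply(split(counts, symbols), sum, integer(1L))
  # stable, chemistry-conventional order: C, H, then alphabetical
  ord <- c(intersect(c("C", "H"), names(out)), sort(setdiff(names(out), c("C", "H"))))
  out[ord]
}

#' Monoisotopic mass of an element composition
#'
#' Sum over elements of count times most-abundant-isotope mass. An empty
#' composition has mass 0.
#'
#' @param composition named integer vector (element symbol to count), as
#'   returned by [parse_formula()], or a formula string which is parsed first.
#' @param elements named numeric vector of element masses
#'   (see [isotope_masses()]).
#' @return monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C15H10O7")   # quercetin, 302.0427
#' monoisotopic_mass(c(C = 16, H = 18, O = 9))  # chlorogenic acid, 354.0951
monoisotopic_mass <- function(composition, elements = isotope_masses()) {
  if (length(composition) == 0L) {
    return(0)
  }
  if (is.character(composition)) {
    composition <- parse_formula(composition, elements = elements)
  }
  if (is.null(names(composition)) || any(composition < 1)) {
    stop("'composition' must be a named vector of positive counts", call. = FALSE)
  }
  unknown <- setdiff(names(composition), names(elements))
  if (length(unknown)) {
    stop(sprintf("unknown element symbol%s: %s",
                 if (length(unknown) > 1L) "s" else "",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  sum(composition * elements[names(composition)])
}

#' Theoretical m/z of the protonated molecular ion
#'
#' @param monoisotopic neutral monoisotopic mass in Da; must be positive.
#' @return m/z of \eqn{[M+H]^+} in Da (charge 1).
#' @export
#' @examples
#' protonated_mz(monoisotopic_mass("C18H16O7"))  # eupatilin, 345.0969
protonated_mz <- function(monoisotopic) {
  if (!is.numeric(monoisotopic) || any(!is.finite(monoisotopic)) || any(monoisotopic <= 0)) {
    stop("'monoisotopic' must be a positive finite mass", call. = FALSE)
  }
  monoisotopic + PROTON_MASS
}

#' Relative mass error in parts per million
#'
#' \eqn{(measured - theoretical) / theoretical \times 10^6}. The sign
#' convention is that of accurate-mass annotation tables: a measured m/z
#' below the theoretical value gives a negative error.
#'
#' @param measured_mz measured m/z (Da), positive.
#' @param theoretical_mz theoretical m/z (Da), positive.
#' @return signed error in ppm. Vectorised over both arguments.
#' @export
#' @examples
#' ppm_error(303.0498, protonated_mz(monoisotopic_mass("C15H10O7")))
ppm_error <- function(measured_mz, theoretical_mz) {
  if (!is.numeric(measured_mz) || !is.numeric(theoretical_mz)) {
    stop("m/z values must be numeric", call. = FALSE)
  }
  if (any(!is.finite(theoretical_mz)) || any(theoretical_mz <= 0)) {
    stop("'theoretical_mz' must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(measured_mz)) || any(measured_mz <= 0)) {
    stop("'measured_mz' must be positive and finite", call. = FALSE)
  }
  (measured_mz - theoretical_mz) / theoretical_mz * 1e6
}
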