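#' Element reference data
#'
#' Bundled per-element constants used throughout the package: atomic number,
#' atomic mass (u), covalent radius (Cordero single-bond values, Angstrom) used
#' for hydrogen-cap placement, and van der Waals radius (Bondi/Alvarez
#' compilation, Angstrom) used by the Gaussian-overlap volume model.
#'
#' @return A tibble with columns `element`, `number`, `mass`, `r_cov`, `r_vdw`.
#' @examples
#' element_data()
#' @export
element_data <- function() {
  tibble::tribble(
    ~element, ~number, ~mass,    ~r_cov, ~r_vdw,
    "H",       1L,      1.008,   0.31,   1.20,
    "He",      2L,      4.003,   0.28,   1.40,
    "B",       5L,     10.811,   0.84,   1.92,
    "C",       6L,     12.011,   0.76,   1.70,
    "N",       7L,     14.007,   0.71,   1.55,
    "O",       8L,     15.999,   0.66,   1.52,
    "F",       9L,     18.998,   0.57,   1.47,
    "Ne",     10L,     20.180,   0.58,   1.54,
    "Na",     11L,     22.990,   1.66,   2.27,
    "Mg",     12L,     24.305,   1.41,   1.73,
    "Si",     14L,     28.086,   1.11,   2.10,
    "P",      15L,     30.974,   1.07,   1.80,
    "S",      16L,     32.066,   1.05,   1.80,
    "Cl",     17L,     35.453,   1.02,   1.75,
    "Ar",     18L,     39.948,   1.06,   1.88,
    "K",      19L,     39.098,   2.03,   2.75,
    "Ca",     20L,     40.078,   1.76,   2.31,
    "Br",     35L,     79.904,   1.20,   1.85,
    "I",      53L,    126.904,   1.39,   1.98
  )
}

# Fast internal lookup: named vectors keyed by element symbol.
.elem_env <- new.env(parent = emptyenv())

.elem_table <- function() {
  if (is.null(.elem_env$tab)) .elem_env$tab <- element_data()
  .elem_env$tab
}

.elem_lookup <- function(elements, column) {
  tab <- .elem_table()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop("element(s) not in the bundled radius tables: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab[[column]][idx]
}

#' Covalent radii (Angstrom)
#' @param elements Character vector of element symbols.
#' @return Numeric vector of covalent radii.
#' @export
covalent_radius <- function(elements) .elem_lookup(elements, "r_cov")

#' Van der Waals radii (Angstrom)
#' @param elements Character vector of element symbols.
#' @return Numeric vector of van der Waals radii.
#' @export
vdw_radius <- function(elements) .elem_lookup(elements, "r_vdw")

#' Atomic masses (u)
#' @param elements Character vector of element symbols.
#' @return Numeric vector of atomic masses.
#' @export
atomic_mass <- function(elements) .elem_lookup(elements, "mass")

#' Reference bond lengths
#'
#' Static element-pair by bond-order table of reference covalent bond lengths
#' (Angstrom) drawn from standard covalent-geometry compilations. Bond
#' perception declares a bond between two atoms when their distance does not
#' exceed the longest reference length for the pair plus a 0.25 Angstrom
#' tolerance; the assigned order is the one whose reference length is closest
#' to the observed distance. Pairs absent from the table fall back to the sum
#' of covalent radii as a single-bond reference.
#'
#' @return A tibble with columns `a`, `b` (element symbols, unordered pair),
#'   `order` (1, 2 or 3) and `length` (Angstrom).
#' @export
bond_length_table <- function() {
  tibble::tribble(
    ~a,   ~b,   ~order, ~length,
    "H",  "H",  1L, 0.74,
    "C",  "H",  1L, 1.09,
    "N",  "H",  1L, 1.01,
    "O",  "H",  1L, 0.96,
    "S",  "H",  1L, 1.34,
    "P",  "H",  1L, 1.42,
    "C",  "C",  1L, 1.54,
    "C",  "C",  2L, 1.34,
    "C",  "C",  3L, 1.20,
    "C",  "N",  1L, 1.47,
    "C",  "N",  2L, 1.28,
    "C",  "N",  3L, 1.16,
    "C",  "O",  1L, 1.43,
    "C",  "O",  2L, 1.21,
    "C",  "S",  1L, 1.82,
    "C",  "S",  2L, 1.60,
    "C",  "F",  1L, 1.35,
    "C",  "Cl", 1L, 1.77,
    "C",  "Br", 1L, 1.94,
    "C",  "I",  1L, 2.14,
    "C",  "P",  1L, 1.84,
    "N",  "N",  1L, 1.45,
    "N",  "N",  2L, 1.25,
    "N",  "N",  3L, 1.10,
    "N",  "O",  1L, 1.40,
    "N",  "O",  2L, 1.21,
    "O",  "O",  1L, 1.48,
    "O",  "P",  1L, 1.63,
    "O",  "P",  2L, 1.50,
    "O",  "S",  1L, 1.57,
    "O",  "S",  2L, 1.43,
    "S",  "S",  1L, 2.05
  )
}
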