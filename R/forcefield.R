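#' Construct an energy backend
#'
#' A backend is a deterministic function from a geometry tibble (`element`,
#' `x`, `y`, `z`, optional `is_cap`) to a single-point energy in kJ/mol.
#' Backends returning kcal/mol are converted at 4.184 kJ/kcal via the
#' `units` field.
#'
#' @param name Backend name.
#' @param fn Function `geometry -> energy`.
#' @param units "kJ/mol" (default) or "kcal/mol".
#' @param deterministic Same geometry always gives the same energy.
#' @return An `ff_backend` object.
#' @export
ff_backend <- function(name, fn, units = "kJ/mol", deterministic = TRUE) {
  stopifnot(is.function(fn), units %in% c("kJ/mol", "kcal/mol"))
  structure(list(name = name, fn = fn, units = units,
                 deterministic = deterministic),
            class = "ff_backend")
}

#' @export
print.ff_backend <- function(x, ...) {
  cat(sprintf("<ff_backend> %s (%s)\n", x$name, x$units))
  invisible(x)
}

#' Single-point energy of a geometry
#'
#' @param geometry Geometry tibble (`element`, `x`, `y`, `z`).
#' @param backend An `ff_backend`.
#' @return Energy in kJ/mol.
#' @export
ff_energy <- function(geometry, backend) {
  stopifnot(inherits(backend, "ff_backend"))
  e <- backend$fn(geometry)
  if (!is.finite(e)) stop("backend '", backend$name, "' returned a non-finite energy",
                          call. = FALSE)
  if (backend$units == "kcal/mol") e <- e * 4.184
  e
}

#' Additive toy backend
#'
#' Closed-form test backend: the energy is the sum of per-element constants
#' over all atoms (caps included). Useful because every MBE bookkeeping
#' quantity has an exact closed form under additivity.
#'
#' @param constants Named per-element energies (kJ/mol).
#' @return An `ff_backend`.
#' @export
ff_toy_additive <- function(constants = c(H = 1, C = 10, N = 12, O = 14,
                                          S = 20, Cl = 17, F = 9, P = 18,
                                          Br = 35, I = 53)) {
  ff_backend("toy-additive", function(geometry) {
    v <- constants[geometry$element]
    if (anyNA(v)) stop("toy-additive: element without a constant", call. = FALSE)
    sum(v)
  })
}

#' Pairwise toy backend
#'
#' Strictly two-body test backend:
#' `E = sum_i u(element_i) + sum_{i<j} v(r_ij)` with a smooth Gaussian pair
#' term. The two-body MBE is exact for this Hamiltonian (when evaluated on
#' uncapped fragments), which pins down the expansion bookkeeping.
#'
#' @param atom_constants Named per-element energies (kJ/mol).
#' @param pair_scale Amplitude of the Gaussian pair interaction (kJ/mol).
#' @param pair_width Width (Angstrom) of the pair Gaussian.
#' @return An `ff_backend`.
#' @export
ff_toy_pairwise <- function(atom_constants = c(H = 1, C = 10, N = 12, O = 14,
                                               S = 20, Cl = 17, F = 9, P = 18,
                                               Br = 35, I = 53),
                            pair_scale = -2, pair_width = 2.5) {
  ff_backend("toy-pairwise", function(geometry) {
    u <- atom_constants[geometry$element]
    if (anyNA(u)) stop("toy-pairwise: element without a constant", call. = FALSE)
    e <- sum(u)
    n <- nrow(geometry)
    if (n >= 2) {
      d <- stats::dist(as.matrix(geometry[, c("x", "y", "z")]))
      e <- e + sum(pair_scale * exp(-(d / pair_width)^2))
    }
    e
  })
}

#' Three-body toy backend
#'
#' Adds a genuine three-body term to [ff_toy_pairwise()]:
#' `sum_{i<j<k} w * exp(-(r_ij + r_ik + r_jk)/width)`. The three-body MBE is
#' exact for it; the two-body MBE misses exactly the summed triple terms.
#'
#' @inheritParams ff_toy_pairwise
#' @param triple_scale Amplitude of the three-body term (kJ/mol).
#' @param triple_width Decay length (Angstrom) of the three-body term.
#' @return An `ff_backend`.
#' @export
ff_toy_threebody <- function(atom_constants = c(H = 1, C = 10, N = 12, O = 14,
                                                S = 20, Cl = 17, F = 9, P = 18,
                                                Br = 35, I = 53),
                             pair_scale = -2, pair_width = 2.5,
                             triple_scale = 0.5, triple_width = 4) {
  pairwise <- ff_toy_pairwise(atom_constants, pair_scale, pair_width)
  ff_backend("toy-threebody", function(geometry) {
    e <- pairwise$fn(geometry)
    n <- nrow(geometry)
    if (n >= 3) {
      dm <- as.matrix(stats::dist(as.matrix(geometry[, c("x", "y", "z")])))
      trips <- utils::combn(n, 3)
      peri <- dm[cbind(trips[1, ], trips[2, ])] +
        dm[cbind(trips[1, ], trips[3, ])] +
        dm[cbind(trips[2, ], trips[3, ])]
      e <- e + sum(triple_scale * exp(-peri / triple_width))
    }
    e
  })
}

#' Universal force field backend (Open Babel)
#'
#' Production backend: single-point UFF energies computed by the `obenergy`
#' tool from Open Babel (no geometry optimisation). Requires `obenergy` on
#' the PATH.
#'
#' @return An `ff_backend`.
#' @export
ff_uff <- function() {
  if (Sys.which("obenergy") == "") {
    stop("obenergy (Open Babel) not found on PATH; UFF backend unavailable",
         call. = FALSE)
  }
  ff_backend("uff-openbabel", function(geometry) {
    tmp <- tempfile(fileext = ".xyz")
    on.exit(unlink(tmp))
    write_xyz(geometry, tmp)
    out <- suppressWarnings(
      system2("obenergy", c("-ff", "UFF", shQuote(tmp)),
              stdout = TRUE, stderr = FALSE)
    )
    line <- grep("^TOTAL ENERGY", out, value = TRUE)
    if (!length(line)) stop("obenergy produced no total energy", call. = FALSE)
    val <- as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1", line[1]))
    if (grepl("kcal", line[1])) val <- val * 4.184
    val
  })
}

#' Dimer energy correction of a cut edge
#'
#' For a broken edge whose endpoints fall in fragments I and J,
#' `dE_IJ = E_IJ - E_I - E_J` where `E_I`, `E_J` are the capped monomer
#' energies and `E_IJ` the energy of their union with this edge restored
#' (caps on all other broken bonds retained, at the original coordinates).
#' Large corrections flag chemically damaging cuts: the optimiser blacklists
#' edges with `dE_IJ` above 10 kJ/mol during its first iterations.
#'
#' @param graph A `mol_graph`.
#' @param state A `frag_state` with the edge flagged broken.
#' @param edge Integer position of the edge in `state$edges`.
#' @param backend Energy backend.
#' @param cache Optional environment memoising results by edge +
#'   neighbouring-cut signature.
#' @return Correction in kJ/mol.
#' @export
dimer_energy_correction <- function(graph, state, edge, backend, cache = NULL) {
  stopifnot(state$bits[edge] == 1L)
  i <- state$edges$from[edge]; j <- state$edges$to[edge]
  membership <- .fragment_membership(graph, state)
  if (membership[i] == membership[j]) {
    stop("edge endpoints are in the same fragment; state is inconsistent",
         call. = FALSE)
  }
  atoms_i <- which(membership == membership[i])
  atoms_j <- which(membership == membership[j])
  broken <- state$edges[state$bits == 1L, ]
  if (!is.null(cache)) {
    touching <- broken$from %in% c(atoms_i, atoms_j) |
      broken$to %in% c(atoms_i, atoms_j)
    key <- paste(edge, paste(sort(broken$edge[touching]), collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
  }
  e_i <- ff_energy(.capped_geometry(graph, atoms_i, broken), backend)
  e_j <- ff_energy(.capped_geometry(graph, atoms_j, broken), backend)
  union_atoms <- sort(c(atoms_i, atoms_j))
  e_ij <- ff_energy(.capped_geometry(graph, union_atoms, broken), backend)
  val <- e_ij - e_i - e_j
  if (!is.null(cache)) cache[[key]] <- val
  val
}

# capped geometry of an atom subset: caps on broken bonds crossing the
# subset boundary; broken bonds internal to the subset are restored (no cap)
.capped_geometry <- function(graph, atom_subset, broken) {
  crossing <- broken[xor(broken$from %in% atom_subset,
                         broken$to %in% atom_subset), , drop = FALSE]
  caps <- cap_with_hydrogens(atom_subset, graph, crossing)
  at <- graph$atoms
  nf <- length(atom_subset); nc <- nrow(caps)
  tibble::new_tibble(list(
    element = c(at$element[atom_subset], caps$element),
    x = c(at$x[atom_subset], caps$x), y = c(at$y[atom_subset], caps$y),
    z = c(at$z[atom_subset], caps$z),
    is_cap = rep(c(FALSE, TRUE), c(nf, nc))
  ), nrow = nf + nc)
}

# whole-system geometry without caps
.bare_geometry <- function(graph) {
  at <- graph$atoms
  tibble::new_tibble(list(element = at$element, x = at$x, y = at$y, z = at$z,
                          is_cap = rep(FALSE, nrow(at))), nrow = nrow(at))
}
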