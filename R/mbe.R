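#' Enumerate MBE n-mer index tuples
#'
#' All dimers (and, at level 3, all trimers) over the fragment set — no
#' distance screening.
#'
#' @param n_fragments Number of fragments.
#' @param level 2 or 3.
#' @return List with `dimers` (2-row matrix of strictly increasing index
#'   pairs) and `trimers` (3-row matrix, empty at level 2).
#' @export
enumerate_nmers <- function(n_fragments, level = 2) {
  stopifnot(level %in% c(2, 3))
  dimers <- if (n_fragments >= 2) utils::combn(n_fragments, 2) else
    matrix(integer(), nrow = 2)
  trimers <- if (level == 3 && n_fragments >= 3) utils::combn(n_fragments, 3) else
    matrix(integer(), nrow = 3)
  list(dimers = dimers, trimers = trimers)
}

#' Many-body expansion energy of a fragmentation
#'
#' Assembles the MBE energy from backend energies of capped monomers, dimers
#' and (level 3) trimers:
#' \eqn{E_{MBE} = \sum_I E_I + \sum_{I<J} \Delta E_{IJ} +
#'      \sum_{I<J<K} \Delta E_{IJK}}
#' with \eqn{\Delta E_{IJ} = E_{IJ} - E_I - E_J} and
#' \eqn{\Delta E_{IJK} = E_{IJK} - \Delta E_{IJ} - \Delta E_{IK} -
#'      \Delta E_{JK} - E_I - E_J - E_K}.
#' An n-mer geometry is the union of its member fragments with hydrogen caps
#' only on cut bonds crossing the union boundary (cut bonds internal to the
#' union are restored, so the corrections telescope).
#'
#' @param graph A `mol_graph`.
#' @param state A `frag_state`.
#' @param backend Energy backend ([ff_backend()]).
#' @param level MBE truncation level, 2 or 3 (1 = monomers only).
#' @param cap Cap severed bonds with hydrogens (default `TRUE`). `cap = FALSE`
#'   evaluates the expansion on bare atom subsets, isolating the bookkeeping
#'   from the capping approximation (used by the exactness properties of the
#'   toy Hamiltonians).
#' @param e_tot Optional externally supplied total energy (kJ/mol); computed
#'   from the backend when `NULL`.
#' @return An `mbe_terms` object: monomer energies, dimer/trimer correction
#'   tibbles, `e_mbe`, `e_tot` and the fragmentation error
#'   `delta_e = e_tot - e_mbe`.
#' @export
mbe_energy <- function(graph, state, backend, level = 2, cap = TRUE,
                       e_tot = NULL) {
  stopifnot(level %in% c(1, 2, 3))
  membership <- .fragment_membership(graph, state)
  broken <- state$edges[state$bits == 1L, ]
  frag_ids <- sort(unique(membership))
  frag_atoms <- lapply(frag_ids, function(f) which(membership == f))
  n_f <- length(frag_atoms)

  geom_of <- function(atom_sets) {
    atoms <- sort(unlist(atom_sets))
    if (cap) .capped_geometry(graph, atoms, broken) else
      .capped_geometry(graph, atoms, broken[0, , drop = FALSE])
  }
  energy_of <- function(atom_sets, what) {
    tryCatch(ff_energy(geom_of(atom_sets), backend),
             error = function(e) stop("backend failed on ", what, ": ",
                                      conditionMessage(e), call. = FALSE))
  }

  e_mono <- vapply(seq_len(n_f), function(i)
    energy_of(frag_atoms[i], paste0("monomer ", i)), 0)

  nm <- enumerate_nmers(max(n_f, 2), level = max(level, 2))
  dimers <- tibble::tibble(i = integer(), j = integer(), e = numeric(),
                           delta = numeric())
  if (level >= 2 && n_f >= 2) {
    dm <- nm$dimers
    dm <- dm[, dm[1, ] <= n_f & dm[2, ] <= n_f, drop = FALSE]
    e_d <- vapply(seq_len(ncol(dm)), function(c) {
      energy_of(frag_atoms[dm[, c]], sprintf("dimer %d-%d", dm[1, c], dm[2, c]))
    }, 0)
    dimers <- tibble::tibble(
      i = dm[1, ], j = dm[2, ], e = e_d,
      delta = e_d - e_mono[dm[1, ]] - e_mono[dm[2, ]]
    )
  }
  trimers <- tibble::tibble(i = integer(), j = integer(), k = integer(),
                            e = numeric(), delta = numeric())
  if (level == 3 && n_f >= 3) {
    tm <- nm$trimers
    d_lookup <- function(a, b) dimers$delta[dimers$i == min(a, b) &
                                              dimers$j == max(a, b)]
    e_t <- vapply(seq_len(ncol(tm)), function(c) {
      energy_of(frag_atoms[tm[, c]],
                sprintf("trimer %d-%d-%d", tm[1, c], tm[2, c], tm[3, c]))
    }, 0)
    delta_t <- vapply(seq_len(ncol(tm)), function(c) {
      i <- tm[1, c]; j <- tm[2, c]; k <- tm[3, c]
      e_t[c] - d_lookup(i, j) - d_lookup(i, k) - d_lookup(j, k) -
        e_mono[i] - e_mono[j] - e_mono[k]
    }, 0)
    trimers <- tibble::tibble(i = tm[1, ], j = tm[2, ], k = tm[3, ],
                              e = e_t, delta = delta_t)
  }

  e_mbe <- sum(e_mono) +
    (if (level >= 2) sum(dimers$delta) else 0) +
    (if (level == 3) sum(trimers$delta) else 0)
  if (is.null(e_tot)) {
    geom_all <- tibble::tibble(element = graph$atoms$element,
                               x = graph$atoms$x, y = graph$atoms$y,
                               z = graph$atoms$z, is_cap = FALSE)
    e_tot <- ff_energy(geom_all, backend)
  }
  structure(
    list(monomer_energies = e_mono, dimer_corrections = dimers,
         trimer_corrections = trimers, level = level,
         e_mbe = e_mbe, e_tot = e_tot,
         delta_e = fragmentation_error(e_tot, e_mbe)),
    class = "mbe_terms"
  )
}

#' Fragmentation energy error
#'
#' Signed difference between the unfragmented total energy and the
#' fragmentation-derived energy, `delta_e = e_tot - e_f`.
#'
#' @param e_tot Total (unfragmented) energy, kJ/mol.
#' @param e_f Fragmentation energy (e.g. `e_mbe`), kJ/mol.
#' @return Signed error in kJ/mol (report `abs()` alongside as needed).
#' @export
fragmentation_error <- function(e_tot, e_f) e_tot - e_f

#' @export
print.mbe_terms <- function(x, ...) {
  cat(sprintf("<mbe_terms> level %d: E_MBE = %.6f, E_tot = %.6f, dE = %.6g kJ/mol\n",
              x$level, x$e_mbe, x$e_tot, x$delta_e))
  invisible(x)
}

#' Tidy MBE terms
#'
#' @param x An `mbe_terms` object.
#' @param ... Unused.
#' @return Long tibble of monomer energies and dimer/trimer corrections.
#' @export
tidy.mbe_terms <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(order = 1L,
                   indices = as.character(seq_along(x$monomer_energies)),
                   energy = x$monomer_energies),
    tibble::tibble(order = 2L,
                   indices = paste(x$dimer_corrections$i, x$dimer_corrections$j,
                                   sep = "-"),
                   energy = x$dimer_corrections$delta),
    tibble::tibble(order = 3L,
                   indices = paste(x$trimer_corrections$i, x$trimer_corrections$j,
                                   x$trimer_corrections$k, sep = "-"),
                   energy = x$trimer_corrections$delta)
  )
}

#' @export
glance.mbe_terms <- function(x, ...) {
  tibble::tibble(level = x$level, e_mbe = x$e_mbe, e_tot = x$e_tot,
                 delta_e = x$delta_e, abs_delta_e = abs(x$delta_e),
                 n_fragments = length(x$monomer_energies))
}

#' Assemble an MBE from externally computed n-mer energies
#'
#' Accepts a table of per-n-mer energies (e.g. ab initio energies computed
#' elsewhere) and assembles the expansion without calling a backend.
#'
#' @param energies Tibble/data frame with columns `indices` (fragment indices
#'   separated by "-", e.g. `"1"`, `"1-3"`, `"1-2-4"`) and `energy` (kJ/mol).
#' @param level 2 or 3.
#' @param e_tot Optional total energy for the error.
#' @return An `mbe_terms` object.
#' @export
mbe_from_energies <- function(energies, level = 2, e_tot = NA_real_) {
  idx <- strsplit(as.character(energies$indices), "-")
  ord <- lengths(idx)
  mono <- energies$energy[ord == 1][order(as.integer(unlist(idx[ord == 1])))]
  n_f <- length(mono)
  get_e <- function(key) {
    hit <- which(vapply(idx, function(v) identical(as.integer(v), key), TRUE))
    if (!length(hit)) stop("missing energy for n-mer ", paste(key, collapse = "-"),
                           call. = FALSE)
    energies$energy[hit[1]]
  }
  nm <- enumerate_nmers(n_f, level = level)
  dimers <- tibble::tibble(i = integer(), j = integer(), e = numeric(),
                           delta = numeric())
  if (n_f >= 2) {
    e_d <- vapply(seq_len(ncol(nm$dimers)), function(c)
      get_e(as.integer(nm$dimers[, c])), 0)
    dimers <- tibble::tibble(i = nm$dimers[1, ], j = nm$dimers[2, ], e = e_d,
                             delta = e_d - mono[nm$dimers[1, ]] - mono[nm$dimers[2, ]])
  }
  trimers <- tibble::tibble(i = integer(), j = integer(), k = integer(),
                            e = numeric(), delta = numeric())
  if (level == 3 && n_f >= 3) {
    d_lookup <- function(a, b) dimers$delta[dimers$i == min(a, b) &
                                              dimers$j == max(a, b)]
    e_t <- vapply(seq_len(ncol(nm$trimers)), function(c)
      get_e(as.integer(nm$trimers[, c])), 0)
    delta_t <- vapply(seq_len(ncol(nm$trimers)), function(c) {
      i <- nm$trimers[1, c]; j <- nm$trimers[2, c]; k <- nm$trimers[3, c]
      e_t[c] - d_lookup(i, j) - d_lookup(i, k) - d_lookup(j, k) -
        mono[i] - mono[j] - mono[k]
    }, 0)
    trimers <- tibble::tibble(i = nm$trimers[1, ], j = nm$trimers[2, ],
                              k = nm$trimers[3, ], e = e_t, delta = delta_t)
  }
  e_mbe <- sum(mono) + sum(dimers$delta) +
    (if (level == 3) sum(trimers$delta) else 0)
  structure(
    list(monomer_energies = mono, dimer_corrections = dimers,
         trimer_corrections = trimers, level = level,
         e_mbe = e_mbe, e_tot = e_tot,
         delta_e = if (is.na(e_tot)) NA_real_ else fragmentation_error(e_tot, e_mbe)),
    class = "mbe_terms"
  )
}
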