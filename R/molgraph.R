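#' Perceive covalent bonds from coordinates
#'
#' Bonds and bond orders are assigned by comparing interatomic distances with
#' the bundled reference-length table ([bond_length_table()]): a bond exists
#' between two atoms when their distance is at most the longest reference
#' length tabulated for that element pair plus 0.25 Angstrom, and the assigned
#' order is the reference order with the smallest absolute length deviation.
#' Element pairs without a tabulated entry fall back to the sum of covalent
#' radii as a single-bond reference.
#'
#' @param atoms Atoms tibble with columns `element`, `x`, `y`, `z`.
#' @return A bonds tibble with columns `from`, `to` (row indices into `atoms`,
#'   `from < to`), `order` and `length` (Angstrom).
#' @export
perceive_bonds <- function(atoms) {
  n <- nrow(atoms)
  stopifnot(n >= 1)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  if (n == 1) {
    return(tibble::tibble(from = integer(), to = integer(),
                          order = integer(), length = numeric()))
  }
  d <- as.matrix(stats::dist(xyz))
  ij <- which(upper.tri(d), arr.ind = TRUE)
  len <- d[ij]

  too_close <- which(len < 0.3)
  if (length(too_close)) {
    k <- too_close[1]
    stop(sprintf("overlapping atoms %d and %d (distance %.3f Angstrom)",
                 ij[k, 1], ij[k, 2], len[k]), call. = FALSE)
  }

  ref <- bond_length_table()
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  ref_key <- key(ref$a, ref$b)
  pair_key <- key(atoms$element[ij[, 1]], atoms$element[ij[, 2]])

  # longest tabulated reference per pair, for the existence window
  max_ref <- tapply(ref$length, ref_key, max)
  win <- unname(max_ref[pair_key])
  fallback <- covalent_radius(atoms$element[ij[, 1]]) +
    covalent_radius(atoms$element[ij[, 2]])
  win[is.na(win)] <- fallback[is.na(win)]

  hit <- which(len <= win + 0.25)
  if (!length(hit)) {
    return(tibble::tibble(from = integer(), to = integer(),
                          order = integer(), length = numeric()))
  }

  ord <- integer(length(hit))
  for (h in seq_along(hit)) {
    k <- hit[h]
    cand <- ref[ref_key == pair_key[k], ]
    if (nrow(cand) == 0) {
      ord[h] <- 1L
    } else {
      ord[h] <- cand$order[which.min(abs(len[k] - cand$length))]
    }
  }
  out <- tibble::tibble(
    from = as.integer(ij[hit, 1]), to = as.integer(ij[hit, 2]),
    order = ord, length = len[hit]
  )
  dplyr::arrange(out, .data$from, .data$to)
}

#' Assign node attributes (hybridisation, pi electrons, radii)
#'
#' Hybridisation follows multiple-bond participation: a triple bond or two
#' double bonds gives sp, exactly one double bond gives sp2, hydrogens and
#' halogens are "other", everything else is sp3. A second pass promotes sp3
#' N/O/S atoms adjacent to an sp2/sp atom to sp2, modelling lone-pair
#' donation into the pi path (as in pyrrole or an amide nitrogen).
#'
#' Provisional per-atom pi contributions are recorded (`pi_provisional`): 1
#' for a double-bond atom, 2 for a triple-bond atom or promoted lone-pair
#' donor, 2 for an anionic sp2 carbon and 0 for a cationic one. The final
#' `n_pi` attribute is non-zero only for members of a conjugated system and is
#' filled in by [find_conjugated_systems()].
#'
#' @param atoms Atoms tibble.
#' @param bonds Bonds tibble from [perceive_bonds()].
#' @return The atoms tibble with columns `id`, `hybridisation`,
#'   `pi_provisional`, `n_pi` (0 until systems are found), `r_cov`, `r_vdw`,
#'   `mass` added.
#' @export
assign_node_attributes <- function(atoms, bonds) {
  n <- nrow(atoms)
  atoms$id <- seq_len(n)
  if (!("formal_charge" %in% names(atoms))) atoms$formal_charge <- 0L
  atoms$r_cov <- covalent_radius(atoms$element)
  atoms$r_vdw <- vdw_radius(atoms$element)
  atoms$mass <- atomic_mass(atoms$element)

  n_double <- n_triple <- integer(n)
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] == 2L) {
      n_double[bonds$from[k]] <- n_double[bonds$from[k]] + 1L
      n_double[bonds$to[k]] <- n_double[bonds$to[k]] + 1L
    } else if (bonds$order[k] == 3L) {
      n_triple[bonds$from[k]] <- n_triple[bonds$from[k]] + 1L
      n_triple[bonds$to[k]] <- n_triple[bonds$to[k]] + 1L
    }
  }

  hyb <- rep("sp3", n)
  hyb[n_triple >= 1L | n_double >= 2L] <- "sp"
  hyb[n_triple == 0L & n_double == 1L] <- "sp2"
  hyb[atoms$element %in% c("H", "F", "Cl", "Br", "I", "He", "Ne", "Ar")] <- "other"

  # lone-pair promotion: sp3 N/O/S next to an sp2/sp heavy atom joins the
  # pi path (pyrrole N, amide N, ester O ...)
  nb <- .neighbour_list(n, bonds)
  promoted <- logical(n)
  for (i in which(hyb == "sp3" & atoms$element %in% c("N", "O", "S"))) {
    if (any(hyb[nb[[i]]] %in% c("sp", "sp2"))) {
      promoted[i] <- TRUE
    }
  }
  hyb[promoted] <- "sp2"

  pi_prov <- integer(n)
  pi_prov[n_double == 1L] <- 1L
  pi_prov[n_triple >= 1L | n_double >= 2L] <- 2L
  pi_prov[promoted] <- 2L
  is_c <- atoms$element == "C" & hyb == "sp2"
  pi_prov[is_c & atoms$formal_charge > 0L] <- 0L
  pi_prov[is_c & atoms$formal_charge < 0L] <- 2L

  atoms$hybridisation <- hyb
  atoms$pi_provisional <- pi_prov
  atoms$lp_promoted <- promoted
  atoms$n_pi <- 0L
  atoms
}

.neighbour_list <- function(n, bonds) {
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer()
  for (k in seq_len(nrow(bonds))) {
    nb[[bonds$from[k]]] <- c(nb[[bonds$from[k]]], bonds$to[k])
    nb[[bonds$to[k]]] <- c(nb[[bonds$to[k]]], bonds$from[k])
  }
  nb
}

#' Find conjugated systems
#'
#' A conjugated system is a maximal connected component of the subgraph
#' induced by sp2/sp atoms, with at least three members. Each system stores
#' the per-atom pi contributions, its conjugation score
#' \eqn{cs = (1/N_A) \sum_i N_e^i / N_A}, and its internal bonds. The `n_pi`
#' attribute of member atoms is set from the provisional contributions; all
#' other atoms keep `n_pi = 0`.
#'
#' @param atoms Attributed atoms tibble ([assign_node_attributes()]).
#' @param bonds Bonds tibble.
#' @return List with `systems` (list of conjugated-system records:
#'   `atom_indices`, `pi_contribution`, `n_atoms`, `cs`, `member_bonds`,
#'   `delta_max`) and `atoms` (atoms with `n_pi` filled in).
#' @export
find_conjugated_systems <- function(atoms, bonds) {
  sp_atoms <- which(atoms$hybridisation %in% c("sp", "sp2"))
  systems <- list()
  if (length(sp_atoms) >= 3) {
    sub_bonds <- bonds[bonds$from %in% sp_atoms & bonds$to %in% sp_atoms, ]
    g <- igraph::make_empty_graph(n = nrow(atoms), directed = FALSE)
    g <- igraph::add_edges(g, rbind(sub_bonds$from, sub_bonds$to))
    comp <- igraph::components(g)
    for (cid in seq_len(comp$no)) {
      members <- intersect(which(comp$membership == cid), sp_atoms)
      if (length(members) < 3) next
      pi_contrib <- atoms$pi_provisional[members]
      names(pi_contrib) <- members
      na <- length(members)
      cs <- sum(pi_contrib / na) / na
      mb <- bonds[bonds$from %in% members & bonds$to %in% members, ]
      systems[[length(systems) + 1L]] <- list(
        atom_indices = members,
        pi_contribution = pi_contrib,
        n_atoms = na,
        cs = cs,
        member_bonds = mb,
        delta_max = na - 1
      )
    }
  }
  in_system <- unlist(lapply(systems, `[[`, "atom_indices"))
  atoms$n_pi <- 0L
  atoms$n_pi[in_system] <- atoms$pi_provisional[in_system]
  list(systems = systems, atoms = atoms)
}

#' Find hyperconjugated donor/acceptor pairs
#'
#' Enumerates sigma and pi groups and pairs them when exactly one member of
#' the pair is a sigma system and the other a pi system, their atom sets are
#' disjoint, and the graph distance between the groups is between one and
#' three bonds.
#'
#' Pi groups: conjugated systems (donor/acceptor), isolated C=C and C#C
#' double/triple bonds (donor/acceptor), isolated C=O (acceptor), charged sp2
#' carbons (cation acceptor, anion donor), and sp3 N/O lone pairs (donor).
#' Sigma groups: C-H bonds (donor/acceptor) and C-halogen bonds (acceptor);
#' on a halogen-bearing carbon the more polarised C-halogen bond supersedes
#' that carbon's C-H bonds. When both orientations of a pair are admissible
#' the pi group is taken as the donor, so each group pair is counted once.
#'
#' @param atoms Attributed atoms tibble.
#' @param bonds Bonds tibble.
#' @param conj_systems Conjugated systems ([find_conjugated_systems()]).
#' @return List of pair records: `donor`/`acceptor` (each `atoms`, `type`
#'   ("sigma"/"pi"), `label`), `separation_bonds`, `donated_electrons`,
#'   `donor_atom_count`, `delta_max`, `donor_per_atom` (named contribution
#'   vector used when a donor group is split across fragments).
#' @export
find_hyperconjugated_pairs <- function(atoms, bonds, conj_systems) {
  n <- nrow(atoms)
  groups <- list()
  add_group <- function(atoms_idx, type, roles, label, n_e, per_atom = NULL) {
    if (is.null(per_atom)) {
      per_atom <- rep(n_e / length(atoms_idx), length(atoms_idx))
      names(per_atom) <- atoms_idx
    }
    groups[[length(groups) + 1L]] <<- list(
      atoms = as.integer(atoms_idx), type = type, roles = roles,
      label = label, n_e = n_e, per_atom = per_atom
    )
  }

  conj_atoms <- integer()
  for (cs in conj_systems) {
    pa <- cs$pi_contribution
    add_group(cs$atom_indices, "pi", c("donor", "acceptor"),
              "conjugated-system", sum(pa), per_atom = pa)
    conj_atoms <- c(conj_atoms, cs$atom_indices)
  }

  elem <- atoms$element
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$from[k]; j <- bonds$to[k]
    ei <- elem[i]; ej <- elem[j]
    if (bonds$order[k] >= 2L && ei == "C" && ej == "C" &&
        !(i %in% conj_atoms) && !(j %in% conj_atoms)) {
      add_group(c(i, j), "pi", c("donor", "acceptor"),
                if (bonds$order[k] == 3L) "C#C" else "C=C", 2)
    }
    if (bonds$order[k] == 2L && sort(c(ei, ej))[1] == "C" &&
        sort(c(ei, ej))[2] == "O" && !(i %in% conj_atoms) && !(j %in% conj_atoms)) {
      add_group(c(i, j), "pi", "acceptor", "C=O", 0)
    }
  }

  # charged sp2 carbons and sp3 N/O lone pairs outside conjugated systems
  for (i in seq_len(n)) {
    if (i %in% conj_atoms) next
    if (elem[i] == "C" && atoms$hybridisation[i] == "sp2") {
      if (atoms$formal_charge[i] > 0L) add_group(i, "pi", "acceptor", "C+(sp2)", 0)
      if (atoms$formal_charge[i] < 0L) add_group(i, "pi", "donor", "C-(sp2)", 2)
    }
    if (elem[i] %in% c("N", "O") && atoms$hybridisation[i] == "sp3") {
      add_group(i, "pi", "donor", paste0(elem[i], "(sp3)"), 2)
    }
  }

  halogens <- c("F", "Cl", "Br", "I")
  has_halogen <- logical(n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$from[k]; j <- bonds$to[k]
    if (elem[i] == "C" && elem[j] %in% halogens) has_halogen[i] <- TRUE
    if (elem[j] == "C" && elem[i] %in% halogens) has_halogen[j] <- TRUE
  }
  for (k in seq_len(nrow(bonds))) {
    if (bonds$order[k] != 1L) next
    i <- bonds$from[k]; j <- bonds$to[k]
    cx <- if (elem[i] == "C") i else if (elem[j] == "C") j else next
    xx <- setdiff(c(i, j), cx)
    if (elem[xx] %in% halogens) {
      add_group(c(cx, xx), "sigma", "acceptor", paste0("C-", elem[xx]), 0)
    } else if (elem[xx] == "H" && !has_halogen[cx]) {
      add_group(c(cx, xx), "sigma", c("donor", "acceptor"), "C-H", 2)
    }
  }

  if (length(groups) < 2) return(list())

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(bonds$from, bonds$to))
  dmat <- igraph::distances(g)

  pairs <- list()
  ng <- length(groups)
  for (a in seq_len(ng - 1)) {
    for (b in seq(a + 1, ng)) {
      ga <- groups[[a]]; gb <- groups[[b]]
      if (ga$type == gb$type) next
      if (length(intersect(ga$atoms, gb$atoms)) > 0) next
      # weakly polarised C-H sigma bonds couple to localised pi systems
      # (isolated multiple bonds, lone pairs, charged carbons) but not to
      # delocalised conjugated systems; C-halogen acceptors couple to both
      labels <- c(ga$label, gb$label)
      if ("C-H" %in% labels && "conjugated-system" %in% labels) next
      sep <- min(dmat[ga$atoms, gb$atoms, drop = FALSE])
      if (!is.finite(sep) || sep < 1 || sep > 3) next
      pi_g <- if (ga$type == "pi") ga else gb
      sg_g <- if (ga$type == "pi") gb else ga
      # orientation: pi donor preferred when both directions are legal
      if ("donor" %in% pi_g$roles && "acceptor" %in% sg_g$roles) {
        donor <- pi_g; acceptor <- sg_g
      } else if ("donor" %in% sg_g$roles && "acceptor" %in% pi_g$roles) {
        donor <- sg_g; acceptor <- pi_g
      } else next
      pairs[[length(pairs) + 1L]] <- list(
        donor = donor[c("atoms", "type", "label")],
        acceptor = acceptor[c("atoms", "type", "label")],
        separation_bonds = as.integer(sep),
        donated_electrons = donor$n_e,
        donor_atom_count = length(donor$atoms),
        delta_max = donor$n_e / length(donor$atoms),
        donor_per_atom = donor$per_atom
      )
    }
  }
  pairs
}

#' Build an attributed molecular graph
#'
#' Runs bond perception, node attribution, conjugated-system detection and
#' hyperconjugated-pair enumeration on a table of atoms, returning the full
#' annotated graph used by the fragmentation machinery.
#'
#' @param atoms Atoms tibble (`element`, `x`, `y`, `z`, optionally
#'   `formal_charge`); from [read_structure()] or a fixture builder.
#' @return A `mol_graph` object: list with `atoms`, `bonds`, `conj_systems`,
#'   `hyper_pairs`, `graph` (igraph), `n_atoms`.
#' @examples
#' g <- mol_graph(build_named_molecule("methanol"))
#' nrow(g$bonds)  # 5
#' @export
mol_graph <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- perceive_bonds(atoms)
  atoms <- assign_node_attributes(atoms, bonds)
  cs <- find_conjugated_systems(atoms, bonds)
  atoms <- cs$atoms
  hp <- find_hyperconjugated_pairs(atoms, bonds, cs$systems)
  g <- igraph::make_empty_graph(n = nrow(atoms), directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, rbind(bonds$from, bonds$to))
  structure(
    list(atoms = atoms, bonds = bonds, conj_systems = cs$systems,
         hyper_pairs = hp, graph = g, n_atoms = nrow(atoms)),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds, %d conjugated system(s), %d hyperconjugated pair(s)\n",
              x$n_atoms, nrow(x$bonds), length(x$conj_systems),
              length(x$hyper_pairs)))
  invisible(x)
}

#' Tidy a molecular graph
#'
#' @param x A `mol_graph`.
#' @param ... Unused.
#' @return The atoms tibble with perception annotations.
#' @export
tidy.mol_graph <- function(x, ...) x$atoms

#' One-row summary of a molecular graph
#' @param x A `mol_graph`.
#' @param ... Unused.
#' @export
glance.mol_graph <- function(x, ...) {
  tibble::tibble(
    n_atoms = x$n_atoms,
    n_bonds = nrow(x$bonds),
    n_conjugated_systems = length(x$conj_systems),
    n_hyperconjugated_pairs = length(x$hyper_pairs)
  )
}
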