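#' Allowed edges of the fragmentation solution space
#'
#' Only order-1 bonds that are bridges of the molecular graph are candidate
#' cut sites (cutting a ring bond leaves the molecule connected, so capping
#' would be ill-defined), and a bridge is kept only when its removal leaves
#' two components that are each at least `ceil(0.6 * n_t)` atoms, so no cut
#' can create a fragment smaller than 60% of the target size.
#'
#' @param graph A `mol_graph`.
#' @param n_t Target fragment size (atoms), `>= 2`.
#' @return Ordered tibble of allowed edges (`from`, `to`, `edge` = position in
#'   the gene vector). Empty when the system cannot be fragmented.
#' @export
allowed_edges <- function(graph, n_t) {
  stopifnot(n_t >= 2)
  min_side <- ceiling(0.6 * n_t)
  single <- graph$bonds[graph$bonds$order == 1L, ]
  if (!nrow(single)) {
    return(tibble::tibble(from = integer(), to = integer(), edge = integer()))
  }
  bridge_eids <- igraph::bridges(graph$graph)
  bridge_ends <- igraph::ends(graph$graph, bridge_eids)
  bridge_key <- paste(pmin(bridge_ends[, 1], bridge_ends[, 2]),
                      pmax(bridge_ends[, 1], bridge_ends[, 2]))
  keep <- paste(single$from, single$to) %in% bridge_key
  single <- single[keep, ]
  ok <- logical(nrow(single))
  for (k in seq_len(nrow(single))) {
    sz <- .split_sizes(graph, single$from[k], single$to[k])
    ok[k] <- min(sz) >= min_side
  }
  out <- single[ok, c("from", "to")]
  out <- dplyr::arrange(out, .data$from, .data$to)
  out$edge <- seq_len(nrow(out))
  out
}

# component sizes after deleting bridge (i, j)
.split_sizes <- function(graph, i, j) {
  eid <- igraph::get_edge_ids(graph$graph, c(i, j))
  g2 <- igraph::delete_edges(graph$graph, eid)
  memb <- igraph::components(g2)$membership
  c(sum(memb == memb[i]), sum(memb == memb[j]))
}

#' Construct a fragmentation state
#'
#' A fragmentation is a binary vector over the allowed edges: 1 = broken,
#' 0 = intact.
#'
#' @param edges Allowed-edge tibble from [allowed_edges()].
#' @param bits Integer/logical vector of the same length (default: no cuts).
#' @return A `frag_state` object.
#' @export
fragmentation_state <- function(edges, bits = rep(0L, nrow(edges))) {
  bits <- as.integer(bits)
  stopifnot(length(bits) == nrow(edges), all(bits %in% c(0L, 1L)))
  structure(list(edges = edges, bits = bits), class = "frag_state")
}

#' @export
print.frag_state <- function(x, ...) {
  cat(sprintf("<frag_state> %d allowed edges, %d broken\n",
              length(x$bits), sum(x$bits)))
  invisible(x)
}

# fragment membership per atom under a state (integer vector)
.fragment_membership <- function(graph, state) {
  broken <- state$edges[state$bits == 1L, ]
  g2 <- graph$graph
  if (nrow(broken)) {
    eids <- igraph::get_edge_ids(g2, rbind(broken$from, broken$to))
    g2 <- igraph::delete_edges(g2, eids)
  }
  igraph::components(g2)$membership
}

#' Place hydrogen caps on a fragment's severed bonds
#'
#' For a severed bond i-j with i inside the fragment, the cap hydrogen is
#' placed on the bond axis at
#' \eqn{x(H) = x(i) + \frac{r(i)+r(H)}{r(i)+r(j)} (x(j)-x(i))}
#' with r the Cordero covalent radii, i.e. at the position where an i-H bond
#' of proportional length would end.
#'
#' @param fragment_atoms Integer vector of atom ids in the fragment.
#' @param graph The parent `mol_graph`.
#' @param severed Tibble of severed bonds (`from`, `to`), each with exactly
#'   one endpoint inside the fragment.
#' @return Tibble of cap atoms (`element` = "H", `x`, `y`, `z`,
#'   `cut_from`, `cut_to`).
#' @export
cap_with_hydrogens <- function(fragment_atoms, graph, severed) {
  at <- graph$atoms
  r_h <- 0.31  # Cordero covalent radius of hydrogen
  nk <- nrow(severed)
  ina <- severed$from %in% fragment_atoms
  inb <- severed$to %in% fragment_atoms
  if (any(ina == inb)) {
    k <- which(ina == inb)[1]
    stop(sprintf("severed bond %d-%d does not cross the fragment boundary",
                 severed$from[k], severed$to[k]), call. = FALSE)
  }
  i <- ifelse(ina, severed$from, severed$to)
  j <- ifelse(ina, severed$to, severed$from)
  frac <- (at$r_cov[i] + r_h) / (at$r_cov[i] + at$r_cov[j])
  tibble::new_tibble(list(
    element = rep("H", nk),
    x = at$x[i] + frac * (at$x[j] - at$x[i]),
    y = at$y[i] + frac * (at$y[j] - at$y[i]),
    z = at$z[i] + frac * (at$z[j] - at$z[i]),
    cut_from = i, cut_to = j
  ), nrow = nk)
}

#' Extract capped fragments from a fragmentation state
#'
#' Fragments are the connected components of the molecular graph with the
#' broken edges removed, ordered by their smallest atom index. Each fragment
#' carries a capped geometry: its own atoms plus one hydrogen cap per broken
#' bond incident to it ([cap_with_hydrogens()]).
#'
#' @param graph A `mol_graph`.
#' @param state A `frag_state`.
#' @param volumes Compute Gaussian-overlap volumes of the capped geometries
#'   (default `TRUE`; skip for speed inside tight loops).
#' @return A fragments tibble: `fragment`, `atom_ids` (list), `n_atoms`
#'   (bare), `n_caps`, `size` (atoms + caps), `geometry` (list of tibbles with
#'   `is_cap` flag), `volume` (Angstrom^3, `NA` when `volumes = FALSE`).
#' @export
extract_fragments <- function(graph, state, volumes = TRUE) {
  memb <- .fragment_membership(graph, state)
  broken <- state$edges[state$bits == 1L, ]
  ids <- sort(unique(memb))
  # order fragments by smallest atom index
  first_atom <- vapply(ids, function(f) min(which(memb == f)), 0L)
  ids <- ids[order(first_atom)]
  at <- graph$atoms
  n_frag <- length(ids)
  atom_ids <- geoms <- vector("list", n_frag)
  n_atoms <- n_caps <- integer(n_frag)
  vol <- rep(NA_real_, n_frag)
  for (k in seq_len(n_frag)) {
    fa <- which(memb == ids[k])
    inc <- broken[xor(broken$from %in% fa, broken$to %in% fa), , drop = FALSE]
    caps <- cap_with_hydrogens(fa, graph, inc)
    nc <- nrow(caps)
    nf <- length(fa)
    geom <- tibble::new_tibble(list(
      element = c(at$element[fa], caps$element),
      x = c(at$x[fa], caps$x), y = c(at$y[fa], caps$y),
      z = c(at$z[fa], caps$z),
      is_cap = rep(c(FALSE, TRUE), c(nf, nc)),
      atom_id = c(fa, rep(NA_integer_, nc))
    ), nrow = nf + nc)
    atom_ids[[k]] <- fa
    geoms[[k]] <- geom
    n_atoms[k] <- nf
    n_caps[k] <- nc
    if (volumes) vol[k] <- fragment_volume(geom)
  }
  tibble::new_tibble(list(
    fragment = seq_len(n_frag), atom_ids = atom_ids, n_atoms = n_atoms,
    n_caps = n_caps, size = n_atoms + n_caps, geometry = geoms, volume = vol
  ), nrow = n_frag)
}

#' Gaussian-overlap volume of a geometry
#'
#' Hard-sphere volumes minus pairwise Gaussian overlaps:
#' \eqn{V = \sum_i \frac{4}{3}\pi\sigma_i^3 - \sum_{i<j} V_{ij}} with
#' \eqn{V_{ij} = a_i a_j \exp(-\frac{\alpha_i\alpha_j r_{ij}^2}{\alpha_i+\alpha_j})
#' (\pi/(\alpha_i+\alpha_j))^{3/2}},
#' \eqn{\alpha_i = \pi (3 a_i / (4\pi\sigma_i^3))^{2/3}} and amplitude
#' \eqn{a_i = 2\sqrt{2}}. \eqn{\sigma_i} is the van der Waals radius.
#'
#' @param geometry Atoms tibble (`element`, `x`, `y`, `z`); caps included.
#' @param sigma Optional numeric vector of per-atom radii overriding the
#'   bundled van der Waals table.
#' @return Volume in cubic Angstrom.
#' @export
fragment_volume <- function(geometry, sigma = NULL) {
  if (is.null(sigma)) sigma <- vdw_radius(geometry$element)
  n <- length(sigma)
  v_hard <- sum(4 / 3 * pi * sigma^3)
  if (n < 2) return(v_hard)
  a <- 2 * sqrt(2)
  alpha <- pi * (3 * a / (4 * pi * sigma^3))^(2 / 3)
  xyz <- as.matrix(geometry[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(xyz))^2
  ij <- which(upper.tri(d2), arr.ind = TRUE)
  ai <- alpha[ij[, 1]]; aj <- alpha[ij[, 2]]
  vij <- a * a * exp(-ai * aj * d2[ij] / (ai + aj)) * (pi / (ai + aj))^1.5
  v_hard - sum(vij)
}

# overlap volume between two atoms given sigmas and distance
.pair_overlap <- function(sigma_i, sigma_j, r) {
  a <- 2 * sqrt(2)
  ai <- pi * (3 * a / (4 * pi * sigma_i^3))^(2 / 3)
  aj <- pi * (3 * a / (4 * pi * sigma_j^3))^(2 / 3)
  a * a * exp(-ai * aj * r^2 / (ai + aj)) * (pi / (ai + aj))^1.5
}

#' Characteristic per-element volumes
#'
#' The per-element building block of [reference_volume()]: for each atom the
#' hard-sphere volume minus the mean overlap with its bonded neighbours, then
#' averaged per element. Exposed separately so the neighbour bookkeeping (e.g.
#' the two bonded pairs entering the oxygen term of methanol) can be audited.
#'
#' @param graph A `mol_graph`.
#' @return Tibble with `element`, `n_atoms`, `mean_n_neighbours`, `v_s`
#'   (cubic Angstrom).
#' @export
element_characteristic_volumes <- function(graph) {
  at <- graph$atoms
  nb <- .neighbour_list(nrow(at), graph$bonds)
  v_atom <- numeric(nrow(at))
  n_neigh <- lengths(nb)
  for (i in seq_len(nrow(at))) {
    v_hard <- 4 / 3 * pi * at$r_vdw[i]^3
    k <- nb[[i]]
    if (!length(k)) {
      v_atom[i] <- v_hard
    } else {
      r <- sqrt((at$x[k] - at$x[i])^2 + (at$y[k] - at$y[i])^2 +
                  (at$z[k] - at$z[i])^2)
      v_atom[i] <- v_hard - mean(.pair_overlap(at$r_vdw[i], at$r_vdw[k], r))
    }
  }
  tibble::tibble(element = at$element, v = v_atom, nn = n_neigh) |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(n_atoms = dplyr::n(),
                     mean_n_neighbours = mean(.data$nn),
                     v_s = mean(.data$v), .groups = "drop")
}

#' Reference volume for a target fragment size
#'
#' Per element s, the characteristic volume is the hard-sphere volume minus
#' the mean Gaussian overlap with the atom's bonded neighbours,
#' \eqn{V_s = \frac{4}{3}\pi\sigma_s^3 - \frac{1}{\|K\|}\sum_{i \in K} V_{s,i}},
#' averaged over all atoms of that element. The reference volume scales the
#' element-weighted mean to the target size:
#' \eqn{V_{ref} = n_t \frac{1}{N_A} \sum_s N_s V_s}.
#'
#' @param graph A `mol_graph`.
#' @param n_t Target fragment size (atoms).
#' @return Reference volume in cubic Angstrom.
#' @export
reference_volume <- function(graph, n_t) {
  cv <- element_characteristic_volumes(graph)
  n_t * sum(cv$n_atoms * cv$v_s) / graph$n_atoms
}
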