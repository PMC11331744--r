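#' Fragment a molecular system recursively
#'
#' Top-level entry point. The system is analysed ([mol_graph()]) and cut by a
#' genetic-algorithm stage aiming at an intermediate target size
#' `n_stage = N / max(2, ceiling(N / (2 n_t)))` (about twice the final
#' target for large systems, half the fragment in the endgame); any resulting
#' fragment still larger than `n_t` bare atoms is fragmented again on its own
#' subgraph (caps stripped, so cap hydrogens never become cut sites). The
#' final cut set is the union over stages; fragments are re-capped on the
#' full system at the end. Oversized fragments without any allowed edge are
#' returned as-is with a warning.
#'
#' Each stage derives its own RNG seed from the master seed and its recursion
#' path, so runs are bit-reproducible for a fixed seed.
#'
#' @param atoms Atoms tibble (or a `mol_graph`).
#' @param n_t Target fragment size (atoms, caps excluded), `>= 2`.
#' @param config A [ga_config()]; `config$seed` is the master seed.
#' @param weights Penalty weights.
#' @param backend Energy backend.
#' @param max_depth Recursion safety cap (default 10).
#' @return A `molfrag_result`: `graph`, `state`, `fragments` tibble,
#'   `cuts` tibble, `stages` tibble (one row per GA stage), `score`
#'   (`frag_score` of the final state), `warnings`.
#' @examples
#' chain <- build_chain(8, kind = "alkane")
#' res <- fragment_system(chain, n_t = 10, config = ga_config(seed = 7))
#' glance(res)
#' @export
fragment_system <- function(atoms, n_t, config = ga_config(),
                            weights = default_weights(),
                            backend = ff_toy_additive(), max_depth = 10) {
  stopifnot(n_t >= 2)
  graph <- if (inherits(atoms, "mol_graph")) atoms else mol_graph(atoms)
  warn <- character()
  stages <- list()

  recurse <- function(atom_ids, depth, path) {
    n_cur <- length(atom_ids)
    if (n_cur <= n_t) return(list())
    if (depth > max_depth) {
      warn <<- c(warn, sprintf("recursion depth cap reached on a %d-atom fragment", n_cur))
      return(list())
    }
    sub <- .subgraph(graph, atom_ids)
    n_stage <- n_cur / max(2, ceiling(n_cur / (2 * n_t)))
    edges <- allowed_edges(sub$graph, n_stage)
    if (!nrow(edges)) {
      warn <<- c(warn, sprintf("fragment of %d atoms exceeds the target size but has no allowed edges", n_cur))
      return(list())
    }
    stage_cfg <- config
    stage_cfg$seed <- .stage_seed(config$seed, depth, path)
    res <- ga_evolve(sub$graph, n_stage, config = stage_cfg,
                     weights = weights, backend = backend, edges = edges,
                     forbid_uncut = TRUE)
    cut_local <- res$best$state$edges[res$best$state$bits == 1L, c("from", "to")]
    stages[[length(stages) + 1L]] <<- tibble::tibble(
      stage = length(stages) + 1L, depth = depth, n_atoms = n_cur,
      stage_target = n_stage, n_cuts = nrow(cut_local),
      n_fragments = res$best$breakdown$n_fragments,
      best_score = res$best$score
    )
    if (!nrow(cut_local)) {
      warn <<- c(warn, sprintf("optimiser kept a %d-atom fragment uncut", n_cur))
      return(list())
    }
    cuts_global <- tibble::tibble(from = sub$to_global[cut_local$from],
                                  to = sub$to_global[cut_local$to])
    frs <- extract_fragments(sub$graph, res$best$state, volumes = FALSE)
    child_cuts <- list()
    for (k in seq_len(nrow(frs))) {
      child_ids <- sub$to_global[frs$atom_ids[[k]]]
      child_cuts <- c(child_cuts, recurse(child_ids, depth + 1L,
                                          path * 131L + k))
    }
    c(list(cuts_global), child_cuts)
  }

  all_cuts <- recurse(seq_len(graph$n_atoms), 1L, 1L)
  cuts <- if (length(all_cuts)) dplyr::bind_rows(all_cuts) else
    tibble::tibble(from = integer(), to = integer())
  cuts <- dplyr::arrange(dplyr::distinct(cuts), .data$from, .data$to)

  # express the union cut set as a state over the full system's single bonds
  edge_tbl <- graph$bonds[graph$bonds$order == 1L, c("from", "to")]
  edge_tbl$edge <- seq_len(nrow(edge_tbl))
  bits <- as.integer(paste(edge_tbl$from, edge_tbl$to) %in%
                       paste(cuts$from, cuts$to))
  state <- fragmentation_state(edge_tbl, bits)
  fragments <- extract_fragments(graph, state, volumes = TRUE)
  score <- score_state(graph, state, n_t, weights = weights, backend = backend)
  for (w in warn) warning(w, call. = FALSE)
  structure(list(
    graph = graph, state = state, fragments = fragments, cuts = cuts,
    stages = if (length(stages)) dplyr::bind_rows(stages) else
      tibble::tibble(stage = integer(), depth = integer(), n_atoms = integer(),
                     stage_target = numeric(), n_cuts = integer(),
                     n_fragments = integer(), best_score = numeric()),
    score = score, n_t = n_t, seed = config$seed, warnings = warn
  ), class = "molfrag_result")
}

# induced subgraph on a set of atom ids, as a fresh mol_graph sharing
# the parent's perception (bonds/attributes are subset, not re-perceived)
.subgraph <- function(graph, atom_ids) {
  atom_ids <- sort(atom_ids)
  remap <- integer(graph$n_atoms)
  remap[atom_ids] <- seq_along(atom_ids)
  atoms <- graph$atoms[atom_ids, ]
  atoms$id <- seq_along(atom_ids)
  keep <- graph$bonds$from %in% atom_ids & graph$bonds$to %in% atom_ids
  bonds <- graph$bonds[keep, ]
  bonds$from <- remap[bonds$from]; bonds$to <- remap[bonds$to]
  conj <- list()
  for (sys in graph$conj_systems) {
    inside <- sys$atom_indices[sys$atom_indices %in% atom_ids]
    if (length(inside) < 3) next
    pc <- sys$pi_contribution[as.character(inside)]
    names(pc) <- remap[inside]
    na <- length(inside)
    mb <- sys$member_bonds[sys$member_bonds$from %in% atom_ids &
                             sys$member_bonds$to %in% atom_ids, ]
    mb$from <- remap[mb$from]; mb$to <- remap[mb$to]
    conj[[length(conj) + 1L]] <- list(
      atom_indices = remap[inside], pi_contribution = pc, n_atoms = na,
      cs = sum(pc / na) / na, member_bonds = mb, delta_max = na - 1
    )
  }
  hyper <- list()
  for (p in graph$hyper_pairs) {
    if (!all(c(p$donor$atoms, p$acceptor$atoms) %in% atom_ids)) next
    p$donor$atoms <- remap[p$donor$atoms]
    p$acceptor$atoms <- remap[p$acceptor$atoms]
    names(p$donor_per_atom) <- remap[as.integer(names(p$donor_per_atom))]
    hyper[[length(hyper) + 1L]] <- p
  }
  g <- igraph::make_empty_graph(n = nrow(atoms), directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, rbind(bonds$from, bonds$to))
  sub <- structure(
    list(atoms = atoms, bonds = bonds, conj_systems = conj,
         hyper_pairs = hyper, graph = g, n_atoms = nrow(atoms)),
    class = "mol_graph"
  )
  list(graph = sub, to_global = atom_ids)
}

# stage seed below 2^31, reproducibly derived from master seed + path
.stage_seed <- function(master, depth, path) {
  as.integer((as.double(master) * 2654435 + depth * 97003 + path * 7919) %% 2147483647)
}

#' @export
print.molfrag_result <- function(x, ...) {
  cat(sprintf("<molfrag_result> %d atoms -> %d fragment(s) (target %d), %d cut(s), score %.4f\n",
              x$graph$n_atoms, nrow(x$fragments), x$n_t, nrow(x$cuts),
              x$score$total))
  invisible(x)
}

#' Tidy a fragmentation result
#'
#' @param x A `molfrag_result`.
#' @param ... Unused.
#' @return One row per fragment: `fragment`, `n_atoms`, `n_caps`, `size`,
#'   `volume`.
#' @export
tidy.molfrag_result <- function(x, ...) {
  x$fragments[, c("fragment", "n_atoms", "n_caps", "size", "volume")]
}

#' One-row summary of a fragmentation result
#' @param x A `molfrag_result`.
#' @param ... Unused.
#' @export
glance.molfrag_result <- function(x, ...) {
  tibble::tibble(
    n_atoms = x$graph$n_atoms, n_t = x$n_t,
    n_fragments = nrow(x$fragments), n_cuts = nrow(x$cuts),
    n_stages = nrow(x$stages),
    mean_size = mean(x$fragments$size),
    max_bare_size = max(x$fragments$n_atoms),
    score = x$score$total
  )
}

#' Plot fragment sizes of a result
#' @param object A `molfrag_result`.
#' @param ... Unused.
#' @export
autoplot.molfrag_result <- function(object, ...) {
  d <- tidy.molfrag_result(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fragment), y = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$n_t, linetype = 2) +
    ggplot2::labs(x = "fragment", y = "atoms (caps included)") +
    ggplot2::theme_minimal()
}
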