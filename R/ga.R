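#' Genetic algorithm configuration
#'
#' Defaults follow the published optimiser settings where stated (iteration
#' cap 100, stagnation limit 50, blacklisting restricted to the first ten
#' iterations at a 10 kJ/mol dimer-correction threshold, two parents for
#' populations of eight or fewer and floor(0.25 * population) otherwise);
#' population size, tournament size, mutation rate and single-elite
#' preservation are this implementation's defaults, all configurable.
#'
#' @param population_size Number of individuals (default 16).
#' @param max_iterations Iteration cap (default 100).
#' @param stagnation_limit Stop after this many iterations without
#'   improvement of the best score (default 50).
#' @param blacklist_window Dimer-energy blacklisting is active during the
#'   first this-many iterations (default 10).
#' @param blacklist_threshold Blacklist an edge when its dimer correction
#'   exceeds this (kJ/mol, default 10).
#' @param tournament_size Tournament size for parent selection (default 3).
#' @param mutation_prob Per-gene mutation probability; `NULL` = 1 / n_genes.
#' @param init_flip_prob Per-gene flip probability when padding the initial
#'   population with mutated copies of the seeded guesses (default 0.1).
#' @param seed RNG seed (integer).
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 16, max_iterations = 100,
                      stagnation_limit = 50, blacklist_window = 10,
                      blacklist_threshold = 10, tournament_size = 3,
                      mutation_prob = NULL, init_flip_prob = 0.1,
                      seed = 1L) {
  structure(list(
    population_size = population_size, max_iterations = max_iterations,
    stagnation_limit = stagnation_limit, blacklist_window = blacklist_window,
    blacklist_threshold = blacklist_threshold, tournament_size = tournament_size,
    mutation_prob = mutation_prob, init_flip_prob = init_flip_prob,
    seed = as.integer(seed)
  ), class = "ga_config")
}

.n_parents <- function(population_size) {
  if (population_size <= 8) 2L else max(2L, as.integer(floor(0.25 * population_size)))
}

#' Inertia-frame reference points
#'
#' The system's bounding box in the principal-axes-of-inertia frame is split
#' into equal intervals along the axis of largest spatial extent; the
#' interval midpoints (box centre in the other two axes) are returned in the
#' original frame. As a set they are invariant under rigid motion and
#' reflection because the inertia frame itself is.
#'
#' @param atoms Attributed atoms tibble (needs `mass`).
#' @param n_points Number of intervals/points (e.g. `ceiling(N_A / n_t)`).
#' @return `n_points` x 3 matrix of reference points.
#' @export
reference_points <- function(atoms, n_points) {
  stopifnot(nrow(atoms) >= 2, n_points >= 1)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  m <- atoms$mass
  com <- colSums(xyz * m) / sum(m)
  rel <- sweep(xyz, 2, com)
  inertia <- diag(sum(m * rowSums(rel^2)), 3) -
    t(rel * m) %*% rel
  axes <- eigen(inertia, symmetric = TRUE)$vectors
  proj <- rel %*% axes
  extent <- apply(proj, 2, function(v) diff(range(v)))
  main <- which.max(extent)  # largest spatial extent, robust to degenerate inertia
  lo <- apply(proj, 2, min); hi <- apply(proj, 2, max)
  centre <- (lo + hi) / 2
  step <- (hi[main] - lo[main]) / n_points
  mids <- lo[main] + (seq_len(n_points) - 0.5) * step
  pts <- matrix(rep(centre, each = n_points), nrow = n_points)
  pts[, main] <- mids
  pts %*% t(axes) + matrix(com, nrow = n_points, ncol = 3, byrow = TRUE)
}

#' Primitive monomers of the solution space
#'
#' Cutting every allowed edge yields the minimal building blocks of initial
#' guesses. Two monomers are adjacent when an allowed edge joins them.
#'
#' @param graph A `mol_graph`.
#' @param edges Allowed-edge tibble.
#' @return List with `membership` (atom -> monomer id), `atoms` (list of atom
#'   id vectors), `centroids` (matrix), `adjacency` (list of neighbour ids
#'   per monomer), `edge_monomers` (per allowed edge, the two monomer ids).
#' @export
primitive_monomers <- function(graph, edges) {
  g2 <- graph$graph
  if (nrow(edges)) {
    eids <- igraph::get_edge_ids(g2, rbind(edges$from, edges$to))
    g2 <- igraph::delete_edges(g2, eids)
  }
  memb <- igraph::components(g2)$membership
  ids <- sort(unique(memb))
  atoms <- lapply(ids, function(i) which(memb == i))
  xyz <- as.matrix(graph$atoms[, c("x", "y", "z")])
  centroids <- t(vapply(atoms, function(a) colMeans(xyz[a, , drop = FALSE]),
                        numeric(3)))
  adj <- lapply(ids, function(i) integer())
  em <- matrix(0L, nrow = nrow(edges), ncol = 2)
  for (k in seq_len(nrow(edges))) {
    a <- memb[edges$from[k]]; b <- memb[edges$to[k]]
    em[k, ] <- c(a, b)
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  list(membership = memb, atoms = atoms, centroids = centroids,
       adjacency = adj, edge_monomers = em)
}

#' Initial guess from a reference point
#'
#' Starting at the unvisited primitive monomer whose centroid is nearest the
#' reference point (ties broken by lowest atom index), fragments are grown
#' breadth-first over monomer adjacency, each stopping once it reaches 90% of
#' the target size; the procedure repeats until every monomer is assigned.
#' The returned state breaks exactly the allowed edges joining different
#' grown fragments.
#'
#' @param graph A `mol_graph`.
#' @param edges Allowed-edge tibble.
#' @param n_t Target fragment size (atoms).
#' @param ref_point 3-vector.
#' @param monomers Optional precomputed [primitive_monomers()].
#' @return A `frag_state`.
#' @export
initial_guess <- function(graph, edges, n_t, ref_point, monomers = NULL) {
  if (is.null(monomers)) monomers <- primitive_monomers(graph, edges)
  n_mon <- length(monomers$atoms)
  sizes <- lengths(monomers$atoms)
  min_atom <- vapply(monomers$atoms, min, 0L)
  d_ref <- sqrt(colSums((t(monomers$centroids) - ref_point)^2))
  visited <- logical(n_mon)
  frag_of <- integer(n_mon)
  frag_id <- 0L
  while (any(!visited)) {
    frag_id <- frag_id + 1L
    cand <- which(!visited)
    ref_mon <- cand[order(d_ref[cand], min_atom[cand])][1]
    # breadth-first growth to >= 90% of n_t
    queue <- ref_mon
    members <- ref_mon
    visited[ref_mon] <- TRUE
    size <- sizes[ref_mon]
    while (length(queue) && size < 0.9 * n_t) {
      v <- queue[1]; queue <- queue[-1]
      for (w in sort(monomers$adjacency[[v]])) {
        if (!visited[w]) {
          visited[w] <- TRUE
          members <- c(members, w)
          queue <- c(queue, w)
          size <- size + sizes[w]
          if (size >= 0.9 * n_t) break
        }
      }
    }
    frag_of[members] <- frag_id
  }
  bits <- as.integer(frag_of[monomers$edge_monomers[, 1]] !=
                       frag_of[monomers$edge_monomers[, 2]])
  fragmentation_state(edges, bits)
}

#' Minimise the fragmentation score with a genetic algorithm
#'
#' Binary-chromosome GA over the allowed edges: tournament selection,
#' single-point crossover, mutation by replacement (offspring only), single
#' elite. The population is seeded with one inertia-guided initial guess per
#' reference point, padded with mutated copies. During the first
#' `blacklist_window` iterations, every broken edge of every evaluated
#' individual is screened by its dimer energy correction and permanently
#' forced to 0 when the correction exceeds the threshold. With a fixed seed
#' the run is bit-reproducible; the best-so-far score is non-increasing.
#'
#' @param graph A `mol_graph`.
#' @param n_t Target fragment size (atoms).
#' @param config A [ga_config()].
#' @param weights Penalty weights.
#' @param backend Energy backend (scoring and blacklisting).
#' @param edges Optional precomputed allowed edges.
#' @param forbid_uncut Treat the uncut (all-zero) state as infeasible
#'   (infinite fitness). Used by the recursive driver, whose stages must
#'   partition an oversized fragment.
#' @return A `ga_result`: `best` (list with `state`, `score`,
#'   `breakdown`), `trace` (tibble iteration/best score), `blacklist`
#'   (edge positions), `n_evaluations`.
#' @export
ga_evolve <- function(graph, n_t, config = ga_config(),
                      weights = default_weights(),
                      backend = ff_toy_additive(), edges = NULL,
                      forbid_uncut = FALSE) {
  if (is.null(edges)) edges <- allowed_edges(graph, n_t)
  n_genes <- nrow(edges)
  v_ref <- reference_volume(graph, n_t)
  e_tot <- ff_energy(.bare_geometry(graph), backend)
  score_cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score_of <- function(bits) {
    key <- paste(bits, collapse = "")
    hit <- score_cache[[key]]
    if (!is.null(hit)) return(hit)
    br <- score_state(graph, fragmentation_state(edges, bits), n_t,
                      weights = weights, backend = backend, v_ref = v_ref,
                      e_tot = e_tot)
    n_eval <<- n_eval + 1L
    score_cache[[key]] <- br
    br
  }

  if (n_genes == 0L) {
    state <- fragmentation_state(edges)
    br <- score_state(graph, state, n_t, weights = weights, backend = backend)
    return(structure(list(
      best = list(state = state, score = br$total, breakdown = br),
      trace = tibble::tibble(iteration = 0L, best_score = br$total),
      blacklist = integer(), n_evaluations = 1L, edges = edges
    ), class = "ga_result"))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  mut_p <- if (is.null(config$mutation_prob)) 1 / n_genes else config$mutation_prob
  monomers <- primitive_monomers(graph, edges)
  n_pts <- max(1L, ceiling(graph$n_atoms / n_t))
  refs <- reference_points(graph$atoms, n_pts)
  seeds_states <- lapply(seq_len(nrow(refs)), function(r)
    initial_guess(graph, edges, n_t, refs[r, ], monomers))
  pop <- lapply(seeds_states, `[[`, "bits")
  pop <- unique(pop)
  n_seeds <- length(pop)
  while (length(pop) < config$population_size) {
    base <- pop[[1 + (length(pop) %% n_seeds)]]
    flip <- stats::runif(n_genes) < config$init_flip_prob
    base[flip] <- 1L - base[flip]
    pop[[length(pop) + 1L]] <- base
  }
  pop <- pop[seq_len(config$population_size)]

  blacklist <- logical(n_genes)
  dimer_tested <- new.env(parent = emptyenv())
  dimer_cache <- new.env(parent = emptyenv())
  apply_blacklist <- function(p) lapply(p, function(b) { b[blacklist] <- 0L; b })

  screen_edges <- function(p) {
    for (b in p) {
      for (e in which(b == 1L & !blacklist)) {
        st <- fragmentation_state(edges, b)
        broken <- edges$edge[b == 1L]
        key <- paste(e, paste(broken, collapse = ","))
        if (!is.null(dimer_tested[[key]])) next
        dimer_tested[[key]] <- TRUE
        de <- dimer_energy_correction(graph, st, e, backend, cache = dimer_cache)
        if (de > config$blacklist_threshold) blacklist[e] <<- TRUE
      }
    }
  }

  pop <- apply_blacklist(pop)
  best_bits <- NULL; best_score <- Inf
  trace <- numeric(0)
  stagnation <- 0L
  for (iter in seq_len(config$max_iterations)) {
    if (iter <= config$blacklist_window) {
      screen_edges(pop)
      pop <- apply_blacklist(pop)
      if (!is.null(best_bits) && any(best_bits[blacklist] == 1L)) {
        # stored best became invalid; it re-enters the race blacklist-cleaned
        best_bits[blacklist] <- 0L
        best_score <- if (forbid_uncut && sum(best_bits) == 0L) Inf else
          score_of(best_bits)$total
      }
    }
    fitness <- vapply(pop, function(b)
      if (forbid_uncut && sum(b) == 0L) Inf else score_of(b)$total, 0)
    local_best <- which.min(fitness)
    if (fitness[local_best] < best_score) {
      best_score <- fitness[local_best]
      best_bits <- pop[[local_best]]
      stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
    }
    trace <- c(trace, best_score)
    if (stagnation > config$stagnation_limit) break
    if (iter == config$max_iterations) break

    np <- .n_parents(config$population_size)
    parents <- lapply(seq_len(np), function(s) {
      contenders <- sample.int(length(pop), config$tournament_size, replace = TRUE)
      pop[[contenders[which.min(fitness[contenders])]]]
    })
    n_children <- config$population_size - 1L
    children <- vector("list", n_children)
    for (c in seq_len(n_children)) {
      pr <- sample.int(np, 2, replace = np < 2)
      p1 <- parents[[pr[1]]]; p2 <- parents[[pr[2]]]
      cut <- sample.int(n_genes, 1)
      child <- c(p1[seq_len(cut)], if (cut < n_genes) p2[seq(cut + 1, n_genes)])
      flip <- stats::runif(n_genes) < mut_p
      child[flip] <- sample(c(0L, 1L), sum(flip), replace = TRUE)
      child[blacklist] <- 0L
      children[[c]] <- child
    }
    pop <- c(list(best_bits), children)
  }

  best_state <- fragmentation_state(edges, best_bits)
  structure(list(
    best = list(state = best_state, score = best_score,
                breakdown = score_of(best_bits)),
    trace = tibble::tibble(iteration = seq_along(trace), best_score = trace),
    blacklist = which(blacklist),
    n_evaluations = n_eval,
    edges = edges
  ), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> best score %.6f after %d iteration(s), %d cut(s), %d blacklisted edge(s)\n",
              x$best$score, nrow(x$trace), sum(x$best$state$bits),
              length(x$blacklist)))
  invisible(x)
}

#' Plot a GA convergence trace
#' @param object A `ga_result`.
#' @param ... Unused.
#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_score)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best score") +
    ggplot2::theme_minimal()
}
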