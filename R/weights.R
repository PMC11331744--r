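#' Initial weight grid for Bayesian tuning
#'
#' The 16 starting weight vectors of the published grid search (steps of 0.1,
#' with the energy and volume weights floored at 0.2). Every row sums to 1.
#'
#' @return A 16 x 6 tibble (`pe`, `conj`, `hyper`, `vol`, `comp`, `vrange`).
#' @export
initial_weight_grid <- function() {
  m <- matrix(c(
    0.2, 0.1, 0.1, 0.2, 0.1, 0.3,
    0.2, 0.1, 0.1, 0.2, 0.2, 0.2,
    0.2, 0.1, 0.1, 0.3, 0.1, 0.2,
    0.2, 0.1, 0.1, 0.4, 0.1, 0.1,
    0.2, 0.1, 0.2, 0.2, 0.1, 0.2,
    0.2, 0.1, 0.2, 0.3, 0.1, 0.1,
    0.2, 0.1, 0.3, 0.2, 0.1, 0.1,
    0.2, 0.2, 0.1, 0.2, 0.1, 0.2,
    0.2, 0.2, 0.1, 0.3, 0.1, 0.1,
    0.2, 0.2, 0.2, 0.2, 0.1, 0.1,
    0.2, 0.3, 0.1, 0.2, 0.1, 0.1,
    0.3, 0.1, 0.1, 0.2, 0.1, 0.2,
    0.3, 0.1, 0.1, 0.3, 0.1, 0.1,
    0.3, 0.1, 0.2, 0.2, 0.1, 0.1,
    0.3, 0.2, 0.1, 0.2, 0.1, 0.1,
    0.4, 0.1, 0.1, 0.2, 0.1, 0.1
  ), ncol = 6, byrow = TRUE)
  colnames(m) <- c("pe", "conj", "hyper", "vol", "comp", "vrange")
  tibble::as_tibble(m)
}

# energy-error normaliser of the tuning objective: logistic in |dE| with
# 5%/95% boundary points at 1 and 4 kJ/mol -> midpoint 2.5, steepness 2 ln(19)/3
.s_energy <- function(delta_e) {
  stats::plogis((2 * log(19) / 3) * (abs(delta_e) - 2.5))
}

#' Tuning objective over a dataset
#'
#' \eqn{f = \alpha \frac{1}{n}\sum_i p_{vol}^i +
#'      (1-\alpha)\frac{1}{n}\sum_i S(\Delta E_i)}:
#' each system is fragmented with the candidate weights, its volume penalty
#' is taken from the resulting score breakdown and its fragmentation energy
#' error from a two-body MBE under the configured (cheap) energy model. S is
#' a logistic in |dE| with boundary points 1 and 4 kJ/mol. Systems whose
#' fragmentation fails are skipped with a warning and n adjusted.
#'
#' @param weights Named weight vector (simplex).
#' @param dataset List of atoms tibbles (or `mol_graph`s).
#' @param n_t Target fragment size.
#' @param backend Inner energy model (an [ff_backend()]).
#' @param alpha Volume/energy balance in `[0, 1]` (default 0.5, equal
#'   weighting).
#' @param config GA configuration used for the inner fragmentations.
#' @return Objective value in `[0, 1]`.
#' @export
score_objective <- function(weights, dataset, n_t = 50,
                            backend = ff_toy_pairwise(), alpha = 0.5,
                            config = ga_config()) {
  stopifnot(length(dataset) >= 1, alpha >= 0, alpha <= 1)
  p_vol <- de <- numeric(0)
  for (sys in dataset) {
    res <- tryCatch(
      suppressWarnings(fragment_system(sys, n_t = n_t, config = config,
                                       weights = weights, backend = backend)),
      error = function(e) NULL)
    if (is.null(res)) {
      warning("fragmentation failed on a dataset system; skipped", call. = FALSE)
      next
    }
    p_vol <- c(p_vol, unname(res$score$penalties["vol"]))
    mbe <- mbe_energy(res$graph, res$state, backend, level = 2)
    de <- c(de, mbe$delta_e)
  }
  if (!length(p_vol)) stop("no dataset system could be fragmented", call. = FALSE)
  alpha * mean(p_vol) + (1 - alpha) * mean(.s_energy(de))
}

#' Bayesian optimisation of the penalty weights
#'
#' Gaussian-process surrogate (radial-basis-function kernel) with
#' expected-improvement acquisition, maximised over the probability simplex
#' by candidate sampling (Dirichlet draws plus local perturbations of the
#' incumbent, renormalised). Starts from the evaluated initial grid and stops
#' when the minimum objective has not changed for `stagnation_limit`
#' iterations or at `max_iterations`. The GP posterior is computed directly
#' (Cholesky solve); kernel length scale and noise variance both default
#' to 1.
#'
#' @param objective Function `weights (named numeric) -> f`.
#' @param initial Tibble/matrix of starting weight vectors (default the
#'   published 16-row grid).
#' @param seed RNG seed.
#' @param max_iterations Iteration cap (default 300).
#' @param stagnation_limit Stop after this many non-improving iterations
#'   (default 200, the published stopping rule).
#' @param n_candidates Dirichlet candidates per iteration (default 4096).
#' @param length_scale RBF kernel length scale (default 1).
#' @param noise Observation noise variance (default 1; use a small value for
#'   deterministic objectives).
#' @return A `weights_opt` object: `best_weights`, `best_f`, `trace` tibble
#'   (iteration, f, best so far), `samples` (matrix of all evaluated points).
#' @export
tune_weights <- function(objective, initial = initial_weight_grid(),
                         seed = 1L, max_iterations = 300,
                         stagnation_limit = 200, n_candidates = 4096,
                         length_scale = 1, noise = 1) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  x <- as.matrix(initial)
  stopifnot(all(abs(rowSums(x) - 1) < 1e-9), all(x >= 0))
  dims <- colnames(x)
  f_of <- function(row) {
    w <- as.numeric(row); names(w) <- dims
    objective(w)
  }
  y <- apply(x, 1, f_of)
  trace <- tibble::tibble(iteration = 0L, f = NA_real_, best_f = min(y))

  stagnation <- 0L
  for (iter in seq_len(max_iterations)) {
    cand <- .simplex_candidates(n_candidates, ncol(x),
                                incumbent = x[which.min(y), ])
    ei <- .expected_improvement(x, y, cand, length_scale, noise)
    xn <- cand[which.max(ei), ]
    fn <- f_of(xn)
    x <- rbind(x, xn); y <- c(y, fn)
    improved <- fn < min(y[-length(y)]) - 1e-12
    stagnation <- if (improved) 0L else stagnation + 1L
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      iteration = iter, f = fn, best_f = min(y)))
    if (stagnation >= stagnation_limit) break
  }
  best <- which.min(y)
  bw <- as.numeric(x[best, ]); names(bw) <- dims
  structure(list(best_weights = bw, best_f = y[best], trace = trace,
                 samples = x, values = y),
            class = "weights_opt")
}

# candidate pool on the simplex: global Dirichlet(1) draws plus
# concentrated Dirichlet perturbations around the incumbent
.simplex_candidates <- function(n, d, incumbent = NULL) {
  n_glob <- ceiling(n / 2)
  g <- matrix(stats::rexp(n_glob * d), ncol = d)
  g <- g / rowSums(g)
  if (is.null(incumbent)) return(g)
  n_loc <- n - n_glob
  conc <- 50
  l <- matrix(stats::rgamma(n_loc * d, shape = pmax(incumbent, 1e-3) * conc + 0.5),
              ncol = d, byrow = TRUE)
  l <- l / rowSums(l)
  rbind(g, l)
}

# GP posterior (RBF kernel) + closed-form expected improvement (minimisation)
.expected_improvement <- function(x, y, cand, length_scale, noise) {
  k_rbf <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    exp(-pmax(d2, 0) / (2 * length_scale^2))
  }
  mu_y <- mean(y)
  kxx <- k_rbf(x, x) + diag(noise + 1e-10, nrow(x))
  ch <- chol(kxx)
  alpha <- backsolve(ch, forwardsolve(t(ch), y - mu_y))
  kxs <- k_rbf(x, cand)
  mu <- mu_y + t(kxs) %*% alpha
  v <- forwardsolve(t(ch), kxs)
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  f_min <- min(y)
  z <- (f_min - mu) / s
  as.numeric((f_min - mu) * stats::pnorm(z) + s * stats::dnorm(z))
}

#' @export
print.weights_opt <- function(x, ...) {
  cat(sprintf("<weights_opt> best f = %.6f after %d evaluation(s)\n",
              x$best_f, length(x$values)))
  print(round(x$best_weights, 6))
  invisible(x)
}

#' Tidy a weight-tuning trace
#' @param x A `weights_opt` object.
#' @param ... Unused.
#' @export
tidy.weights_opt <- function(x, ...) x$trace

#' @export
glance.weights_opt <- function(x, ...) {
  tibble::tibble(best_f = x$best_f, n_evaluations = length(x$values))
}

#' Plot a weight-tuning trace
#' @param object A `weights_opt` object.
#' @param ... Unused.
#' @export
autoplot.weights_opt <- function(object, ...) {
  d <- object$trace[!is.na(object$trace$f), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$best_f)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best objective f") +
    ggplot2::theme_minimal()
}
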