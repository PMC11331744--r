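# perception is deterministic, so fixture graphs are cached across tests
.graph_cache <- new.env(parent = emptyenv())

cached_graph <- function(name) {
  if (is.null(.graph_cache[[name]])) {
    .graph_cache[[name]] <- mol_graph(build_named_molecule(name))
  }
  .graph_cache[[name]]
}

# fragmentation state cutting the given from-to bonds (any single bonds)
make_state <- function(graph, cuts) {
  ed <- graph$bonds[graph$bonds$order == 1L, c("from", "to")]
  ed$edge <- seq_len(nrow(ed))
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  want <- paste(pmin(cuts$from, cuts$to), pmax(cuts$from, cuts$to))
  stopifnot(all(want %in% key))
  fragmentation_state(ed, as.integer(key %in% want))
}

# rigid motion: rotate about z then x, translate
rigid_motion <- function(atoms, theta = 0.7, phi = -0.4,
                         shift = c(5, -3, 2)) {
  rz <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0,
                 0, 0, 1), 3)
  rx <- matrix(c(1, 0, 0, 0, cos(phi), sin(phi),
                 0, -sin(phi), cos(phi)), 3)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rz %*% rx)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# independent closed-form evaluation of the Gaussian-overlap pair volume
# (second implementation, kept deliberately separate from the package's)
oracle_pair_overlap <- function(sig1, sig2, r) {
  amp <- 2 * sqrt(2)
  al <- function(s) pi * (3 * amp / (4 * pi * s^3))^(2 / 3)
  a1 <- al(sig1); a2 <- al(sig2)
  amp^2 * exp(-a1 * a2 * r^2 / (a1 + a2)) * (pi / (a1 + a2))^(3 / 2)
}
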