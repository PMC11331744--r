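#' Deterministic fixture molecules
#'
#' Idealised geometries for the worked-example molecules used throughout the
#' documentation and tests. Bond lengths are chosen so that the distance-based
#' perception recovers the intended topology and orders unambiguously; these
#' are synthetic constructions, not experimental structures. Coordinates are
#' bit-identical across calls.
#'
#' Registry: `methane`, `ethane`, `ethene`, `n-butane`, `1,3-butadiene`,
#' `propene`, `methanol`, `pyrrole`, `3-chloroprop-1-ene` (atoms 1,2 = C=C,
#' 3 = CH2, 4 = Cl, matching the numbering used in the hyperconjugation
#' worked example), `stearic-like-chain` (an 18-carbon fatty-acid-like chain
#' with a carboxyl head).
#'
#' @param name Registry name.
#' @return An atoms tibble (`element`, `x`, `y`, `z`, `formal_charge`).
#' @examples
#' mol_graph(build_named_molecule("pyrrole"))
#' @export
build_named_molecule <- function(name) {
  registry <- list(
    "methane" = .fix_methane,
    "ethane" = .fix_ethane,
    "ethene" = .fix_ethene,
    "n-butane" = function() build_chain(4, kind = "alkane", seed = NULL),
    "1,3-butadiene" = .fix_butadiene,
    "propene" = function() .fix_propene_skeleton(chloro = FALSE),
    "methanol" = .fix_methanol,
    "pyrrole" = .fix_pyrrole,
    "3-chloroprop-1-ene" = function() .fix_propene_skeleton(chloro = TRUE),
    "stearic-like-chain" = .fix_stearic
  )
  if (!name %in% names(registry)) {
    stop("unknown molecule '", name, "'; registry: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  registry[[name]]()
}

.atoms_tbl <- function(element, xyz) {
  tibble::tibble(element = element,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 formal_charge = 0L)
}

.fix_methane <- function() {
  r <- 1.09 / sqrt(3)
  .atoms_tbl(c("C", "H", "H", "H", "H"), rbind(
    c(0, 0, 0), c(r, r, r), c(r, -r, -r), c(-r, r, -r), c(-r, -r, r)))
}

.fix_ethane <- function() {
  # staggered, C-C 1.54, C-H 1.09
  c1 <- c(0, 0, 0); c2 <- c(1.54, 0, 0)
  h <- function(c0, sgn, phase) {
    ang <- phase + c(0, 2, 4) * pi / 3
    t(vapply(ang, function(a)
      c0 + c(sgn * 1.09 * cos(1.23096), 1.09 * sin(1.23096) * cos(a),
             1.09 * sin(1.23096) * sin(a)), numeric(3)))
  }
  .atoms_tbl(c("C", "C", rep("H", 6)),
             rbind(c1, c2, h(c1, -1, 0), h(c2, 1, pi / 3)))
}

.fix_ethene <- function() {
  .atoms_tbl(c("C", "C", "H", "H", "H", "H"), rbind(
    c(0, 0, 0), c(1.33, 0, 0),
    c(-0.545, 0.944, 0), c(-0.545, -0.944, 0),
    c(1.875, 0.944, 0), c(1.875, -0.944, 0)))
}

.fix_butadiene <- function() {
  # s-trans planar: C1=C2 1.34, C2-C3 1.47, C3=C4 1.34
  c1 <- c(0, 0, 0)
  c2 <- c(1.34, 0, 0)
  c3 <- c2 + 1.47 * c(cos(pi / 3), sin(pi / 3), 0)
  c4 <- c3 + 1.34 * c(1, 0, 0)
  hpos <- rbind(
    c1 + 1.09 * c(-cos(pi / 3), sin(pi / 3), 0),
    c1 + 1.09 * c(-cos(pi / 3), -sin(pi / 3), 0),
    c2 + 1.09 * c(cos(pi / 3), -sin(pi / 3), 0),
    c3 + 1.09 * c(-cos(pi / 3), sin(pi / 3), 0),
    c4 + 1.09 * c(cos(pi / 3), 0.0, 0) + c(0, 1.09 * sin(pi / 3), 0) * 0 +
      c(0, 0, 0),
    c4 + 1.09 * c(cos(pi / 3), -sin(pi / 3), 0)
  )
  hpos[5, ] <- c4 + 1.09 * c(cos(pi / 3), sin(pi / 3), 0)
  .atoms_tbl(c(rep("C", 4), rep("H", 6)), rbind(c1, c2, c3, c4, hpos))
}

.fix_methanol <- function() {
  c0 <- c(0, 0, 0)
  o <- c(1.43, 0, 0)
  ho <- o + 0.96 * c(cos(1.823), sin(1.823), 0)  # ~104.5 deg C-O-H
  hc <- rbind(
    c0 + 1.09 * c(-1 / sqrt(3), sqrt(2 / 3), 0),
    c0 + 1.09 * c(-1 / sqrt(3), -sqrt(1 / 6), sqrt(0.5)),
    c0 + 1.09 * c(-1 / sqrt(3), -sqrt(1 / 6), -sqrt(0.5)))
  .atoms_tbl(c("C", "O", "H", "H", "H", "H"), rbind(c0, o, ho, hc))
}

.fix_pyrrole <- function() {
  # planar ring N1 C2 C3 C4 C5 with perceived orders
  # N-C single (1.42), C2=C3 and C4=C5 double (1.35), C3-C4 single (1.45)
  npos <- c(0, 2.1144, 0)
  c2 <- c(1.15, 1.2814, 0); c5 <- c(-1.15, 1.2814, 0)
  c3 <- c(0.725, 0, 0); c4 <- c(-0.725, 0, 0)
  centroid <- c(0, (2.1144 + 2 * 1.2814) / 5, 0)
  outward <- function(p, r) {
    d <- p - centroid; d <- d / sqrt(sum(d^2)); p + r * d
  }
  .atoms_tbl(
    c("N", "C", "C", "C", "C", "H", "H", "H", "H", "H"),
    rbind(npos, c2, c3, c4, c5,
          outward(npos, 1.01), outward(c2, 1.08), outward(c3, 1.08),
          outward(c4, 1.08), outward(c5, 1.08)))
}

# propene (chloro = FALSE) and 3-chloroprop-1-ene (chloro = TRUE);
# atoms 1,2 = C=C, 3 = CH2 carbon, 4 = Cl (or H), then the remaining H's
.fix_propene_skeleton <- function(chloro) {
  c1 <- c(0, 0, 0); c2 <- c(1.34, 0, 0)
  c3 <- c2 + 1.50 * c(cos(pi / 3), sin(pi / 3), 0)
  x4 <- if (chloro) c3 + 1.77 * c(1, 0, 0) else c3 + 1.09 * c(1, 0, 0)
  h1a <- c1 + 1.09 * c(-cos(pi / 3), sin(pi / 3), 0)
  h1b <- c1 + 1.09 * c(-cos(pi / 3), -sin(pi / 3), 0)
  h2 <- c2 + 1.09 * c(cos(pi / 3), -sin(pi / 3), 0)
  # two out-of-plane substituents on C3 (tetrahedral)
  h3a <- c3 + 1.09 * c(-0.289, 0.5, 0.816)
  h3b <- c3 + 1.09 * c(-0.289, 0.5, -0.816)
  .atoms_tbl(
    c("C", "C", "C", if (chloro) "Cl" else "H", "H", "H", "H", "H", "H"),
    rbind(c1, c2, c3, x4, h1a, h1b, h2, h3a, h3b))
}

.fix_stearic <- function() {
  chain <- build_chain(18, kind = "alkane", seed = NULL)
  # replace one terminal methyl hydrogen pair with a carboxyl head:
  # drop the three H on C1, attach =O and -OH
  g <- perceive_bonds(chain)
  h_on_c1 <- g$to[g$from == 1 & chain$element[g$to] == "H"]
  chain <- chain[setdiff(seq_len(nrow(chain)), h_on_c1), ]
  c1 <- unlist(chain[1, c("x", "y", "z")])
  o1 <- c1 + 1.21 * c(-0.5, 0.866, 0)
  o2 <- c1 + 1.40 * c(-0.5, -0.866, 0)
  h2 <- o2 + 0.96 * c(-1, 0, 0)
  dplyr::bind_rows(
    chain,
    .atoms_tbl(c("O", "O", "H"), rbind(o1, o2, h2)))
}

#' Synthetic peptide-like and alkane chains
#'
#' Linear chains emulating small single-chain protein systems (extended
#' glycine/alanine backbone with amide C=O, so the amide C-N, Calpha-N and
#' Calpha-C bond classes are all present) or plain alkanes. Geometries are
#' idealised zig-zags; a seeded uniform jitter of at most 0.02 Angstrom is
#' added so different seeds give distinct but topologically identical
#' structures. The same seed always reproduces the same coordinates.
#'
#' An alkane of `n` carbons has `3n + 2` atoms; a glycine-only peptide of
#' `n` residues has `7n + 3` atoms (NH2 N-terminus, COOH C-terminus), and
#' every alanine adds 3.
#'
#' @param n_residues Number of residues (peptide) or carbons (alkane).
#' @param kind "alkane" or "peptide".
#' @param seed Integer seed for the coordinate jitter; `NULL` = no jitter.
#' @param alanine_at Integer vector of residue positions carrying a methyl
#'   side chain (peptide only).
#' @return An atoms tibble.
#' @examples
#' nrow(build_chain(10, kind = "alkane"))          # 32
#' nrow(build_chain(24, kind = "peptide", alanine_at = 12))  # 174
#' @export
build_chain <- function(n_residues, kind = c("alkane", "peptide"), seed = NULL,
                        alanine_at = integer()) {
  kind <- match.arg(kind)
  stopifnot(n_residues >= 1)
  atoms <- if (kind == "alkane") .chain_alkane(n_residues) else
    .chain_peptide(n_residues, alanine_at)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(as.integer(seed))
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::runif(n, -0.02, 0.02)
    atoms$y <- atoms$y + stats::runif(n, -0.02, 0.02)
    atoms$z <- atoms$z + stats::runif(n, -0.02, 0.02)
  }
  atoms
}

.chain_alkane <- function(n) {
  # zig-zag backbone: C-C 1.54, tetrahedral-ish; atoms ordered C_i then its H's
  dx <- 1.54 * sin(55.75 * pi / 180)
  dy <- 1.54 * cos(55.75 * pi / 180)
  elements <- character(); coords <- NULL
  for (i in seq_len(n)) {
    ci <- c((i - 1) * dx, if (i %% 2 == 0) dy else 0, 0)
    elements <- c(elements, "C"); coords <- rbind(coords, ci)
    up <- if (i %% 2 == 0) -1 else 1  # H fan opens away from the zig-zag
    coords <- rbind(coords,
                    ci + 1.09 * c(0, up * 0.5, 0.866),
                    ci + 1.09 * c(0, up * 0.5, -0.866))
    elements <- c(elements, "H", "H")
    if (i == 1 || i == n) {
      sgn <- if (i == 1) -1 else 1
      coords <- rbind(coords, ci + 1.09 * c(sgn * 0.94, up * -0.34, 0))
      elements <- c(elements, "H")
    }
  }
  .atoms_tbl(elements, coords)
}

.chain_peptide <- function(n, alanine_at = integer()) {
  up <- c(cos(pi / 6), sin(pi / 6), 0)
  dn <- c(cos(pi / 6), -sin(pi / 6), 0)
  elements <- character(); coords <- NULL; going_up <- TRUE
  add <- function(el, p) {
    elements <<- c(elements, el)
    coords <<- rbind(coords, p)
  }
  step <- function(from, len) {
    d <- if (going_up) up else dn
    going_up <<- !going_up
    from + len * d
  }
  # substituent opposite the two in-plane bond directions at p
  opp <- function(p, d1, d2, len) {
    u <- -(d1 / sqrt(sum(d1^2)) + d2 / sqrt(sum(d2^2)))
    p + len * u / sqrt(sum(u^2))
  }
  npos <- c(0, 0, 0)
  add("N", npos)
  prev_cprime <- NULL
  for (r in seq_len(n)) {
    if (r == 1) {
      add("H", npos + 1.01 * c(-cos(pi / 3), sin(pi / 3), 0))
      add("H", npos + 1.01 * c(-cos(pi / 3), -sin(pi / 3), 0))
    }
    ca <- step(npos, 1.47)
    add("C", ca)
    cp <- step(ca, 1.53)
    # side positions on Calpha (out of plane)
    ha1 <- ca + 1.09 * .oop_dir(npos - ca, cp - ca, +1)
    if (r %in% alanine_at) {
      cb <- ca + 1.53 * .oop_dir(npos - ca, cp - ca, -1)
      add("H", ha1); add("C", cb)
      for (d in .tetra_fan(ca - cb)) add("H", cb + 1.09 * d)
    } else {
      add("H", ha1)
      add("H", ca + 1.09 * .oop_dir(npos - ca, cp - ca, -1))
    }
    add("C", cp)
    if (r < n) {
      nn <- step(cp, 1.40)
      add("O", opp(cp, ca - cp, nn - cp, 1.23))
      add("N", nn)
      hn <- opp(nn, cp - nn, step(nn, 1) - nn, 1.01); going_up <- !going_up  # undo probe step
      add("H", hn)
      npos <- nn
      prev_cprime <- cp
    } else {
      o2 <- step(cp, 1.40)
      add("O", opp(cp, ca - cp, o2 - cp, 1.23))
      add("O", o2)
      add("H", o2 + 0.96 * c(1, 0, 0))
    }
  }
  .atoms_tbl(elements, coords)
}

# three unit vectors at ~109.5 deg from `axis`, mutually symmetric
# (methyl hydrogen fan given the direction towards the bonded heavy atom)
.tetra_fan <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  ct <- cos(109.47 * pi / 180); st <- sin(109.47 * pi / 180)
  lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi)
    ct * a + st * (cos(phi) * e1 + sin(phi) * e2))
}

# unit vector out of the plane spanned by d1, d2, tilted tetrahedrally
.oop_dir <- function(d1, d2, sgn) {
  u1 <- d1 / sqrt(sum(d1^2)); u2 <- d2 / sqrt(sum(d2^2))
  bis <- -(u1 + u2); bis <- bis / sqrt(sum(bis^2))
  nrm <- c(u1[2] * u2[3] - u1[3] * u2[2],
           u1[3] * u2[1] - u1[1] * u2[3],
           u1[1] * u2[2] - u1[2] * u2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  v <- bis * cos(0.955) + sgn * nrm * sin(0.955)  # ~54.7 deg tilt
  v / sqrt(sum(v^2))
}
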