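test_that("allowed edges: single bonds, bridges, and the 60% size rule", {
  # ethene's C=C is order 2 and its C-H cuts strand single atoms
  expect_equal(nrow(allowed_edges(cached_graph("ethene"), 2)), 0)

  # terminal C-H always excluded at a 20-atom target
  g <- mol_graph(build_chain(20, kind = "alkane"))
  ed <- allowed_edges(g, 20)
  elems <- cached_elems <- g$atoms$element
  expect_true(all(elems[ed$from] == "C" & elems[ed$to] == "C"))

  # exhaustive check: a cut is allowed iff both sides have >= ceil(0.6*20)
  min_side <- ceiling(0.6 * 20)
  key_allowed <- paste(ed$from, ed$to)
  singles <- g$bonds[g$bonds$order == 1L, ]
  for (k in seq_len(nrow(singles))) {
    eid <- igraph::get_edge_ids(g$graph, c(singles$from[k], singles$to[k]))
    memb <- igraph::components(igraph::delete_edges(g$graph, eid))$membership
    both_big <- min(table(memb)) >= min_side
    expect_equal(paste(singles$from[k], singles$to[k]) %in% key_allowed,
                 both_big)
  }
})

test_that("ring bonds are excluded from the solution space", {
  ed <- allowed_edges(cached_graph("pyrrole"), 2)
  # pyrrole's only bridges are X-H bonds; every ring bond must be absent
  ring <- c(1:5)
  expect_false(any(ed$from %in% ring & ed$to %in% ring))
})

test_that("fragment extraction conserves atoms and orders deterministically", {
  g <- mol_graph(build_chain(10, kind = "alkane", seed = 7))
  ed <- allowed_edges(g, 8)

  # all-zero state: the whole system
  f0 <- extract_fragments(g, fragmentation_state(ed))
  expect_equal(nrow(f0), 1)
  expect_equal(f0$n_atoms, g$n_atoms)
  expect_equal(f0$n_caps, 0)

  # all-ones state: the primitive monomers
  f1 <- extract_fragments(g, fragmentation_state(ed, rep(1L, nrow(ed))))
  mono <- primitive_monomers(g, ed)
  expect_equal(nrow(f1), length(mono$atoms))

  # conservation and ordering for random states
  set.seed(42)
  for (rep in 1:5) {
    bits <- as.integer(stats::runif(nrow(ed)) < 0.5)
    fr <- extract_fragments(g, fragmentation_state(ed, bits))
    expect_equal(sum(fr$n_atoms), g$n_atoms)
    expect_equal(sum(fr$size - fr$n_caps), g$n_atoms)
    firsts <- vapply(fr$atom_ids, min, 0L)
    expect_equal(firsts, sort(firsts))
    # one cap per broken bond incident to each fragment
    expect_equal(sum(fr$n_caps), 2 * sum(bits))
  }
})

test_that("hydrogen caps sit on the severed bond axis at the radius fraction", {
  g <- mol_graph(build_chain(12, kind = "alkane", seed = 1))
  ed <- allowed_edges(g, 10)
  bits <- integer(nrow(ed)); bits[2] <- 1L
  st <- fragmentation_state(ed, bits)
  fr <- extract_fragments(g, st)
  i <- ed$from[2]; j <- ed$to[2]
  xi <- unlist(g$atoms[i, c("x", "y", "z")])
  xj <- unlist(g$atoms[j, c("x", "y", "z")])

  geom <- fr$geometry[[1]]
  cap <- geom[geom$is_cap, ]
  expect_equal(nrow(cap), 1)
  cap_xyz <- unlist(cap[, c("x", "y", "z")])

  # C(sp3)-C cut with Cordero radii: fraction (0.76+0.31)/(0.76+0.76)
  frac <- (0.76 + 0.31) / (0.76 + 0.76)
  expect_equal(unname(cap_xyz), unname(xi + frac * (xj - xi)), tolerance = 1e-12)

  # collinearity with the severed bond to 1e-10
  v1 <- cap_xyz - xi; v2 <- xj - xi
  cross <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
  expect_lt(max(abs(cross)), 1e-10)
  # cap lies between the two endpoints
  expect_gt(sum(v1 * v2), 0)
  expect_lt(sqrt(sum(v1^2)), sqrt(sum(v2^2)))
})

test_that("cap placement degenerate cases", {
  # when r(j) = r(H) the cap lands exactly on x(j): use an H-H style pair
  g <- structure(list(
    atoms = tibble::tibble(element = c("C", "H"), x = c(0, 1.09), y = 0, z = 0,
                           formal_charge = 0L, id = 1:2,
                           r_cov = c(0.76, 0.31), r_vdw = c(1.7, 1.2),
                           mass = c(12, 1))), class = "mol_graph")
  caps <- cap_with_hydrogens(1L, g, tibble::tibble(from = 1L, to = 2L))
  expect_equal(c(caps$x, caps$y, caps$z), c(1.09, 0, 0))

  # a severed bond fully inside the fragment is a bookkeeping error
  expect_error(cap_with_hydrogens(c(1L, 2L), g,
                                  tibble::tibble(from = 1L, to = 2L)),
               "does not cross")
})

test_that("Gaussian-overlap volumes match the closed form", {
  one <- tibble::tibble(element = "H", x = 0, y = 0, z = 0)
  expect_equal(fragment_volume(one, sigma = 1), 4 * pi / 3, tolerance = 1e-12)

  # two identical atoms far apart: overlap vanishes
  two_far <- tibble::tibble(element = c("C", "C"), x = c(0, 500), y = 0, z = 0)
  expect_equal(fragment_volume(two_far), 2 * 4 / 3 * pi * 1.7^3,
               tolerance = 1e-9)

  # two carbons at bonding distance vs the independent oracle
  two <- tibble::tibble(element = c("C", "C"), x = c(0, 1.54), y = 0, z = 0)
  expected <- 2 * 4 / 3 * pi * 1.7^3 - oracle_pair_overlap(1.7, 1.7, 1.54)
  expect_equal(fragment_volume(two), expected, tolerance = 1e-10)
})

test_that("volumes are invariant under rigid motion", {
  a <- build_named_molecule("methanol")
  g <- mol_graph(a)
  v0 <- fragment_volume(a)
  v1 <- fragment_volume(rigid_motion(a))
  expect_equal(v0, v1, tolerance = 1e-9)
  expect_equal(reference_volume(mol_graph(rigid_motion(a)), 4),
               reference_volume(g, 4), tolerance = 1e-9)
})

test_that("reference volume: per-element characteristic volumes", {
  # an isolated atom has no neighbours: pure hard-sphere volume
  lone <- mol_graph(tibble::tibble(element = "Ar", x = 0, y = 0, z = 0,
                                   formal_charge = 0L))
  expect_equal(reference_volume(lone, 1), 4 / 3 * pi * 1.88^3,
               tolerance = 1e-9)

  # methanol oxygen: its overlap average runs over exactly two bonded pairs
  gm <- cached_graph("methanol")
  cv <- element_characteristic_volumes(gm)
  expect_equal(cv$mean_n_neighbours[cv$element == "O"], 2)
  o_row <- gm$atoms[gm$atoms$element == "O", ]
  nb <- gm$bonds[gm$bonds$from == o_row$id | gm$bonds$to == o_row$id, ]
  v_o_expected <- 4 / 3 * pi * 1.52^3 -
    mean(vapply(seq_len(nrow(nb)), function(k) {
      other <- setdiff(c(nb$from[k], nb$to[k]), o_row$id)
      oracle_pair_overlap(1.52, gm$atoms$r_vdw[other], nb$length[k])
    }, 0))
  expect_equal(cv$v_s[cv$element == "O"], v_o_expected, tolerance = 1e-10)

  # homonuclear diatomic: V_ref(n_t = 2) = 2 V_s with one overlap each
  h2 <- mol_graph(tibble::tibble(element = c("H", "H"), x = c(0, 0.74),
                                 y = 0, z = 0, formal_charge = 0L))
  v_s <- 4 / 3 * pi * 1.2^3 - oracle_pair_overlap(1.2, 1.2, 0.74)
  expect_equal(reference_volume(h2, 2), 2 * v_s, tolerance = 1e-10)
})

test_that("no single allowed-edge cut creates a fragment below 60% of target", {
  for (seed in 1:3) {
    g <- mol_graph(build_chain(14, kind = "alkane", seed = seed))
    n_t <- 12
    ed <- allowed_edges(g, n_t)
    for (k in seq_len(nrow(ed))) {
      bits <- integer(nrow(ed)); bits[k] <- 1L
      fr <- extract_fragments(g, fragmentation_state(ed, bits),
                              volumes = FALSE)
      expect_gte(min(fr$n_atoms), ceiling(0.6 * n_t))
    }
  }
})

test_that("fragment writer emits XYZ files and a JSON manifest", {
  g <- mol_graph(build_chain(8, kind = "alkane", seed = 2))
  ed <- allowed_edges(g, 10)
  bits <- integer(nrow(ed)); bits[1] <- 1L
  fr <- extract_fragments(g, fragmentation_state(ed, bits))
  dir <- withr::local_tempdir()
  write_fragments(fr, dir, cuts = ed[1, c("from", "to")])
  expect_true(file.exists(file.path(dir, "fragment_001.xyz")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_fragments, 2)
  expect_equal(sum(man$sizes_bare), g$n_atoms)
})
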