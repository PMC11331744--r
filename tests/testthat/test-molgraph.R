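test_that("bond perception follows the reference-length window and order rule", {
  # far-apart hydrogens: no bond
  far <- tibble::tibble(element = c("H", "H"), x = c(0, 10), y = 0, z = 0,
                        formal_charge = 0L)
  expect_equal(nrow(perceive_bonds(far)), 0)

  # methanol: exactly the five expected single bonds
  b <- cached_graph("methanol")$bonds
  expect_equal(nrow(b), 5)
  expect_true(all(b$order == 1L))

  # ethene: C=C assigned order 2 by nearest reference length
  b2 <- cached_graph("ethene")$bonds
  cc <- b2[b2$from == 1 & b2$to == 2, ]
  expect_equal(cc$order, 2L)

  # overlapping atoms are a hard error naming the pair
  clash <- tibble::tibble(element = c("C", "C"), x = c(0, 0.1), y = 0, z = 0,
                          formal_charge = 0L)
  expect_error(perceive_bonds(clash), "overlapping atoms 1 and 2")
})

test_that("bond perception is invariant under rigid motion", {
  for (name in c("methanol", "pyrrole", "3-chloroprop-1-ene")) {
    a <- build_named_molecule(name)
    b0 <- perceive_bonds(a)
    b1 <- perceive_bonds(rigid_motion(a))
    expect_equal(b1[, c("from", "to", "order")], b0[, c("from", "to", "order")],
                 info = name)
  }
})

test_that("node attributes: hybridisation and pi-electron counting", {
  # pyrrole nitrogen donates its lone pair: two pi electrons
  gp <- cached_graph("pyrrole")
  n_idx <- which(gp$atoms$element == "N")
  expect_equal(gp$atoms$n_pi[n_idx], 2L)
  expect_equal(gp$atoms$hybridisation[n_idx], "sp2")

  # methane: sp3 carbon, no pi system anywhere
  gm <- cached_graph("methane")
  expect_equal(gm$atoms$hybridisation[1], "sp3")
  expect_true(all(gm$atoms$n_pi == 0L))

  # 1,3-butadiene: four sp2 carbons contributing one pi electron each
  gb <- cached_graph("1,3-butadiene")
  carbons <- which(gb$atoms$element == "C")
  expect_true(all(gb$atoms$hybridisation[carbons] == "sp2"))
  expect_true(all(gb$atoms$n_pi[carbons] == 1L))

  # unknown element is a hard error
  bad <- tibble::tibble(element = c("C", "Xx"), x = c(0, 1.5), y = 0, z = 0,
                        formal_charge = 0L)
  expect_error(mol_graph(bad), "Xx")
})

test_that("conjugated systems and their scores", {
  # pyrrole: one 5-atom system with conjugation score 6/25
  gp <- cached_graph("pyrrole")
  expect_length(gp$conj_systems, 1)
  sys <- gp$conj_systems[[1]]
  expect_equal(sys$n_atoms, 5)
  expect_equal(sys$cs, 6 / 25)
  expect_equal(sys$delta_max, 4)

  # n-butane: saturated, no conjugation
  expect_length(cached_graph("n-butane")$conj_systems, 0)

  # 1,3-butadiene: one 4-atom system, cs = (1/4) * 4 * (1/4)
  gb <- cached_graph("1,3-butadiene")
  expect_length(gb$conj_systems, 1)
  expect_equal(gb$conj_systems[[1]]$cs, 1 / 4)
})

test_that("stored conjugation scores reproduce from the pi-contribution map", {
  for (name in c("pyrrole", "1,3-butadiene", "stearic-like-chain")) {
    for (sys in cached_graph(name)$conj_systems) {
      cs_re <- sum(sys$pi_contribution / sys$n_atoms) / sys$n_atoms
      expect_equal(sys$cs, cs_re, tolerance = 1e-12, info = name)
    }
  }
})

test_that("hyperconjugated pair enumeration matches the worked examples", {
  # 3-chloroprop-1-ene: exactly one pair, C=C donor (atoms 1,2),
  # C-Cl acceptor (atoms 3,4), one bond apart
  gc <- cached_graph("3-chloroprop-1-ene")
  expect_length(gc$hyper_pairs, 1)
  p <- gc$hyper_pairs[[1]]
  expect_setequal(p$donor$atoms, c(1L, 2L))
  expect_setequal(p$acceptor$atoms, c(3L, 4L))
  expect_equal(p$donor$type, "pi")
  expect_equal(p$acceptor$type, "sigma")
  expect_equal(p$separation_bonds, 1L)
  expect_equal(p$donated_electrons, 2)

  # methane: nothing to pair
  expect_length(cached_graph("methane")$hyper_pairs, 0)

  # propene: the C=C pi donor pairs with each allylic C-H at separation 1
  gpr <- cached_graph("propene")
  allylic <- Filter(function(p) p$donor$label == "C=C" &&
                      p$acceptor$label == "C-H" && p$separation_bonds == 1L,
                    gpr$hyper_pairs)
  expect_gte(length(allylic), 1)
})

test_that("hyperconjugated pairs obey the structural invariants", {
  for (name in c("propene", "3-chloroprop-1-ene", "methanol",
                 "stearic-like-chain")) {
    g <- cached_graph(name)
    for (p in g$hyper_pairs) {
      expect_false(p$donor$type == p$acceptor$type)
      expect_lte(p$separation_bonds, 3L)
      expect_gte(p$separation_bonds, 1L)
      expect_length(intersect(p$donor$atoms, p$acceptor$atoms), 0)
    }
    # pi-electron attribute is zero outside conjugated systems
    members <- unlist(lapply(g$conj_systems, `[[`, "atom_indices"))
    outside <- setdiff(seq_len(g$n_atoms), members)
    expect_true(all(g$atoms$n_pi[outside] == 0L))
  }
})

test_that("tidy and glance summarise a molecular graph", {
  g <- cached_graph("pyrrole")
  expect_equal(nrow(tidy(g)), 10)
  gl <- glance(g)
  expect_equal(gl$n_atoms, 10)
  expect_equal(gl$n_conjugated_systems, 1)
})
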