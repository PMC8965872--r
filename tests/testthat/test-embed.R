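test_that("benzene embeds as a planar regular hexagon, deterministically", {
  b <- embed_molecule(mol_from_smiles("c1ccccc1", "benzene"))
  xyz <- as.matrix(b$atoms[b$atoms$element == "C", c("x", "y", "z")])
  ring_d <- vapply(1:6, function(i) sqrt(sum((xyz[i, ] - xyz[i %% 6 + 1, ])^2)),
                   numeric(1))
  expect_lt(diff(range(ring_d)), 1e-9)
  expect_lt(diff(range(xyz %*% svd(scale(xyz, scale = FALSE))$v[, 3])), 1e-9)
  b2 <- embed_molecule(mol_from_smiles("c1ccccc1", "benzene"))
  expect_identical(b$atoms, b2$atoms)
})

test_that("acyclic chains use idealized bond lengths and tetrahedral angles", {
  e <- embed_molecule(mol_from_smiles("CCO", "ethanol"))
  xyz <- as.matrix(e$atoms[, c("x", "y", "z")])
  cc <- sqrt(sum((xyz[1, ] - xyz[2, ])^2))
  co <- sqrt(sum((xyz[2, ] - xyz[3, ])^2))
  expect_equal(cc, 1.52, tolerance = 1e-6)
  expect_equal(co, 1.42, tolerance = 1e-6)
  v1 <- xyz[1, ] - xyz[2, ]; v2 <- xyz[3, ] - xyz[2, ]
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(ang, 109.47, tolerance = 0.01)
})

test_that("fused ring systems are rejected with a clear error", {
  expect_error(embed_molecule(mol_from_smiles("c1ccc2ccccc2c1", "naphthalene")),
               class = "fragesp_embed_unsupported")
})

test_that("anchored ensembles pin the anchor to the template exactly", {
  tmpl <- anchor_template()
  frag <- ring_fragment_of("CCCCc1ccccc1")  # the ring side
  ens <- generate_anchored_conformers(attach_anchor(frag), tmpl,
                                      max_confs = 10, seed = 7)
  for (conf in ens$conformers) {
    expect_equal(conf[ens$anchor, ], unname(tmpl$coords), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("rigid fragments give one conformer; flexible ones several, seeded", {
  benz <- ring_fragment_of("Cc1ccccc1")
  ens_rigid <- generate_anchored_conformers(attach_anchor(benz), max_confs = 10, seed = 1)
  expect_length(ens_rigid$conformers, 1)

  frs <- fragment_molecule(mol_from_smiles("CCCCc1ccccc1", "butylbenzene"))
  butyl <- frs[[which(vapply(frs, function(f) f$canonical_key, character(1)) == "*CCCC")]]
  ens <- generate_anchored_conformers(attach_anchor(butyl), max_confs = 10, seed = 7)
  expect_gte(length(ens$conformers), 2)
  expect_lte(length(ens$conformers), 10)
  ens2 <- generate_anchored_conformers(attach_anchor(butyl), max_confs = 10, seed = 7)
  expect_identical(ens$conformers, ens2$conformers)
  ens3 <- generate_anchored_conformers(attach_anchor(butyl), max_confs = 10, seed = 8)
  expect_false(identical(ens$conformers, ens3$conformers))
})

test_that("torsion driving respects minimum nonbonded separations", {
  frs <- fragment_molecule(mol_from_smiles("CCCCc1ccccc1", "butylbenzene"))
  butyl <- frs[[which(vapply(frs, function(f) f$canonical_key, character(1)) == "*CCCC")]]
  ens <- generate_anchored_conformers(attach_anchor(butyl), max_confs = 10, seed = 7)
  vd <- vdw_radii(ens$mol$atoms$element)
  topo <- igraph::distances(fragesp:::.mol_graph(ens$mol))
  far <- which(topo >= 3 & upper.tri(topo), arr.ind = TRUE)
  for (conf in ens$conformers) {
    d <- sqrt(rowSums((conf[far[, 1], ] - conf[far[, 2], ])^2))
    expect_true(all(d >= 0.5 * (vd[far[, 1]] + vd[far[, 2]])))
  }
})
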