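test_that("the ring-bond cutting rule produces the expected fragments", {
  tol <- fragment_molecule(mol_from_smiles("Cc1ccccc1", "toluene"))
  expect_length(tol, 2)
  sizes <- sort(vapply(tol, function(f) nrow(f$mol$atoms), integer(1)))
  expect_equal(sizes, c(1, 6))
  expect_true(all(vapply(tol, function(f) nrow(f$attachments), integer(1)) == 1))

  cyc <- fragment_molecule(mol_from_smiles("C1CCCCC1", "cyclohexane"))
  expect_length(cyc, 1)
  expect_equal(nrow(cyc[[1]]$attachments), 0)
  expect_true(attr(cyc, "ring_free") == FALSE || nrow(cyc[[1]]$attachments) == 0)

  # anisole: only the O-ring bond qualifies (O-CH3 has no ring end)
  ani <- fragment_molecule(mol_from_smiles("COc1ccccc1", "anisole"))
  expect_length(ani, 2)
  keys <- sort(vapply(ani, function(f) f$canonical_key, character(1)))
  expect_true("*c1ccccc1" %in% keys)
  expect_true(any(grepl("O", keys)))  # the methoxy piece stays whole

  # biaryl single bonds are cut (both ends are ring atoms)
  bip <- fragment_molecule(mol_from_smiles("c1ccc(-c2ccccc2)cc1", "biphenyl"))
  expect_length(bip, 2)
})

test_that("fragmentation conserves heavy atoms and reassembly restores the parent", {
  for (m in make_toy_drug_molecules(10, seed = 3)) {
    frs <- fragment_molecule(m)
    got <- sort(unlist(lapply(frs, function(f) f$mol$atoms$element[f$mol$atoms$element != "H"])))
    want <- sort(m$atoms$element[m$atoms$element != "H"])
    expect_identical(got, want)
    expect_identical(canonical_smiles(reassemble_fragments(frs, m$id)),
                     canonical_smiles(m))
  }
})

test_that("canonical keys are invariant under input atom ordering", {
  a <- fragment_molecule(mol_from_smiles("Cc1ccncc1", "w1"))
  b <- fragment_molecule(mol_from_smiles("c1cc(C)ccn1", "w2"))
  expect_setequal(vapply(a, function(f) f$canonical_key, character(1)),
                  vapply(b, function(f) f$canonical_key, character(1)))
})

test_that("capping uses hydrogen at the primary and methyl elsewhere", {
  benz <- ring_fragment_of("Cc1ccccc1")
  capped <- cap_fragment(benz)
  expect_equal(canonical_smiles(capped), "c1ccccc1")
  expect_equal(attr(capped, "cap_state"), "h_capped")

  mesitylene <- ring_fragment_of("Cc1cc(C)cc(C)c1")
  expect_equal(nrow(mesitylene$attachments), 3)
  capped3 <- cap_fragment(mesitylene, 1)
  # one H cap + two methyl caps: a xylene
  expect_equal(sum(capped3$atoms$element == "C"), 8)
  expect_identical(canonical_smiles(cap_fragment(mesitylene, 1)),
                   canonical_smiles(capped3))  # idempotent on the key
  expect_error(cap_fragment(benz, 5), class = "fragesp_bad_attachment")
})

test_that("the anchor attaches, tags ten atoms, and round-trips through removal", {
  frag <- ring_fragment_of("Cc1ccccc1")
  anchored <- attach_anchor(frag)
  expect_length(anchored$anchor, 10)
  expect_equal(sum(anchored$atoms$element == "N"), 6)
  ens <- generate_anchored_conformers(anchored, max_confs = 3, seed = 1)
  removed <- remove_anchor(ens$mol)
  expect_identical(canonical_smiles(removed), canonical_smiles(cap_fragment(frag)))
  expect_error(remove_anchor(cap_fragment(frag)), class = "fragesp_anchor_error")
})

test_that("anchoring a hexazine-containing input is refused", {
  hex <- fragment_molecule(mol_from_smiles("CN1N=NN=NN1", "hexazine_methyl"))
  ring <- hex[[which.max(vapply(hex, function(f) nrow(f$mol$atoms), integer(1)))]]
  expect_error(attach_anchor(ring), class = "fragesp_anchor_clash")
})
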