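test_that("point-charge pairs regenerate bit-identically and honour their modes", {
  p1 <- make_point_charge_pair(5, seed = 42)
  p2 <- make_point_charge_pair(5, seed = 42)
  expect_identical(p1, p2)
  expect_false(identical(p1, make_point_charge_pair(5, seed = 43)))
  mir <- make_point_charge_pair(4, seed = 7, mode = "mirror")
  expect_identical(mir$B$charges, -mir$A$charges)
  expect_identical(mir$B$positions, mir$A$positions)
  idn <- make_point_charge_pair(4, seed = 7, mode = "identical")
  expect_identical(idn$A, idn$B)
  expect_true(all(abs(p1$A$charges) <= 1))
  expect_true(all(abs(p1$A$positions) <= 3))
})

test_that("the heteroaromatic panel is fixed and fully fragmentable", {
  lib1 <- make_heteroaromatic_library()
  lib2 <- make_heteroaromatic_library()
  expect_identical(vapply(lib1, canonical_smiles, character(1)),
                   vapply(lib2, canonical_smiles, character(1)))
  expect_length(lib1, 12)
  rf <- ring_fragments(lib1)
  expect_gte(length(rf), 8)
  # every member contributes at least one ring fragment
  for (m in lib1) {
    frs <- fragment_molecule(m)
    has_ring <- vapply(frs, function(f) {
      nrow(f$mol$bonds) >= nrow(f$mol$atoms)
    }, logical(1))
    expect_true(any(has_ring))
  }
  pair <- attr(lib1, "bioisostere_pair")
  expect_length(pair, 2)
  expect_true(all(pair %in% names(rf)))
})

test_that("the lead set is valid, fixed, and straddles the property ranges", {
  leads <- make_lead_set()
  expect_length(leads, 8)
  smis <- vapply(leads, canonical_smiles, character(1))
  expect_false(anyNA(smis))
  expect_identical(smis, vapply(make_lead_set(), canonical_smiles, character(1)))
  props <- dplyr::bind_rows(lapply(smis, mol_properties))
  spec <- reward_spec()
  flags <- cbind(props$mw > 320 & props$mw < 420,
                 props$clogp > 2.3 & props$clogp < 4.3,
                 props$psa > 45 & props$psa < 65)
  expect_true(all(rowSums(flags) < 3))     # none already in the sweet spot
  expect_true(any(!flags[, 1]) || any(!flags[, 2]) || any(!flags[, 3]))
  expect_true(any(flags))                  # but not uniformly outside either
})

test_that("sweet-spot states are reachable under the generator's action space", {
  leads <- make_lead_set(verify = TRUE)
  expect_true(attr(leads, "sweet_spot_reachable"))
  expect_gt(sum(attr(leads, "sweet_per_lead") > 0), 1)
  expect_gt(attr(leads, "n_enumerated"), 100)
})

test_that("toy drug molecules are seeded samples of a fixed panel", {
  a <- make_toy_drug_molecules(25, seed = 1)
  b <- make_toy_drug_molecules(25, seed = 1)
  expect_identical(vapply(a, function(m) m$id, character(1)),
                   vapply(b, function(m) m$id, character(1)))
  expect_length(unique(vapply(a, function(m) m$id, character(1))), 25)
})
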