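test_that("best_shape_pair scans all pairs and breaks ties toward low indices", {
  frag <- ring_fragment_of("Cc1ccccc1")
  ens <- generate_anchored_conformers(attach_anchor(frag), max_confs = 10, seed = 1)
  sel <- best_shape_pair(ens, ens)
  expect_equal(sel$conf_a, 1)
  expect_equal(sel$conf_b, 1)
  expect_equal(sel$shape_value, 1, tolerance = 1e-9)
})

test_that("best_shape_pair finds the only overlapping conformer pair", {
  # synthetic two-conformer ensembles: only (2, 1) overlaps
  mk_ens <- function(positions_list) {
    structure(list(
      mol = list(atoms = tibble::tibble(element = c("C", "C"))),
      conformers = positions_list, anchor = integer(), seed = 1L
    ), class = "conformer_ensemble")
  }
  far <- function(x) matrix(c(x, 0, 0, x + 1.5, 0, 0), 2, 3, byrow = TRUE)
  ens_a <- mk_ens(list(far(100), far(0)))
  ens_b <- mk_ens(list(far(0.2), far(200)))
  sel <- best_shape_pair(ens_a, ens_b)
  expect_equal(c(sel$conf_a, sel$conf_b), c(2, 1))
  # exhaustive scan confirms
  vals <- outer(1:2, 1:2, Vectorize(function(i, j) {
    shape_tanimoto(list(positions = ens_a$conformers[[i]], vdw = c(1.7, 1.7)),
                   list(positions = ens_b$conformers[[j]], vdw = c(1.7, 1.7)))
  }))
  expect_equal(which(vals == max(vals), arr.ind = TRUE)[1, ], c(row = 2, col = 1))
})

test_that("a fragment is identical to itself through the full pipeline", {
  cfg <- run_config()
  frag <- ring_fragment_of("Cc1cccnc1")
  res <- fragment_pair_similarity(frag, frag, cfg)
  expect_equal(res$tanimoto, 1, tolerance = 1e-9)
  expect_equal(res$carbo, 1, tolerance = 1e-9)
  expect_equal(res$shape_tanimoto, 1, tolerance = 1e-9)
})

test_that("ESP similarity orders benzene closer to pyridine than to a nitro group", {
  cfg <- run_config()
  benz <- ring_fragment_of("Cc1ccccc1")
  pyr <- ring_fragment_of("Cc1ccccn1")
  nb <- fragment_molecule(mol_from_smiles("O=[N+]([O-])c1ccccc1", "nitrobenzene"))
  nitro <- nb[[which(vapply(nb, function(f) nrow(f$mol$atoms), integer(1)) == 3)]]
  s_py <- fragment_pair_similarity(benz, pyr, cfg)$tanimoto
  s_no2 <- fragment_pair_similarity(benz, nitro, cfg)$tanimoto
  expect_lt(s_py, 1)
  expect_gt(s_py, s_no2)
})

test_that("zero partial charges make the ESP degenerate with a clear error", {
  z <- charged_point_set(matrix(rnorm(9), 3, 3), rep(0, 3), vdw = rep(1.7, 3))
  expect_error(esp_similarity(z, z, run_config()),
               class = "fragesp_degenerate_overlap")
})

test_that("the pipeline is deterministic given the config seed", {
  cfg <- run_config(seed = 5)
  a <- ring_fragment_of("CCCc1ccccc1")
  b <- ring_fragment_of("Cc1cccnc1")
  r1 <- fragment_pair_similarity(a, b, cfg)
  r2 <- fragment_pair_similarity(a, b, cfg)
  expect_identical(r1, r2)
})
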