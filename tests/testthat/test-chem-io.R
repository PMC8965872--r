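test_that("SMILES files parse to heavy-atom records and report bad lines", {
  tf <- tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene", "CCO ethanol", "xx$$bad junk"), tf)
  expect_warning(mols <- read_molecules(tf, "smiles"), "failed to parse")
  expect_length(mols, 2)
  expect_equal(n_atoms(mols[[1]], heavy_only = TRUE), 6)
  expect_equal(mols[[1]]$provenance, "input_2d")
  failures <- attr(mols, "failures")
  expect_equal(nrow(failures), 1)
  expect_equal(failures$index, 3)
})

test_that("SDF roundtrip preserves graph, coordinates and provenance", {
  m <- embed_molecule(mol_from_smiles("CCO", "ethanol"))
  tf <- tempfile(fileext = ".sdf")
  write_molecules(list(m), tf)
  back <- read_molecules(tf, "sdf")
  expect_length(back, 1)
  expect_equal(back[[1]]$provenance, "input_3d")
  expect_equal(n_atoms(back[[1]]), n_atoms(m))
  expect_equal(back[[1]]$bonds, m$bonds)
  # SDF carries 4 decimals
  expect_equal(as.matrix(back[[1]]$atoms[, c("x", "y", "z")]),
               round(as.matrix(m$atoms[, c("x", "y", "z")]), 4),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(canonical_smiles(back[[1]]), canonical_smiles(m))
})

test_that("empty or missing molecule files are errors", {
  expect_error(read_molecules(tempfile(), "smiles"), class = "fragesp_io_error")
  tf <- tempfile(); writeLines("not-a-smiles", tf)
  suppressWarnings(expect_error(read_molecules(tf, "smiles"),
                                class = "fragesp_io_error"))
})

test_that("charge files roundtrip exactly and mismatches are hard errors", {
  tf <- tempfile()
  writeLines("0.1 -0.1", tf)
  expect_equal(read_charges(tf, 2), c(0.1, -0.1))
  expect_error(read_charges(tf, 3), class = "fragesp_charge_mismatch")
  q <- c(0.123456789012345, -3.2e-5, 1)
  write_charges(q, tf)
  expect_identical(read_charges(tf, 3), q)
  writeLines("0.1, abc", tf)
  expect_error(read_charges(tf, 2), class = "fragesp_io_error")
})

test_that("YAML config merges with CLI-style overrides and rejects unknown keys", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("integrator: monte_carlo", "mc_samples: 500", "seed: 9",
               "property_ranges:", "  mw: [300, 400]"), tf)
  cfg <- read_run_config(tf, overrides = list(metric = "carbo"))
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$integrator, "monte_carlo")
  expect_equal(cfg$mc_samples, 500L)
  expect_equal(cfg$metric, "carbo")
  expect_equal(cfg$property_ranges$mw_range, c(300, 400))
  writeLines("bogus_key: 1", tf)
  expect_error(read_run_config(tf), class = "fragesp_config_error")
  expect_error(run_config(mc_margin = -1))
})
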