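test_that("the reward ladder matches its weights", {
  spec <- reward_spec()
  expect_equal(property_reward(NULL, spec), 0)
  expect_equal(property_reward(NA, spec), 0)
  center <- tibble::tibble(mw = 370, clogp = 3.3, psa = 55)
  expect_equal(property_reward("CCO", spec, props = center), 1)
  none <- tibble::tibble(mw = 100, clogp = 0, psa = 100)
  expect_equal(property_reward("CCO", spec, props = none), 0.25)
  one <- tibble::tibble(mw = 370, clogp = 0, psa = 100)
  expect_equal(property_reward("CCO", spec, props = one), 0.5)
})

test_that("satisfying more ranges never lowers the reward", {
  spec <- reward_spec()
  inr <- list(mw = 370, clogp = 3.3, psa = 55)
  out <- list(mw = 100, clogp = 9, psa = 200)
  combos <- expand.grid(mw = c(TRUE, FALSE), clogp = c(TRUE, FALSE), psa = c(TRUE, FALSE))
  rewards <- apply(combos, 1, function(row) {
    props <- tibble::tibble(mw = if (row[1]) inr$mw else out$mw,
                            clogp = if (row[2]) inr$clogp else out$clogp,
                            psa = if (row[3]) inr$psa else out$psa)
    property_reward("C", spec, props = props)
  })
  for (i in seq_len(nrow(combos))) {
    for (j in seq_len(nrow(combos))) {
      if (all(combos[i, ] >= combos[j, ])) expect_gte(rewards[i], rewards[j])
    }
  }
})

test_that("lead states decode back to their lead and reject misfits", {
  leads <- make_lead_set()
  flib <- make_generator_library(leads, run_config(), metric = "fp")
  st <- lead_state(leads[[1]], flib)
  d <- decode_state(st, flib)
  expect_identical(attr(d, "smiles"), canonical_smiles(leads[[1]]))

  # swapping a linker slot code for a single-attachment fragment: invalid
  natt <- flib$codes$n_attachments[match(st$codes, flib$codes$code)]
  linker_slot <- which(natt == 2)[1]
  bad <- st
  bad$codes[linker_slot] <- flib$codes$code[flib$codes$n_attachments == 1][1]
  expect_null(decode_state(bad, flib))

  # unknown code: invalid, not an exception
  unknown <- setdiff(vapply(0:15, function(i) paste(rev(as.integer(intToBits(i))[1:4]), collapse = ""), character(1)),
                     flib$codes$code)
  if (length(unknown) > 0) {
    bad2 <- st
    bad2$codes[1] <- unknown[1]
    expect_null(decode_state(bad2, flib))
  }

  # a single-fragment (ring-free) lead decodes to the fragment itself
  single <- fragment_molecule(mol_from_smiles("CCO", "ethanol_lead"))
  expect_equal(nrow(single[[1]]$attachments), 0)
})

test_that("zero training epochs give an empty run", {
  leads <- make_lead_set()
  flib <- make_generator_library(leads, run_config(), metric = "fp")
  fit <- train_generator(leads, flib, run_config(epochs = 0))
  expect_equal(nrow(fit$generated), 0)
  expect_equal(nrow(fit$stats), 0)
})

test_that("short training runs are seed-deterministic and well-formed", {
  leads <- make_lead_set()
  flib <- make_generator_library(leads, run_config(), metric = "fp")
  cfg <- run_config(epochs = 2, episodes_per_epoch = 30, seed = 17)
  f1 <- train_generator(leads, flib, cfg)
  f2 <- train_generator(leads, flib, cfg)
  expect_identical(f1$stats, f2$stats)
  expect_identical(f1$generated, f2$generated)
  expect_true(all(f1$stats$frac_sweet_spot <= f1$stats$frac_mw + 1e-12))
  expect_true(all(f1$stats$frac_valid >= f1$stats$frac_sweet_spot))
  expect_true(all(vapply(f1$generated$reward, function(r) r >= 0 && r <= 1, logical(1))))
  # broom-style accessors
  expect_identical(tidy(f1), f1$stats)
  expect_equal(glance(f1)$epochs, 2)
  expect_s3_class(autoplot(f1), "ggplot")
})

test_that("sweet-spot reports count fractions correctly", {
  spec <- reward_spec()
  empty <- sweet_spot_report(tibble::tibble(smiles = character(), mw = numeric(),
                                            clogp = numeric(), psa = numeric()), spec)
  expect_equal(empty$n_molecules, 0)
  allin <- tibble::tibble(smiles = c("a", "b"), mw = c(350, 400),
                          clogp = c(3, 4), psa = c(50, 60))
  expect_equal(sweet_spot_report(allin, spec)$frac_sweet_spot, 1)
  mixed <- tibble::tibble(smiles = letters[1:4], mw = c(350, 100, 100, 100),
                          clogp = c(3, 3, 9, 9), psa = c(50, 50, 50, 200))
  expect_equal(sweet_spot_report(mixed, spec)$frac_sweet_spot, 0.25)
})
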