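test_that("Coulomb potential reproduces point-charge closed forms", {
  A1 <- charged_point_set(matrix(0, 1, 3), 1, vdw = 1.7)
  expect_equal(coulomb_potential(A1, c(1, 0, 0))$potential, 1)
  A2 <- charged_point_set(rbind(c(1, 0, 0), c(-1, 0, 0)), c(1, -1), vdw = c(1.7, 1.7))
  expect_equal(coulomb_potential(A2, c(0, 0, 0))$potential, 0)
  A3 <- charged_point_set(matrix(0, 1, 3), 2, vdw = 1.7)
  expect_equal(coulomb_potential(A3, c(0, 0, 2))$potential, 1)
  expect_error(coulomb_potential(A1, c(0, 0, 0)), class = "fragesp_singular_point")
  # prefactor scales linearly
  expect_equal(coulomb_potential(A1, c(2, 0, 0), unit_convention(332.06))$potential,
               332.06 / 2)
})

test_that("the three-Gaussian expansion tracks 1/r within 5 percent and is deterministic", {
  g <- fit_inverse_r()
  r <- exp(seq(log(g$fit_range[1]), log(g$fit_range[2]), length.out = 400))
  fit <- colSums(g$a * exp(-outer(g$b, r^2)))
  expect_lt(max(abs(fit - 1 / r) * r), 0.05)
  expect_lt(abs(sum(g$a * exp(-g$b)) - 1), 0.05)  # value at r = 1 A
  g2 <- fit_inverse_r()
  expect_identical(g$a, g2$a)
  expect_identical(g$b, g2$b)
  expect_error(fit_inverse_r(c(2, 1)))
})

test_that("analytic Gaussian overlap matches its closed form and is symmetric", {
  g <- fit_inverse_r()
  unit <- charged_point_set(matrix(0, 1, 3), 1, vdw = 1.7)
  closed <- sum(outer(g$a, g$a) * (pi / outer(g$b, g$b, "+"))^1.5)
  expect_equal(overlap_gaussian(unit, unit, g), closed, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:5) {
    p <- make_point_charge_pair(5, seed = i)
    expect_equal(overlap_gaussian(p$A, p$B, g), overlap_gaussian(p$B, p$A, g),
                 tolerance = 1e-12)
  }
})

test_that("analytic overlap agrees with the brute-force quadrature oracle", {
  g <- fit_inverse_r()
  set.seed(11)
  for (i in 1:4) {
    p <- make_point_charge_pair(sample(2:4, 1), seed = 100 + i)
    o_ana <- overlap_gaussian(p$A, p$B, g)
    o_quad <- quad_overlap_oracle(p$A, p$B, "expansion", h = 0.35, g = g)
    expect_lt(abs(o_ana - o_quad) / abs(o_quad), 0.05)
  }
})

test_that("Monte Carlo overlap is seeded-deterministic and tracks the shell oracle", {
  p <- make_point_charge_pair(2, seed = 5)
  mc1 <- overlap_mc(p$A, p$B, margin = 4, n_samples = 4000, seed = 42)
  mc2 <- overlap_mc(p$A, p$B, margin = 4, n_samples = 4000, seed = 42)
  expect_identical(mc1$estimate, mc2$estimate)
  oracle <- quad_overlap_oracle(p$A, p$B, "coulomb", margin = 4, h = 0.2)
  expect_lt(abs(mc1$estimate - oracle), 3 * mc1$std_error)
  # degenerate geometry: margin entirely inside the vdW spheres is impossible,
  # but zero accepted samples can be forced with a tiny absurd margin
  tiny <- charged_point_set(matrix(0, 1, 3), 1, vdw = 1e-6)
  expect_error(overlap_mc(tiny, tiny, margin = 1e-9, n_samples = 100, seed = 1),
               class = "fragesp_mc_degenerate")
})

test_that("Monte Carlo error shrinks like one over root n", {
  p <- make_point_charge_pair(3, seed = 9)
  oracle <- quad_overlap_oracle(p$A, p$B, "coulomb", margin = 4, h = 0.2)
  errs <- function(n) {
    vapply(1:20, function(s) {
      abs(overlap_mc(p$A, p$B, margin = 4, n_samples = n, seed = 1000 + s)$estimate - oracle)
    }, numeric(1))
  }
  ratio <- mean(errs(4000)) / mean(errs(1000))
  # expect roughly 1/2 (doubling twice); allow generous stochastic slack
  expect_lt(ratio, 0.85)
})

test_that("Carbo and Tanimoto metrics match their algebraic identities", {
  expect_equal(carbo_similarity(1, 1, 1), 1)
  expect_equal(tanimoto_similarity(1, 1, 1), 1)
  expect_equal(tanimoto_similarity(0.5, 1, 1), 1 / 3)
  expect_equal(tanimoto_similarity(-1, 1, 1), -1 / 3)
  expect_error(carbo_similarity(1, 0, 1), class = "fragesp_degenerate_overlap")
  # charge negation: carbo -1, tanimoto -1/3
  p <- make_point_charge_pair(4, seed = 2, mode = "mirror")
  g <- fit_inverse_r()
  o_ab <- overlap_gaussian(p$A, p$B, g)
  o_aa <- overlap_gaussian(p$A, p$A, g)
  o_bb <- overlap_gaussian(p$B, p$B, g)
  expect_equal(carbo_similarity(o_ab, o_aa, o_bb), -1, tolerance = 1e-12)
  expect_equal(tanimoto_similarity(o_ab, o_aa, o_bb), -1 / 3, tolerance = 1e-12)
  # carbo invariant under one-sided scaling
  k <- 3
  expect_equal(carbo_similarity(k * o_ab, k^2 * o_aa, o_bb),
               carbo_similarity(o_ab, o_aa, o_bb), tolerance = 1e-12)
  # tanimoto invariant under joint scaling
  expect_equal(tanimoto_similarity(2 * o_ab, 2 * o_aa, 2 * o_bb),
               tanimoto_similarity(o_ab, o_aa, o_bb), tolerance = 1e-12)
})

test_that("tanimoto never exceeds carbo for equal self-overlaps and non-negative cross overlap", {
  set.seed(8)
  for (i in 1:50) {
    s <- runif(1, 0.1, 10)
    o <- runif(1, 0, s)
    expect_lte(tanimoto_similarity(o, s, s), carbo_similarity(o, s, s) + 1e-12)
  }
})

test_that("renormalization maps the metric ranges onto [0, 1]", {
  expect_equal(renormalize_similarity(-1, "carbo"), 0)
  expect_equal(renormalize_similarity(1, "carbo"), 1)
  expect_equal(renormalize_similarity(-1 / 3, "tanimoto"), 0)
  expect_equal(renormalize_similarity(1, "tanimoto"), 1)
})

test_that("the combo score is the plain sum on [0, 2]", {
  expect_equal(esp_combo(1, 1), 2)
  expect_equal(esp_combo(0, 0), 0)
  expect_equal(esp_combo(0.6, 0.4), 1)
  expect_error(esp_combo(1.2, 0.1), class = "fragesp_range_error")
  expect_error(esp_combo(0.5, -0.2), class = "fragesp_range_error")
})

test_that("esp_similarity self-comparison is exactly 1 for both integrators", {
  p <- make_point_charge_pair(5, seed = 21, mode = "identical")
  res_g <- esp_similarity(p$A, p$B, run_config())
  expect_equal(res_g$carbo, 1, tolerance = 1e-12)
  expect_equal(res_g$tanimoto, 1, tolerance = 1e-12)
  res_mc <- esp_similarity(p$A, p$B, run_config(integrator = "monte_carlo",
                                                mc_samples = 2000, seed = 3))
  expect_equal(res_mc$carbo, 1, tolerance = 1e-9)
})

test_that("similarities are invariant under joint rigid motion", {
  g <- fit_inverse_r()
  p <- make_point_charge_pair(5, seed = 31)
  rot <- random_rotation(7)
  shift <- c(3.2, -1.1, 0.7)
  move <- function(ps) charged_point_set(sweep(ps$positions %*% t(rot), 2, shift, "+"),
                                         ps$charges, vdw = ps$vdw)
  s0 <- carbo_similarity(overlap_gaussian(p$A, p$B, g),
                         overlap_gaussian(p$A, p$A, g),
                         overlap_gaussian(p$B, p$B, g))
  s1 <- carbo_similarity(overlap_gaussian(move(p$A), move(p$B), g),
                         overlap_gaussian(move(p$A), move(p$A), g),
                         overlap_gaussian(move(p$B), move(p$B), g))
  expect_lt(abs(s0 - s1), 1e-9)
})
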