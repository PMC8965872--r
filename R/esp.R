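#' Charged point sets
#'
#' The sole input to all electrostatics: atom positions (angstrom), partial
#' charges (e) and van der Waals radii (angstrom). Working units drop the
#' Coulomb prefactor 1/(4 pi eps0): the Carbo metric is invariant to it by
#' normalization and the Tanimoto metric because all three overlaps scale
#' identically, so potentials are reported in units of e/angstrom times the
#' prefactor of the chosen [unit_convention()].
#'
#' @param positions n x 3 numeric matrix (angstrom).
#' @param charges Length-n numeric vector (e).
#' @param vdw Length-n vector of vdW radii (angstrom); defaults to Bondi
#'   radii looked up from `elements`.
#' @param elements Optional element symbols used to look up radii.
#' @return A `charged_point_set`.
#' @export
charged_point_set <- function(positions, charges, vdw = NULL, elements = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) abort("positions must be an n x 3 matrix.")
  n <- nrow(positions)
  if (length(charges) != n) {
    abort("positions and charges differ in length.", class = "fragesp_charge_mismatch")
  }
  if (is.null(vdw)) {
    if (is.null(elements)) abort("Supply either vdw radii or elements.")
    vdw <- vdw_radii(elements)
  }
  if (length(vdw) != n || any(vdw <= 0)) abort("Bad vdW radii.")
  if (!all(is.finite(positions))) abort("Non-finite positions.")
  structure(list(positions = unname(positions), charges = as.numeric(charges),
                 vdw = as.numeric(vdw)),
            class = "charged_point_set")
}

#' @export
print.charged_point_set <- function(x, ...) {
  cat(sprintf("<charged_point_set> %d point charges, net %+0.3f e\n",
              length(x$charges), sum(x$charges)))
  invisible(x)
}

# Charged point set from a charged, hydrogen-complete molecule record.
.mol_point_set <- function(mol) {
  if (is.null(mol$charges)) {
    abort(paste0("Molecule ", mol$id, " carries no partial charges."),
          class = "fragesp_charge_error")
  }
  charged_point_set(.coords(mol), mol$charges, elements = mol$atoms$element)
}

#' Unit convention for potentials
#'
#' Houses the constant multiplying q/r. The package default is 1 (atomic
#' charge / angstrom working units); both similarity metrics are invariant
#' to the choice as long as both members of a pair share it.
#'
#' @param coulomb_prefactor Strictly positive scalar.
#' @return A `unit_convention`.
#' @export
unit_convention <- function(coulomb_prefactor = 1) {
  stopifnot(is.numeric(coulomb_prefactor), coulomb_prefactor > 0)
  structure(list(coulomb_prefactor = coulomb_prefactor), class = "unit_convention")
}

#' Coulomb potential of a charged point set
#'
#' V(r) = prefactor * sum_i q_i / |r - r_i|, the point-charge potential the
#' whole similarity machinery is built on.
#'
#' @param A A [charged_point_set()].
#' @param r Evaluation point (length-3) or an m x 3 matrix of points.
#' @param units A [unit_convention()].
#' @return For a single point, a tibble with columns `x`, `y`, `z`,
#'   `potential`; for a matrix, one row per point.
#' @export
coulomb_potential <- function(A, r, units = unit_convention()) {
  stopifnot(inherits(A, "charged_point_set"))
  r <- if (is.null(dim(r))) matrix(r, ncol = 3) else as.matrix(r)
  d2 <- outer(rowSums(r^2), rowSums(A$positions^2), "+") - 2 * r %*% t(A$positions)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 1e-8)) {
    abort("Evaluation point coincides with an atom center (distance < 1e-8).",
          class = "fragesp_singular_point")
  }
  v <- units$coulomb_prefactor * as.numeric((1 / d) %*% A$charges)
  tibble(x = r[, 1], y = r[, 2], z = r[, 3], potential = v)
}

#' Three-Gaussian expansion of 1/r
#'
#' Least-squares fit of sum_k a_k exp(-b_k r^2) to 1/r on a 200-point
#' logarithmic grid over `fit_range`, minimizing the *relative* residual so
#' that the fit stays within a uniform percentage band of 1/r across the
#' whole range. Deterministic: fixed grid, fixed starting values
#' (Levenberg-Marquardt via minpack.lm).
#'
#' The default range 0.5-6 angstrom spans from well inside the smallest vdW
#' sphere to beyond typical fragment-pair interatomic distances; three
#' Gaussians hold a <= 5 percent relative error over roughly a twelvefold
#' range, which this window respects.
#'
#' @param fit_range Length-2 numeric, 0 < r_min < r_max (angstrom).
#' @param n_grid Grid size.
#' @return A `gaussian_expansion`: list with `a`, `b` (length 3),
#'   `fit_range`, `max_rel_error`.
#' @export
fit_inverse_r <- function(fit_range = c(0.5, 6), n_grid = 200) {
  stopifnot(length(fit_range) == 2, fit_range[1] > 0, fit_range[1] < fit_range[2])
  k <- 3
  r <- exp(seq(log(fit_range[1]), log(fit_range[2]), length.out = n_grid))
  y <- 1 / r
  centers <- exp(seq(log(fit_range[1]), log(fit_range[2]), length.out = k))
  start <- c(1 / centers, log(1 / centers^2))
  resid_fn <- function(p) {
    a <- p[1:k]; b <- exp(p[(k + 1):(2 * k)])
    f <- colSums(a * exp(-outer(b, r^2)))
    (f - y) / y
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 1000))
  a <- fit$par[1:k]; b <- exp(fit$par[(k + 1):(2 * k)])
  ord <- order(b, decreasing = TRUE)
  a <- a[ord]; b <- b[ord]
  f <- colSums(a * exp(-outer(b, r^2)))
  max_rel <- max(abs((f - y) / y))
  if (max_rel > 0.25) {
    abort(sprintf("Gaussian fit of 1/r failed to converge (max relative residual %.3f).",
                  max_rel),
          class = "fragesp_fit_error")
  }
  structure(list(a = a, b = b, fit_range = fit_range, max_rel_error = max_rel),
            class = "gaussian_expansion")
}

#' @export
print.gaussian_expansion <- function(x, ...) {
  cat(sprintf("<gaussian_expansion> 1/r ~ sum of 3 Gaussians on [%g, %g] A (max rel err %.2f%%)\n",
              x$fit_range[1], x$fit_range[2], 100 * x$max_rel_error))
  cat("  a:", format(x$a, digits = 6), "\n  b:", format(x$b, digits = 6), "\n")
  invisible(x)
}

# Evaluate the expansion at distances r.
.expansion_eval <- function(g, r) {
  colSums(g$a * exp(-outer(g$b, r^2)))
}

# The package-default expansion, fitted once per session.
.fragesp_cache <- new.env(parent = emptyenv())
default_expansion <- function() {
  if (is.null(.fragesp_cache$expansion)) {
    .fragesp_cache$expansion <- fit_inverse_r()
  }
  .fragesp_cache$expansion
}

#' Analytic ESP overlap via the Gaussian expansion
#'
#' With each 1/|r - r_i| replaced by the three-Gaussian expansion, the
#' overlap integral of two Coulomb potentials over all space has the closed
#' form
#' sum_ij q_i q_j sum_kl a_k a_l (pi/(b_k+b_l))^(3/2)
#'   exp(-(b_k b_l/(b_k+b_l)) d_ij^2).
#'
#' @param A,B [charged_point_set()] objects.
#' @param g A `gaussian_expansion` (package default if omitted).
#' @param units A [unit_convention()].
#' @return A single overlap value (symmetric in A and B).
#' @export
overlap_gaussian <- function(A, B, g = default_expansion(),
                             units = unit_convention()) {
  stopifnot(inherits(A, "charged_point_set"), inherits(B, "charged_point_set"))
  d2 <- outer(rowSums(A$positions^2), rowSums(B$positions^2), "+") -
    2 * A$positions %*% t(B$positions)
  d2 <- pmax(d2, 0)
  k <- length(g$a)
  acc <- matrix(0, nrow(d2), ncol(d2))
  for (kk in seq_len(k)) for (ll in seq_len(k)) {
    bs <- g$b[kk] + g$b[ll]
    acc <- acc + g$a[kk] * g$a[ll] * (pi / bs)^1.5 * exp(-(g$b[kk] * g$b[ll] / bs) * d2)
  }
  units$coulomb_prefactor^2 * as.numeric(A$charges %*% acc %*% B$charges)
}

#' Monte Carlo ESP overlap over the vdW-to-margin shell
#'
#' Uniform rejection sampling in the bounding box of all (vdW + margin)
#' spheres of the union of A's and B's atoms: points inside any vdW sphere
#' or outside every margin sphere are rejected; the estimate is the region
#' volume times the mean of V_A * V_B over accepted points. Fully
#' deterministic for a fixed seed.
#'
#' @param A,B [charged_point_set()] objects.
#' @param margin Shell thickness beyond the vdW surface (angstrom, > 0).
#' @param n_samples Number of box samples (>= 100).
#' @param seed Integer seed.
#' @param units A [unit_convention()].
#' @return A tibble with columns `estimate`, `std_error`, `n_accepted`,
#'   `region_volume`.
#' @export
overlap_mc <- function(A, B, margin = 4, n_samples = 10000, seed = 1L,
                       units = unit_convention()) {
  stopifnot(inherits(A, "charged_point_set"), inherits(B, "charged_point_set"))
  stopifnot(margin > 0, n_samples >= 100)
  pos <- rbind(A$positions, B$positions)
  rad <- c(A$vdw, B$vdw)
  lo <- apply(pos - (rad + margin), 2, min)
  hi <- apply(pos + (rad + margin), 2, max)
  vbox <- prod(hi - lo)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  pts <- cbind(runif(n_samples, lo[1], hi[1]),
               runif(n_samples, lo[2], hi[2]),
               runif(n_samples, lo[3], hi[3]))
  d2 <- outer(rowSums(pts^2), rowSums(pos^2), "+") - 2 * pts %*% t(pos)
  d <- sqrt(pmax(d2, 0))
  inside_vdw <- rowSums(sweep(d, 2, rad, "<")) > 0
  in_margin <- rowSums(sweep(d, 2, rad + margin, "<")) > 0
  ok <- !inside_vdw & in_margin
  if (!any(ok)) {
    abort("No Monte Carlo samples accepted (degenerate geometry).",
          class = "fragesp_mc_degenerate")
  }
  na <- nrow(A$positions)
  va <- as.numeric((1 / d[, seq_len(na), drop = FALSE]) %*% A$charges)
  vb <- as.numeric((1 / d[, na + seq_len(nrow(B$positions)), drop = FALSE]) %*% B$charges)
  f <- ifelse(ok, va * vb, 0) * units$coulomb_prefactor^2
  est <- vbox * mean(f)
  se <- vbox * stats::sd(f) / sqrt(n_samples)
  tibble(estimate = est, std_error = se, n_accepted = sum(ok), region_volume = vbox * mean(ok))
}

#' Carbo similarity from overlap integrals
#'
#' o_ab / sqrt(o_aa * o_bb): the cosine of the two fields, invariant under
#' uniform scaling of either charge set.
#'
#' @param o_ab,o_aa,o_bb Overlap integrals; the self-overlaps must be
#'   positive.
#' @return Value in `[-1, 1]`.
#' @export
carbo_similarity <- function(o_ab, o_aa, o_bb) {
  if (o_aa <= 0 || o_bb <= 0) {
    abort("Self-overlaps must be strictly positive.", class = "fragesp_degenerate_overlap")
  }
  o_ab / sqrt(o_aa * o_bb)
}

#' Tanimoto similarity from overlap integrals
#'
#' o_ab / (o_aa + o_bb - o_ab): magnitude-sensitive, lower bound -1/3,
#' invariant under *joint* uniform scaling of all three overlaps.
#'
#' @inheritParams carbo_similarity
#' @return Value in `[-1/3, 1]`.
#' @export
tanimoto_similarity <- function(o_ab, o_aa, o_bb) {
  if (o_aa <= 0 || o_bb <= 0) {
    abort("Self-overlaps must be strictly positive.", class = "fragesp_degenerate_overlap")
  }
  den <- o_aa + o_bb - o_ab
  stopifnot(den > 0)
  o_ab / den
}

#' Renormalize a raw ESP similarity onto [0, 1]
#'
#' Carbo maps via (s + 1) / 2; Tanimoto via (s + 1/3) / (4/3). Raw values
#' are more informative and stay the library default; the combo score and
#' the generator need a common `[0, 1]` scale.
#'
#' @param s Raw similarity value(s).
#' @param metric `"tanimoto"` or `"carbo"`.
#' @return Renormalized value(s) in `[0, 1]`.
#' @export
renormalize_similarity <- function(s, metric = c("tanimoto", "carbo")) {
  metric <- match.arg(metric)
  switch(metric,
         carbo = (s + 1) / 2,
         tanimoto = (s + 1 / 3) / (4 / 3))
}

#' Combined ESP + shape score
#'
#' Unweighted sum of a renormalized ESP similarity and a shape Tanimoto,
#' both on `[0, 1]`, giving the usual combo range `[0, 2]`.
#'
#' @param esp_renormalized ESP similarity on `[0, 1]`.
#' @param shape Shape Tanimoto on `[0, 1]`.
#' @return Value in `[0, 2]`.
#' @export
esp_combo <- function(esp_renormalized, shape) {
  if (any(esp_renormalized < -1e-12 | esp_renormalized > 1 + 1e-12) ||
      any(shape < -1e-12 | shape > 1 + 1e-12)) {
    abort("Combo inputs must lie in [0, 1].", class = "fragesp_range_error")
  }
  esp_renormalized + shape
}

# RNG bookkeeping: seeded internals must not disturb the caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' ESP similarity of two charged point sets
#'
#' Convenience wrapper running the configured integrator and metric on a
#' prealigned pair and returning the full overlap/similarity record.
#'
#' @param A,B [charged_point_set()] objects.
#' @param cfg A [run_config()].
#' @param shape Optional shape Tanimoto to fold into the combo score.
#' @return A tibble with columns `overlap_ab`, `overlap_aa`, `overlap_bb`,
#'   `carbo`, `tanimoto`, `esp_similarity` (the configured metric, raw or
#'   renormalized per `cfg$renormalize`), `shape_tanimoto`, `combo`,
#'   `integrator`, `renormalized`.
#' @export
esp_similarity <- function(A, B, cfg = run_config(), shape = NA_real_) {
  if (cfg$integrator == "gaussian_fit") {
    g <- default_expansion()
    o_ab <- overlap_gaussian(A, B, g)
    o_aa <- overlap_gaussian(A, A, g)
    o_bb <- overlap_gaussian(B, B, g)
  } else {
    o_ab <- overlap_mc(A, B, cfg$mc_margin, cfg$mc_samples, cfg$seed)$estimate
    o_aa <- overlap_mc(A, A, cfg$mc_margin, cfg$mc_samples, cfg$seed)$estimate
    o_bb <- overlap_mc(B, B, cfg$mc_margin, cfg$mc_samples, cfg$seed)$estimate
  }
  carbo <- carbo_similarity(o_ab, o_aa, o_bb)
  tanimoto <- tanimoto_similarity(o_ab, o_aa, o_bb)
  raw <- if (cfg$metric == "carbo") carbo else tanimoto
  esp <- if (cfg$renormalize) renormalize_similarity(raw, cfg$metric) else raw
  combo <- if (is.na(shape)) NA_real_ else {
    esp_combo(renormalize_similarity(tanimoto, "tanimoto"), shape)
  }
  tibble(overlap_ab = o_ab, overlap_aa = o_aa, overlap_bb = o_bb,
         carbo = carbo, tanimoto = tanimoto, esp_similarity = esp,
         shape_tanimoto = shape, combo = combo,
         integrator = cfg$integrator, renormalized = cfg$renormalize)
}
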