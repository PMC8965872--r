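#' Shape Tanimoto of two conformers
#'
#' Volume-overlap similarity from the Gaussian-sphere model: each atom is
#' a spherical Gaussian rho_i(r) = p exp(-alpha_i |r - r_i|^2) with
#' alpha_i chosen so the Gaussian's integral equals the atom's hard-sphere
#' vdW volume. Only first-order (pairwise) overlap integrals are used;
#' the weight p = 6 is calibrated so that the pairwise-only Tanimoto
#' reproduces hard-sphere (voxel) volume-overlap Tanimoto values for
#' partially overlapping aromatic systems, compensating the higher-order
#' terms a softer weight would need. Overlaps:
#' O_XY = sum_{i in X, j in Y} p^2 (pi/(a_i+a_j))^(3/2)
#'        exp(-a_i a_j d_ij^2 / (a_i+a_j)),
#' and the Tanimoto is O_AB / (O_AA + O_BB - O_AB), which is exactly 1 for
#' a conformer against itself.
#'
#' @param A,B Either `mol_record`s with 3D coordinates or lists with
#'   `positions` (n x 3 matrix) and `vdw` (radii). Hydrogens are included
#'   when present.
#' @param exclude_a,exclude_b Optional atom indices to drop (e.g. anchor
#'   atoms) before comparing.
#' @return Value in `[0, 1]`.
#' @export
shape_tanimoto <- function(A, B, exclude_a = integer(), exclude_b = integer()) {
  sa <- .shape_points(A, exclude_a)
  sb <- .shape_points(B, exclude_b)
  if (nrow(sa$positions) == 0 || nrow(sb$positions) == 0) {
    abort("Empty conformer in shape comparison.", class = "fragesp_empty_molecule")
  }
  o_ab <- .gauss_volume_overlap(sa, sb)
  o_aa <- .gauss_volume_overlap(sa, sa)
  o_bb <- .gauss_volume_overlap(sb, sb)
  o_ab / (o_aa + o_bb - o_ab)
}

.shape_points <- function(x, exclude = integer()) {
  if (inherits(x, "mol_record")) {
    keep <- setdiff(seq_len(nrow(x$atoms)), exclude)
    list(positions = .coords(x)[keep, , drop = FALSE],
         vdw = vdw_radii(x$atoms$element[keep]))
  } else if (inherits(x, "charged_point_set")) {
    keep <- setdiff(seq_len(nrow(x$positions)), exclude)
    list(positions = x$positions[keep, , drop = FALSE], vdw = x$vdw[keep])
  } else {
    keep <- setdiff(seq_len(nrow(x$positions)), exclude)
    list(positions = as.matrix(x$positions)[keep, , drop = FALSE], vdw = x$vdw[keep])
  }
}

# Gaussian-sphere cross overlap between two atom sets (alpha from the
# hard-sphere volume condition p (pi/alpha)^(3/2) = 4/3 pi r^3).
.gauss_volume_overlap <- function(sa, sb, p = 6) {
  alpha_a <- pi * (3 * p / (4 * pi * sa$vdw^3))^(2 / 3)
  alpha_b <- pi * (3 * p / (4 * pi * sb$vdw^3))^(2 / 3)
  d2 <- outer(rowSums(sa$positions^2), rowSums(sb$positions^2), "+") -
    2 * sa$positions %*% t(sb$positions)
  d2 <- pmax(d2, 0)
  asum <- outer(alpha_a, alpha_b, "+")
  aprod <- outer(alpha_a, alpha_b, "*")
  sum(p^2 * (pi / asum)^1.5 * exp(-(aprod / asum) * d2))
}
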