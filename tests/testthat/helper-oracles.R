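# Brute-force quadrature oracle for overlap integrals, built before the
# analytic/MC implementations were tested against it. Midpoint rule on a
# regular grid, processed in slabs to bound memory.
#
# potential = "expansion": integrate the product of the three-Gaussian
#   expanded potentials over the full domain where the expansion has
#   support (checks the analytic double-sum independently).
# potential = "coulomb": integrate the true point-charge potentials over
#   the vdW-excluded shell within `margin` of any atom (the Monte Carlo
#   region).
quad_overlap_oracle <- function(A, B, potential = c("expansion", "coulomb"),
                                margin = 4, h = 0.3,
                                g = fragesp::fit_inverse_r()) {
  potential <- match.arg(potential)
  pos <- rbind(A$positions, B$positions)
  rad <- c(A$vdw, B$vdw)
  # the expansion domain must cover the broadest Gaussian's tail: pad to
  # where exp(-2 b_min r^2) < 1e-7, else truncation bias dominates small
  # cross-overlaps
  pad <- if (potential == "expansion") {
    sqrt(log(1e7) / (2 * min(g$b)))
  } else {
    max(rad) + margin
  }
  lo <- apply(pos, 2, min) - pad
  hi <- apply(pos, 2, max) + pad
  gx <- seq(lo[1] + h / 2, hi[1], by = h)
  gy <- seq(lo[2] + h / 2, hi[2], by = h)
  gz <- seq(lo[3] + h / 2, hi[3], by = h)
  na <- nrow(A$positions)
  eval_pot <- function(d, q) {
    if (potential == "expansion") {
      v <- matrix(0, nrow(d), ncol(d))
      for (k in seq_along(g$a)) v <- v + g$a[k] * exp(-g$b[k] * d^2)
      as.numeric(v %*% q)
    } else {
      as.numeric((1 / d) %*% q)
    }
  }
  total <- 0
  for (x in gx) {
    pts <- as.matrix(expand.grid(x = x, y = gy, z = gz))
    d2 <- outer(rowSums(pts^2), rowSums(pos^2), "+") - 2 * pts %*% t(pos)
    d <- sqrt(pmax(d2, 1e-12))
    if (potential == "coulomb") {
      keep <- rowSums(sweep(d, 2, rad, "<")) == 0 &
        rowSums(sweep(d, 2, rad + margin, "<")) > 0
      if (!any(keep)) next
      d <- d[keep, , drop = FALSE]
    }
    va <- eval_pot(d[, seq_len(na), drop = FALSE], A$charges)
    vb <- eval_pot(d[, na + seq_len(nrow(B$positions)), drop = FALSE], B$charges)
    total <- total + sum(va * vb)
  }
  total * h^3
}

# Voxel (hard-sphere union) volume-overlap Tanimoto oracle for shapes.
voxel_shape_tanimoto <- function(pos_a, rad_a, pos_b, rad_b, h = 0.25) {
  pos <- rbind(pos_a, pos_b)
  rad <- c(rad_a, rad_b)
  lo <- apply(pos - rad, 2, min) - h
  hi <- apply(pos + rad, 2, max) + h
  gx <- seq(lo[1] + h / 2, hi[1], by = h)
  gy <- seq(lo[2] + h / 2, hi[2], by = h)
  gz <- seq(lo[3] + h / 2, hi[3], by = h)
  n_a <- n_b <- n_ab <- 0
  for (x in gx) {
    pts <- as.matrix(expand.grid(x = x, y = gy, z = gz))
    ina <- rep(FALSE, nrow(pts)); inb <- rep(FALSE, nrow(pts))
    for (i in seq_len(nrow(pos_a))) {
      ina <- ina | (rowSums(sweep(pts, 2, pos_a[i, ])^2) < rad_a[i]^2)
    }
    for (i in seq_len(nrow(pos_b))) {
      inb <- inb | (rowSums(sweep(pts, 2, pos_b[i, ])^2) < rad_b[i]^2)
    }
    n_a <- n_a + sum(ina); n_b <- n_b + sum(inb); n_ab <- n_ab + sum(ina & inb)
  }
  n_ab / (n_a + n_b - n_ab)
}

# Random rotation matrix from a seed (QR of a Gaussian matrix).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Largest (ring) fragment of a SMILES, for alignment tests.
ring_fragment_of <- function(smiles, id = "m") {
  frs <- fragesp::fragment_molecule(fragesp::mol_from_smiles(smiles, id))
  frs[[which.max(vapply(frs, function(f) nrow(f$mol$atoms), integer(1)))]]
}

# Random symmetric similarity matrix in [0, 1] with unit diagonal.
random_sim_matrix <- function(n, seed) {
  set.seed(seed)
  v <- matrix(runif(n * n), n, n)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  keys <- sprintf("frag%02d", seq_len(n))
  dimnames(v) <- list(keys, keys)
  structure(list(keys = keys, values = v), class = "similarity_matrix")
}
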