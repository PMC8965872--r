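# Deterministic idealized-geometry embedding.
#
# No installed package offers seeded, let alone coordinate-constrained,
# conformer embedding, and the alignment pipeline needs bit-reproducible
# geometry, so the package carries its own small internal-coordinate
# builder: rings become regular planar polygons, acyclic atoms are placed
# with idealized sp/sp2/sp3 geometry and staggered/anti default torsions,
# and an ensemble is generated by seeded torsion driving of the rotatable
# bonds. Geometries are idealized, not force-field minimized; they are
# meant for shape/ESP comparison of fragment-sized structures, where the
# anchor frame (not conformational fine detail) dominates the alignment.

.tet_ang <- acos(-1 / 3)  # 109.47 deg

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("Degenerate direction in embedding.", class = "fragesp_embed_error")
  v / n
}

# A deterministic perpendicular to u.
.perp <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  .unit(.cross3(ref, u))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Ideal remaining bond directions at an atom.
# placed: matrix of unit vectors (rows) to already-placed neighbors.
# m: total neighbor count; hyb: "sp" | "sp2" | "sp3"; w: azimuth reference.
.ideal_directions <- function(placed, m, hyb, w = NULL) {
  k <- nrow(placed)
  need <- m - k
  if (need <= 0) return(matrix(0, 0, 3))
  ang <- switch(hyb, sp = pi, sp2 = 2 * pi / 3, sp3 = .tet_ang)
  if (k == 0) {
    d1 <- c(1, 0, 0)
    rest <- .ideal_directions(matrix(d1, 1, 3), m, hyb, w)
    return(rbind(d1, rest)[seq_len(need), , drop = FALSE])
  }
  if (k == 1) {
    d <- placed[1, ]
    if (is.null(w)) w <- .perp(d)
    n <- .cross3(d, w)
    if (hyb == "sp") return(matrix(-d, need, 3, byrow = TRUE))
    if (hyb == "sp2") {
      # two in-plane directions at +-120 deg from d
      dirs <- rbind(cos(2 * pi / 3) * d + sin(2 * pi / 3) * w,
                    cos(2 * pi / 3) * d - sin(2 * pi / 3) * w)
      return(dirs[seq_len(need), , drop = FALSE])
    }
    # sp3: up to three directions at tetrahedral angle, azimuths 0/120/240
    az <- c(0, 2 * pi / 3, -2 * pi / 3)
    dirs <- t(vapply(az, function(p) {
      cos(ang) * d + sin(ang) * (cos(p) * w + sin(p) * n)
    }, numeric(3)))
    return(dirs[seq_len(need), , drop = FALSE])
  }
  if (k == 2) {
    b <- -.unit(placed[1, ] + placed[2, ])
    nrm <- .cross3(placed[1, ], placed[2, ])
    if (sqrt(sum(nrm^2)) < 1e-8) nrm <- .perp(placed[1, ]) else nrm <- .unit(nrm)
    if (need == 1) return(matrix(b, 1, 3))
    phi <- .tet_ang / 2
    return(rbind(cos(phi) * b + sin(phi) * nrm,
                 cos(phi) * b - sin(phi) * nrm)[seq_len(need), , drop = FALSE])
  }
  # k >= 3: single remaining tetrahedral direction
  b <- -colSums(placed)
  if (sqrt(sum(b^2)) < 1e-8) b <- .perp(placed[1, ])
  matrix(.unit(b), need, 3, byrow = TRUE)
}

.hybridization <- function(mol) {
  hyb <- rep("sp3", nrow(mol$atoms))
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      if (o >= 2) {
        for (a in c(mol$bonds$a1[k], mol$bonds$a2[k])) {
          hyb[a] <- if (o >= 3 || hyb[a] == "sp2") "sp" else "sp2"
        }
      }
    }
  }
  hyb
}

# Ring systems as simple cycles (atom index sequences in cycle order).
# Fused, bridged and spiro systems are outside the builder's scope.
.simple_rings <- function(mol) {
  gr <- .mol_graph(mol)
  is_bridge <- rep(FALSE, nrow(mol$bonds))
  is_bridge[as.integer(igraph::bridges(gr))] <- TRUE
  re <- mol$bonds[!is_bridge, ]
  if (nrow(re) == 0) return(list())
  rg <- igraph::graph_from_data_frame(
    d = data.frame(from = re$a1, to = re$a2), directed = FALSE,
    vertices = data.frame(name = sort(unique(c(re$a1, re$a2)))))
  if (any(igraph::degree(rg) != 2)) {
    abort(paste0("Molecule ", mol$id, " contains a fused, bridged or spiro ",
                 "ring system; the built-in embedder handles isolated rings only."),
          class = "fragesp_embed_unsupported")
  }
  comps <- igraph::components(rg)
  lapply(seq_len(comps$no), function(ci) {
    vs <- which(comps$membership == ci)
    sub <- igraph::induced_subgraph(rg, vs)
    ord <- as.integer(names(igraph::V(sub))[igraph::dfs(sub, root = 1)$order])
    ord
  })
}

#' Embed a molecule with idealized geometry
#'
#' Produces a single deterministic 3D conformer: rings as regular planar
#' polygons, idealized bond lengths and angles elsewhere, anti/staggered
#' default torsions. Optionally a set of atoms can be pinned to fixed
#' coordinates (the anchored-fragment case); the builder then grows the
#' rest of the molecule outward from them.
#'
#' @param mol A [mol_record()]; hydrogens are made explicit.
#' @param fixed Optional matrix of fixed coordinates with rownames giving
#'   atom indices.
#' @return A [mol_record()] with `provenance = "embedded"`.
#' @export
embed_molecule <- function(mol, fixed = NULL) {
  molh <- add_hydrogens(mol)
  n <- nrow(molh$atoms)
  rings <- .simple_rings(molh)
  ring_of <- rep(NA_integer_, n)
  for (ri in seq_along(rings)) ring_of[rings[[ri]]] <- ri
  hyb <- .hybridization(molh)
  # atoms of conjugated rings (any in-ring double bond) are planar even if
  # they carry no double bond themselves (e.g. pyrrole-type nitrogen)
  for (ring in rings) {
    s <- length(ring)
    has_double <- any(vapply(seq_len(s), function(j) {
      .bond_order_between(molh, ring[j], ring[if (j == s) 1 else j + 1]) >= 2
    }, logical(1)))
    if (has_double) hyb[ring][hyb[ring] == "sp3"] <- "sp2"
  }
  nb <- .neighbors(molh)
  deg <- lengths(nb)
  xyz <- matrix(NA_real_, n, 3)
  placed <- rep(FALSE, n)
  ring_done <- rep(FALSE, length(rings))
  el <- molh$atoms$element

  place_ring <- function(ri, entry = NA_integer_) {
    ord <- rings[[ri]]
    s <- length(ord)
    lens <- vapply(seq_len(s), function(j) {
      a <- ord[j]; b <- ord[if (j == s) 1 else j + 1]
      .bond_length(el[a], el[b], .bond_order_between(molh, a, b))
    }, numeric(1))
    L <- mean(lens)
    R <- L / (2 * sin(pi / s))
    if (!is.na(entry)) {
      ord <- c(ord[which(ord == entry):s], ord[seq_len(which(ord == entry) - 1)])
      # canonical traversal direction from graph invariants (element +
      # heavy-atom degree along the two walks), so the embedding does not
      # depend on input atom order and chemically matched rings land in
      # matched orientations
      walk_inv <- function(atoms) {
        paste(vapply(atoms, function(a) {
          sprintf("%s%d", el[a], sum(el[nb[[a]]] != "H"))
        }, character(1)), collapse = "|")
      }
      fwd <- ord[2:s]
      bwd <- rev(fwd)
      if (walk_inv(bwd) < walk_inv(fwd)) ord <- c(ord[1], bwd)
      pnb <- nb[[entry]][placed[nb[[entry]]]]
      a <- pnb[1]
      u <- .unit(xyz[entry, ] - xyz[a, ])
      center <- xyz[entry, ] + u * R
      e1 <- -u
      e2 <- .perp(u)
    } else {
      center <- c(R, 0, 0)
      e1 <- c(-1, 0, 0)
      e2 <- c(0, 1, 0)
    }
    for (j in seq_len(s)) {
      th <- (j - 1) * 2 * pi / s
      pos <- center + R * (cos(th) * e1 + sin(th) * e2)
      if (!placed[ord[j]]) {
        xyz[ord[j], ] <<- pos
        placed[ord[j]] <<- TRUE
      }
    }
    ring_done[ri] <<- TRUE
  }

  place_neighbors <- function(p) {
    un <- nb[[p]][!placed[nb[[p]]]]
    if (length(un) == 0) return(invisible())
    pd <- nb[[p]][placed[nb[[p]]]]
    placed_dirs <- if (length(pd) > 0) {
      t(vapply(pd, function(q) .unit(xyz[q, ] - xyz[p, ]), numeric(3)))
    } else matrix(0, 0, 3)
    # azimuth reference from the grandparent for anti/planar defaults
    w <- NULL
    if (length(pd) >= 1) {
      g <- pd[1]
      gg <- setdiff(nb[[g]][placed[nb[[g]]]], p)
      if (length(gg) >= 1) {
        d <- placed_dirs[1, ]
        v <- xyz[gg[1], ] - xyz[g, ]
        vperp <- v - sum(v * d) * d
        if (sqrt(sum(vperp^2)) > 1e-8) w <- -.unit(vperp)
      }
    }
    dirs <- .ideal_directions(placed_dirs, deg[p], hyb[p], w)
    # order: heavy atoms before hydrogens, then by index (deterministic)
    un <- un[order(el[un] == "H", un)]
    for (i in seq_along(un)) {
      q <- un[i]
      len <- .bond_length(el[p], el[q], .bond_order_between(molh, p, q))
      xyz[q, ] <<- xyz[p, ] + dirs[min(i, nrow(dirs)), ] * len
      placed[q] <<- TRUE
    }
  }

  queue <- integer()
  queued <- rep(FALSE, n)
  enqueue <- function(atoms) {
    fresh <- atoms[!queued[atoms]]
    queued[fresh] <<- TRUE
    queue <<- c(queue, fresh)
  }
  if (!is.null(fixed)) {
    idx <- as.integer(rownames(fixed))
    xyz[idx, ] <- as.matrix(fixed)
    placed[idx] <- TRUE
    for (ri in seq_along(rings)) if (all(placed[rings[[ri]]])) ring_done[ri] <- TRUE
    enqueue(idx)
  } else {
    root <- 1L
    if (!is.na(ring_of[root])) {
      place_ring(ring_of[root])
      enqueue(rings[[ring_of[root]]])
    } else {
      xyz[root, ] <- c(0, 0, 0)
      placed[root] <- TRUE
      enqueue(root)
    }
  }
  while (length(queue) > 0) {
    p <- queue[1]
    queue <- queue[-1]
    if (!is.na(ring_of[p]) && !ring_done[ring_of[p]]) {
      place_ring(ring_of[p], entry = p)
      enqueue(rings[[ring_of[p]]])
    }
    place_neighbors(p)
    enqueue(nb[[p]][placed[nb[[p]]]])
  }
  if (any(!placed)) {
    abort("Embedding failed to place all atoms (disconnected input?).",
          class = "fragesp_embed_error")
  }
  out <- .set_coords(molh, xyz)
  out$provenance <- "embedded"
  out
}

.bond_order_between <- function(mol, a, b) {
  hit <- (mol$bonds$a1 == a & mol$bonds$a2 == b) | (mol$bonds$a1 == b & mol$bonds$a2 == a)
  if (!any(hit)) 1L else mol$bonds$order[which(hit)[1]]
}

#' The fixed anchor template
#'
#' Reference coordinates of the methylene-hexazine anchor: linker carbon at
#' the origin, first ring nitrogen on +x, ring in the xy-plane, attachment
#' direction tetrahedral off the linker. Every anchored fragment is built
#' in this one frame, which is what makes fragment pairs comparable
#' without any molecular superposition.
#'
#' @return A list with `coords` (10 x 3 matrix: C, N1-N6, two linker H,
#'   ring NH hydrogen, in [attach_anchor()] order) and `attach_dir` (unit
#'   vector from the linker carbon toward the attachment atom).
#' @export
anchor_template <- function() {
  dCN <- .bond_length("C", "N")
  ring_orders <- c(1, 2, 1, 2, 1, 1)
  lens <- .bond_length("N", "N") * ifelse(ring_orders == 2, 0.87, 1)
  L <- mean(lens)
  R <- L / (2 * sin(pi / 6))
  center <- c(dCN + R, 0, 0)
  nring <- t(vapply(0:5, function(j) {
    th <- pi - j * (2 * pi / 6)  # clockwise so N6 sits at +60 deg
    center + R * c(cos(th), sin(th), 0)
  }, numeric(3)))
  dC <- c(1, 0, 0)  # C -> N1
  attach_dir <- cos(.tet_ang) * dC + sin(.tet_ang) * c(0, -1, 0)
  hdirs <- rbind(cos(.tet_ang) * dC + sin(.tet_ang) * (cos(2 * pi / 3) * c(0, -1, 0) + sin(2 * pi / 3) * c(0, 0, 1)),
                 cos(.tet_ang) * dC + sin(.tet_ang) * (cos(2 * pi / 3) * c(0, -1, 0) - sin(2 * pi / 3) * c(0, 0, 1)))
  hC <- hdirs * .bond_length("C", "H")
  hn_dir <- .unit(nring[6, ] - center)
  hN <- nring[6, ] + hn_dir * .bond_length("N", "H")
  coords <- rbind(c(0, 0, 0), nring, hC, hN)
  rownames(coords) <- c("C", paste0("N", 1:6), "HC1", "HC2", "HN6")
  list(coords = coords, attach_dir = attach_dir)
}

# Rotatable acyclic single bonds; bonds internal to `protect` are skipped
# and the rotating side never contains a protected atom.
.rotatable_bonds <- function(mol, protect = integer()) {
  gr <- .mol_graph(mol)
  is_bridge <- rep(FALSE, nrow(mol$bonds))
  is_bridge[as.integer(igraph::bridges(gr))] <- TRUE
  el <- mol$atoms$element
  nb <- .neighbors(mol)
  heavy_deg <- vapply(nb, function(x) sum(el[x] != "H"), integer(1))
  out <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    if (!is_bridge[k] || mol$bonds$order[k] != 1) next
    if (el[a] == "H" || el[b] == "H") next
    if (heavy_deg[a] < 2 || heavy_deg[b] < 2) next
    if (a %in% protect && b %in% protect) next
    # split: atoms on b's side when the bond is removed
    g2 <- igraph::delete_edges(gr, k)
    comp <- igraph::components(g2)$membership
    side_b <- which(comp == comp[b])
    if (length(protect) > 0 && any(protect %in% side_b)) {
      side <- setdiff(which(comp == comp[a]), a)
      axis <- c(b, a)
    } else {
      side <- setdiff(side_b, b)
      axis <- c(a, b)
    }
    if (length(side) == 0) next
    out[[length(out) + 1]] <- list(axis = axis, side = side)
  }
  out
}

.rotate_about <- function(xyz, p0, axis_dir, theta) {
  u <- .unit(axis_dir)
  ct <- cos(theta); st <- sin(theta)
  rel <- sweep(xyz, 2, p0)
  dotp <- rel %*% u
  cross <- cbind(u[2] * rel[, 3] - u[3] * rel[, 2],
                 u[3] * rel[, 1] - u[1] * rel[, 3],
                 u[1] * rel[, 2] - u[2] * rel[, 1])
  rot <- rel * ct + cross * st + (dotp %*% t(u)) * (1 - ct)
  sweep(rot, 2, p0, "+")
}

# Steric acceptability: atoms >= 3 bonds apart may not approach closer
# than half the sum of their vdW radii.
.no_clash <- function(mol, xyz, topo_dist) {
  vd <- vdw_radii(mol$atoms$element)
  far <- which(topo_dist >= 3 & upper.tri(topo_dist), arr.ind = TRUE)
  if (nrow(far) == 0) return(TRUE)
  d <- sqrt(rowSums((xyz[far[, 1], , drop = FALSE] - xyz[far[, 2], , drop = FALSE])^2))
  all(d >= 0.5 * (vd[far[, 1]] + vd[far[, 2]]))
}

#' Generate an anchored conformer ensemble
#'
#' Embeds the anchored fragment with its anchor pinned to the template
#' coordinates, then torsion-drives the rotatable bonds (multiples of 60
#' degrees, seeded sampling, clash-filtered) to give up to `max_confs`
#' conformers. The anchor atoms sit at the template coordinates exactly in
#' every conformer; rigid fragments yield exactly one conformer.
#'
#' @param anchored An anchored [mol_record()] from [attach_anchor()].
#' @param template The [anchor_template()].
#' @param max_confs Conformer cap (>= 1).
#' @param seed Integer seed for torsion sampling.
#' @return A `conformer_ensemble`: list with `mol`, `conformers` (list of
#'   coordinate matrices), `anchor`, `seed`.
#' @export
generate_anchored_conformers <- function(anchored, template = anchor_template(),
                                         max_confs = 10, seed = 1L) {
  if (length(anchored$anchor) != 10) {
    abort("Molecule is not anchored (expect 10 tagged anchor atoms).",
          class = "fragesp_anchor_error")
  }
  fixed <- template$coords
  rownames(fixed) <- as.character(anchored$anchor)
  emb <- embed_molecule(anchored, fixed = fixed)
  xyz0 <- .coords(emb)
  # the anchor and the linker-attachment bond define the fixed frame;
  # torsions are driven only within the fragment itself
  att <- setdiff(unlist(emb$bonds[emb$bonds$a1 == emb$anchor[1] |
                                    emb$bonds$a2 == emb$anchor[1], c("a1", "a2")]),
                 emb$anchor)
  rot <- .rotatable_bonds(emb, protect = c(emb$anchor, att))
  confs <- list(xyz0)
  if (length(rot) > 0 && max_confs > 1) {
    topo <- igraph::distances(.mol_graph(emb))
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    seen <- list(rep(0, length(rot)))
    tries <- 0
    while (length(confs) < max_confs && tries < 40 * max_confs) {
      tries <- tries + 1
      offs <- sample(c(0, 60, 120, 180, 240, 300), length(rot), replace = TRUE)
      if (all(offs == 0) || any(vapply(seen, function(s) all(s == offs), logical(1)))) next
      seen[[length(seen) + 1]] <- offs
      xyz <- xyz0
      for (ri in seq_along(rot)) {
        if (offs[ri] == 0) next
        ax <- rot[[ri]]$axis
        xyz[rot[[ri]]$side, ] <- .rotate_about(xyz[rot[[ri]]$side, , drop = FALSE],
                                               xyz[ax[1], ],
                                               xyz[ax[2], ] - xyz[ax[1], ],
                                               offs[ri] * pi / 180)
      }
      if (.no_clash(emb, xyz, topo)) confs[[length(confs) + 1]] <- xyz
    }
  }
  structure(list(mol = emb, conformers = confs, anchor = emb$anchor,
                 seed = as.integer(seed)),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %s: %d conformer(s), %d atoms (%d anchor), seed %d\n",
              x$mol$id, length(x$conformers), nrow(x$mol$atoms),
              length(x$anchor), x$seed))
  invisible(x)
}
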