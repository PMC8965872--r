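#' Cut a molecule into fragments at ring-adjacent single bonds
#'
#' Every acyclic single bond with at least one end atom in a ring is
#' broken (so biaryl ring-ring single bonds are cut too: both ends are
#' ring atoms). Bonds to hydrogen are never cut. Each cut leaves a labeled
#' attachment point on both resulting fragments; rejoining all fragments
#' at matched labels reproduces the parent graph. Molecules without rings
#' yield a single fragment with zero attachments (flagged).
#'
#' Fragments are heavy-atom subgraphs of the parent; hydrogens are
#' restored by capping/embedding.
#'
#' @param mol A [mol_record()].
#' @return A list of `fragment` objects. Attribute `ring_free` is TRUE
#'   when the molecule had no rings.
#' @export
fragment_molecule <- function(mol) {
  mol <- .strip_hydrogens(mol)
  gr <- .mol_graph(mol)
  bridge_eids <- igraph::bridges(gr)
  is_bridge <- rep(FALSE, nrow(mol$bonds))
  is_bridge[as.integer(bridge_eids)] <- TRUE
  ring_atom <- rep(FALSE, nrow(mol$atoms))
  if (any(!is_bridge)) {
    re <- mol$bonds[!is_bridge, ]
    ring_atom[unique(c(re$a1, re$a2))] <- TRUE
  }
  cut <- is_bridge & mol$bonds$order == 1 &
    (ring_atom[mol$bonds$a1] | ring_atom[mol$bonds$a2])
  if (!any(ring_atom)) {
    frag <- .new_fragment(mol, seq_len(nrow(mol$atoms)),
                          tibble(atom = integer(), label = integer(),
                                 partner_element = character()),
                          index = 1L)
    out <- list(frag)
    attr(out, "ring_free") <- TRUE
    return(out)
  }
  keep_bonds <- mol$bonds[!cut, ]
  gcut <- igraph::graph_from_data_frame(
    d = data.frame(from = keep_bonds$a1, to = keep_bonds$a2),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(mol$atoms))))
  comp <- igraph::components(gcut)$membership
  cut_bonds <- mol$bonds[cut, ]
  frags <- vector("list", max(comp))
  for (ci in seq_len(max(comp))) {
    idx <- which(comp == ci)
    att <- tibble(atom = integer(), label = integer(), partner_element = character())
    if (nrow(cut_bonds) > 0) {
      for (k in seq_len(nrow(cut_bonds))) {
        a <- cut_bonds$a1[k]; b <- cut_bonds$a2[k]
        if (a %in% idx) {
          att <- bind_rows(att, tibble(atom = match(a, idx), label = k,
                                       partner_element = mol$atoms$element[b]))
        }
        if (b %in% idx) {
          att <- bind_rows(att, tibble(atom = match(b, idx), label = k,
                                       partner_element = mol$atoms$element[a]))
        }
      }
    }
    frags[[ci]] <- .new_fragment(mol, idx, att, index = ci)
  }
  attr(frags, "ring_free") <- FALSE
  frags
}

# Drop explicit hydrogens (coordinates are regenerated at embedding time).
.strip_hydrogens <- function(mol) {
  keep <- which(mol$atoms$element != "H")
  if (length(keep) == nrow(mol$atoms)) return(mol)
  .subgraph_mol(mol, keep)
}

.subgraph_mol <- function(mol, idx, id = mol$id) {
  map <- match(seq_len(nrow(mol$atoms)), idx)
  keepb <- mol$bonds$a1 %in% idx & mol$bonds$a2 %in% idx
  bonds <- mol$bonds[keepb, ]
  bonds$a1 <- map[bonds$a1]; bonds$a2 <- map[bonds$a2]
  mol_record(id, mol$atoms[idx, ], bonds,
             charges = if (!is.null(mol$charges)) mol$charges[idx] else NULL,
             provenance = mol$provenance,
             anchor = as.integer(stats::na.omit(map[mol$anchor])))
}

.new_fragment <- function(parent, idx, attachments, index) {
  sub <- .subgraph_mol(parent, idx, id = sprintf("%s#%d", parent$id, index))
  frag <- structure(
    list(parent_id = parent$id, atom_indices = idx, mol = sub,
         attachments = attachments, canonical_key = NA_character_,
         cap_state = "raw"),
    class = "fragment"
  )
  frag$attachments <- .order_attachments(frag)
  frag$canonical_key <- fragment_key(frag)
  frag
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment> %s: %d heavy atoms, %d attachment(s), key %s\n",
              x$mol$id, nrow(x$mol$atoms), nrow(x$attachments), x$canonical_key))
  invisible(x)
}

# Deterministic canonical order of attachment points: sort by the canonical
# SMILES of the fragment with that attachment dummy-marked (ties between
# symmetry-equivalent attachments keep graph order, which is immaterial).
.order_attachments <- function(frag) {
  att <- frag$attachments
  if (nrow(att) <= 1) return(att)
  keys <- vapply(seq_len(nrow(att)), function(i) .attachment_key(frag, i), character(1))
  att[order(keys, att$atom), ]
}

.attachment_key <- function(frag, which_att) {
  .capped_canonical(frag, which_att, mark_primary = TRUE)
}

# Cap and canonicalize. Primary attachment is either hydrogen-capped or
# dummy-marked ([*]); all other attachments get methyl caps.
.capped_canonical <- function(frag, primary, mark_primary = FALSE) {
  m <- .cap_graph(frag, primary, primary_cap = if (mark_primary) "*" else "H")
  canonical_smiles(m)
}

# Graph-level capping: primary attachment capped with `primary_cap`
# ("H", "*", or "C" for methyl), all other attachments capped with methyl.
.cap_graph <- function(frag, primary, primary_cap = "H") {
  att <- frag$attachments
  if (nrow(att) > 0 && (primary < 1 || primary > nrow(att))) {
    abort("primary_attachment is not one of the fragment's attachment points.",
          class = "fragesp_bad_attachment")
  }
  m <- frag$mol
  if (nrow(att) > 0) {
    for (i in seq_len(nrow(att))) {
      el <- if (i == primary) primary_cap else "C"
      # "H": implicit hydrogen completes the valence; "none": left open
      # for the anchor bond.
      if (el %in% c("H", "none")) next
      m$atoms <- bind_rows(m$atoms, tibble(element = el, x = 0, y = 0, z = 0,
                                           formal_charge = 0L))
      m$bonds <- bind_rows(m$bonds, tibble(a1 = att$atom[i], a2 = nrow(m$atoms),
                                           order = 1L))
    }
  }
  m
}

#' Canonical key of a fragment
#'
#' Canonical SMILES of the capped fragment with the primary attachment
#' marked by a dummy atom (`*`) and any other attachments methyl-capped.
#' The dummy keeps positional isomers (e.g. attachment at ring position 3
#' vs 4) distinct; the key is invariant under input atom permutations.
#'
#' @param frag A `fragment`.
#' @param primary Primary attachment index (default 1, the canonical-order
#'   first).
#' @return A canonical SMILES string.
#' @export
fragment_key <- function(frag, primary = 1L) {
  if (nrow(frag$attachments) == 0) return(canonical_smiles(frag$mol))
  .capped_canonical(frag, primary, mark_primary = TRUE)
}

#' Cap a fragment for charging and comparison
#'
#' The primary attachment is capped with hydrogen (the anchor's place after
#' removal); every other attachment gets a methyl cap, which is neutral in
#' electrostatic terms. Explicit hydrogens are added.
#'
#' @param frag A `fragment`.
#' @param primary_attachment Index into the fragment's (canonically
#'   ordered) attachment list.
#' @return A [mol_record()] of the capped fragment (`cap_state` attribute
#'   `"h_capped"`).
#' @export
cap_fragment <- function(frag, primary_attachment = 1L) {
  m <- .cap_graph(frag, primary_attachment, primary_cap = "H")
  m <- add_hydrogens(m)
  .check_valences(m)
  attr(m, "cap_state") <- "h_capped"
  m
}

.check_valences <- function(mol) {
  bo <- .bond_order_sums(mol)
  el <- mol$atoms$element
  limit <- .default_valence[el] + abs(mol$atoms$formal_charge)
  over <- which(bo > limit + 1e-9)
  if (length(over) > 0) {
    abort(sprintf("Valence violation at atom %d (%s).", over[1], el[over[1]]),
          class = "fragesp_valence_error")
  }
  invisible(mol)
}

# Detect a six-membered all-nitrogen ring (the anchor motif).
.has_hexazine <- function(mol) {
  n_idx <- which(mol$atoms$element == "N")
  if (length(n_idx) < 6) return(FALSE)
  sub_bonds <- mol$bonds[mol$bonds$a1 %in% n_idx & mol$bonds$a2 %in% n_idx, ]
  if (nrow(sub_bonds) < 6) return(FALSE)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = match(sub_bonds$a1, n_idx), to = match(sub_bonds$a2, n_idx)),
    directed = FALSE, vertices = data.frame(name = seq_along(n_idx)))
  comp <- igraph::components(g)
  any(tapply(igraph::degree(g), comp$membership, function(d) length(d) == 6 && all(d >= 2)))
}

#' Attach the rigid alignment anchor to a fragment
#'
#' Bonds a methylene-hexazine group (CH2 linked to a six-nitrogen ring) to
#' the primary attachment atom and methyl-caps all other attachments. The
#' anchor atoms (carbon, six nitrogens, their three hydrogens) are tagged
#' for later removal; because hexazines never occur in drug-like inputs
#' the tag can always be re-derived unambiguously. Inputs that already
#' contain a hexazine are rejected (removal would be ambiguous).
#'
#' @param frag A `fragment` with at least one attachment point.
#' @param primary_attachment Attachment index to carry the anchor.
#' @return A [mol_record()] with explicit hydrogens and `anchor` indices
#'   set (`cap_state` attribute `"anchored"`).
#' @export
attach_anchor <- function(frag, primary_attachment = 1L) {
  if (nrow(frag$attachments) == 0) {
    abort("Fragment has no attachment point to anchor.", class = "fragesp_bad_attachment")
  }
  if (.has_hexazine(frag$mol)) {
    abort("Input already contains a hexazine ring; anchor removal would be ambiguous.",
          class = "fragesp_anchor_clash")
  }
  m <- .cap_graph(frag, primary_attachment, primary_cap = "none")
  att_atom <- frag$attachments$atom[primary_attachment]
  n0 <- nrow(m$atoms)
  # anchor atoms: C (linker), N1..N6, H,H on C, H on N6
  anchor_atoms <- tibble(
    element = c("C", rep("N", 6), "H", "H", "H"),
    x = 0, y = 0, z = 0, formal_charge = 0L
  )
  m$atoms <- bind_rows(m$atoms, anchor_atoms)
  ai <- n0 + 1:10  # C=n0+1, N1..N6=n0+2..n0+7, H...
  ring_orders <- c(1L, 2L, 1L, 2L, 1L, 1L)  # N1-N2, N2=N3, ..., N6-N1
  anchor_bonds <- tibble(
    a1 = c(att_atom, ai[1], ai[2:6], ai[7], ai[1], ai[1], ai[7]),
    a2 = c(ai[1], ai[2], ai[3:7], ai[2], ai[8], ai[9], ai[10]),
    order = c(1L, 1L, ring_orders[1:5], ring_orders[6], 1L, 1L, 1L)
  )
  m$bonds <- bind_rows(m$bonds, anchor_bonds)
  m$anchor <- ai
  m <- add_hydrogens(m)
  .check_valences(m)
  attr(m, "cap_state") <- "anchored"
  m
}

#' Remove the anchor from an anchored conformer
#'
#' Deletes the tagged anchor atoms and caps the attachment atom with a
#' hydrogen placed along the former linker-bond direction. Coordinates of
#' all surviving atoms are untouched, so the alignment frame is preserved
#' bit-exactly.
#'
#' @param mol An anchored [mol_record()] (with `anchor` indices and 3D
#'   coordinates).
#' @return A hydrogen-capped [mol_record()] without the anchor.
#' @export
remove_anchor <- function(mol) {
  if (length(mol$anchor) == 0) {
    abort("Molecule carries no anchor tag.", class = "fragesp_anchor_error")
  }
  ai <- mol$anchor
  linker_c <- ai[1]
  att <- setdiff(unlist(mol$bonds[mol$bonds$a1 == linker_c | mol$bonds$a2 == linker_c,
                                  c("a1", "a2")]),
                 c(ai))
  stopifnot(length(att) == 1)
  keep <- setdiff(seq_len(nrow(mol$atoms)), ai)
  xyz_att <- unlist(mol$atoms[att, c("x", "y", "z")])
  xyz_c <- unlist(mol$atoms[linker_c, c("x", "y", "z")])
  u <- xyz_c - xyz_att
  u <- u / sqrt(sum(u^2))
  hlen <- .bond_length(mol$atoms$element[att], "H")
  out <- .subgraph_mol(mol, keep)
  att_new <- match(att, keep)
  out$atoms <- bind_rows(out$atoms, tibble(
    element = "H",
    x = xyz_att[1] + hlen * u[1], y = xyz_att[2] + hlen * u[2],
    z = xyz_att[3] + hlen * u[3], formal_charge = 0L
  ))
  out$bonds <- bind_rows(out$bonds, tibble(a1 = att_new, a2 = nrow(out$atoms),
                                           order = 1L))
  out$anchor <- integer()
  attr(out, "cap_state") <- "h_capped"
  out
}

#' Reassemble fragments into their parent graph
#'
#' Joins fragments at matched attachment labels with single bonds; used to
#' verify that fragmentation conserves the parent structure and to decode
#' generated fragment combinations.
#'
#' @param frags List of `fragment` objects sharing a label space.
#' @param id Identifier for the rebuilt molecule.
#' @return A [mol_record()] of the rebuilt heavy-atom graph.
#' @export
reassemble_fragments <- function(frags, id = "reassembled") {
  atoms <- tibble(); bonds <- tibble(); offset <- 0L
  joins <- list()
  for (f in frags) {
    m <- f$mol
    atoms <- bind_rows(atoms, m$atoms)
    if (nrow(m$bonds) > 0) {
      bonds <- bind_rows(bonds, mutate(m$bonds, a1 = .data$a1 + offset,
                                       a2 = .data$a2 + offset))
    }
    if (nrow(f$attachments) > 0) {
      for (i in seq_len(nrow(f$attachments))) {
        lbl <- as.character(f$attachments$label[i])
        joins[[lbl]] <- c(joins[[lbl]], f$attachments$atom[i] + offset)
      }
    }
    offset <- offset + nrow(m$atoms)
  }
  for (lbl in names(joins)) {
    pair <- joins[[lbl]]
    if (length(pair) != 2) {
      abort(sprintf("Attachment label %s matched %d atoms (need exactly 2).",
                    lbl, length(pair)),
            class = "fragesp_bad_attachment")
    }
    bonds <- bind_rows(bonds, tibble(a1 = pair[1], a2 = pair[2], order = 1L))
  }
  mol_record(id, atoms, bonds, provenance = "input_2d")
}
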