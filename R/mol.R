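#' Molecule records
#'
#' A `mol_record` is the package's lightweight molecular container: an atom
#' table (element, xyz position in angstrom, formal charge), a bond table
#' (atom indices and integer bond order), optional per-atom partial charges
#' (elementary charge units), and a provenance flag saying whether the
#' coordinates came from a 3D input file, a 2D input (no usable geometry),
#' or the package's own embedder.
#'
#' @param id Molecule identifier.
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `formal_charge` (defaults to 0).
#' @param bonds Data frame with columns `a1`, `a2`, `order`.
#' @param charges Optional numeric vector of per-atom partial charges (e).
#' @param provenance One of `"input_2d"`, `"input_3d"`, `"embedded"`.
#' @param anchor Integer indices of anchor atoms (used by the alignment
#'   pipeline), empty for ordinary molecules.
#' @return A `mol_record` object.
#' @export
mol_record <- function(id, atoms, bonds, charges = NULL,
                       provenance = c("input_2d", "input_3d", "embedded"),
                       anchor = integer()) {
  provenance <- match.arg(provenance)
  atoms <- as_tibble(atoms)
  if (!"formal_charge" %in% names(atoms)) atoms$formal_charge <- 0L
  atoms <- atoms[, c("element", "x", "y", "z", "formal_charge")]
  bonds <- as_tibble(bonds)
  if (nrow(bonds) == 0) {
    bonds <- tibble(a1 = integer(), a2 = integer(), order = integer())
  }
  bonds <- bonds[, c("a1", "a2", "order")]
  mol <- structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds,
         charges = charges, provenance = provenance,
         anchor = as.integer(anchor)),
    class = "mol_record"
  )
  validate_mol_record(mol)
}

validate_mol_record <- function(mol) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  if (nrow(atoms) == 0) abort("Molecule has no atoms.", class = "fragesp_empty_molecule")
  bad_el <- setdiff(unique(atoms$element), .known_elements)
  if (length(bad_el) > 0) {
    abort(paste0("Unsupported element symbol(s): ", paste(bad_el, collapse = ", ")),
          class = "fragesp_unsupported_element")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("Non-finite atom coordinates.", class = "fragesp_bad_geometry")
  }
  if (nrow(bonds) > 0) {
    idx <- c(bonds$a1, bonds$a2)
    if (any(idx < 1 | idx > nrow(atoms))) {
      abort("Bond indices out of range.", class = "fragesp_bad_bond")
    }
    if (any(bonds$a1 == bonds$a2)) abort("Self-bond.", class = "fragesp_bad_bond")
  }
  if (!is.null(mol$charges) && length(mol$charges) != nrow(atoms)) {
    abort("Partial charge vector length does not match atom count.",
          class = "fragesp_charge_mismatch")
  }
  mol
}

#' @export
print.mol_record <- function(x, ...) {
  nh <- sum(x$atoms$element != "H")
  cat(sprintf("<mol_record> %s: %d atoms (%d heavy), %d bonds, %s%s%s\n",
              x$id, nrow(x$atoms), nh, nrow(x$bonds), x$provenance,
              if (!is.null(x$charges)) ", charged" else "",
              if (length(x$anchor) > 0) sprintf(", %d anchor atoms", length(x$anchor)) else ""))
  invisible(x)
}

#' @export
as_tibble.mol_record <- function(x, ...) {
  out <- x$atoms
  out$atom <- seq_len(nrow(out))
  if (!is.null(x$charges)) out$charge <- x$charges
  out[, c("atom", setdiff(names(out), "atom"))]
}

#' Number of atoms in a molecule record
#' @param mol A `mol_record`.
#' @param heavy_only Count only non-hydrogen atoms?
#' @return Integer count.
#' @export
n_atoms <- function(mol, heavy_only = FALSE) {
  stopifnot(inherits(mol, "mol_record"))
  if (heavy_only) sum(mol$atoms$element != "H") else nrow(mol$atoms)
}

# Sum of formal charges: the neutrality target for charge assignment.
formal_charge_total <- function(mol) sum(mol$atoms$formal_charge)

# Bond-order sum per atom (explicit bonds only).
.bond_order_sums <- function(mol) {
  s <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$a1[k]] <- s[mol$bonds$a1[k]] + mol$bonds$order[k]
      s[mol$bonds$a2[k]] <- s[mol$bonds$a2[k]] + mol$bonds$order[k]
    }
  }
  s
}

# Number of implicit hydrogens each atom would carry to reach its default
# valence (adjusted by formal charge in the usual organic-chemistry way).
.implicit_h_counts <- function(mol) {
  bo <- .bond_order_sums(mol)
  el <- mol$atoms$element
  fc <- mol$atoms$formal_charge
  target <- .default_valence[el] + ifelse(el %in% c("N", "P"), fc,
                                          ifelse(el %in% c("O", "S"), fc, 0))
  pmax(0, round(target - bo))
}

#' Add explicit hydrogens to a molecule graph
#'
#' Completes each heavy atom to its default valence with explicit hydrogen
#' atoms. Positions of the added hydrogens are meaningful only after
#' embedding; on unembedded records they are placed at the parent atom.
#'
#' @param mol A `mol_record`.
#' @return A `mol_record` with explicit hydrogens.
#' @export
add_hydrogens <- function(mol) {
  nh <- .implicit_h_counts(mol)
  nh[mol$atoms$element == "H"] <- 0
  if (all(nh == 0)) return(mol)
  atoms <- mol$atoms
  bonds <- mol$bonds
  for (i in which(nh > 0)) {
    for (k in seq_len(nh[i])) {
      atoms <- bind_rows(atoms, tibble(
        element = "H", x = atoms$x[i], y = atoms$y[i], z = atoms$z[i],
        formal_charge = 0L
      ))
      bonds <- bind_rows(bonds, tibble(a1 = i, a2 = nrow(atoms), order = 1L))
    }
  }
  mol_record(mol$id, atoms, bonds, charges = NULL,
             provenance = mol$provenance, anchor = mol$anchor)
}

# Neighbor list (adjacency) as a list of integer vectors.
.neighbors <- function(mol) {
  nb <- vector("list", nrow(mol$atoms))
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

# igraph view of the molecular graph (atoms as vertices).
.mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    d = data.frame(from = mol$bonds$a1, to = mol$bonds$a2),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms)))
  )
}

# Multiset of heavy-element symbols, sorted (conservation checks).
heavy_atom_multiset <- function(mol) sort(mol$atoms$element[mol$atoms$element != "H"])

# Extract coordinates as an n x 3 matrix.
.coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

.set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}
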