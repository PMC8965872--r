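# All calls into OpenBabel (via ChemmineR/ChemmineOB and the obabel CLI)
# are concentrated here: SMILES parsing, canonical SMILES, 2D descriptors,
# fingerprints, and Gasteiger/MMFF94 partial charges.

#' Build a molecule record from a SMILES string
#'
#' Parses with OpenBabel (through ChemmineR). The resulting record has no
#' geometry (`provenance = "input_2d"`); use [embed_molecule()] to obtain
#' 3D coordinates. Hydrogens stay implicit until [add_hydrogens()].
#'
#' @param smiles A single SMILES string.
#' @param id Molecule identifier.
#' @return A [mol_record()].
#' @export
#' @examples
#' mol_from_smiles("c1ccccc1", "benzene")
mol_from_smiles <- function(smiles, id = "mol") {
  stopifnot(length(smiles) == 1)
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) abort(paste0("Unparseable SMILES: ", smiles),
                              class = "fragesp_parse_error")
  )
  mol <- if (suppressWarnings(ChemmineR::validSDF(sdfset))[1]) {
    .sdf_to_mol(sdfset[[1]], id = id, provenance = "input_2d")
  } else {
    # bondless (single heavy atom) records are rejected by the SDF reader;
    # fall back to reading the atom lines of the converted V2000 text
    .mol_from_v2000_text(
      tryCatch(ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
               error = function(e) ""),
      id = id
    )
  }
  # OpenBabel writes 2D layout coordinates; they carry no shape information.
  mol$atoms$x <- 0; mol$atoms$y <- 0; mol$atoms$z <- 0
  mol
}

# Minimal V2000 atom/bond block reader for the degenerate records the
# SDF parser refuses (zero bonds).
.mol_from_v2000_text <- function(txt, id) {
  lines <- strsplit(txt, "\n")[[1]]
  if (length(lines) < 4) abort("Unparseable SMILES.", class = "fragesp_parse_error")
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) abort("Unparseable SMILES.", class = "fragesp_parse_error")
  atoms <- do.call(rbind, lapply(lines[4 + seq_len(na)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    data.frame(element = f[4], x = as.numeric(f[1]), y = as.numeric(f[2]),
               z = as.numeric(f[3]), formal_charge = 0L)
  }))
  bonds <- if (nb > 0) {
    do.call(rbind, lapply(lines[4 + na + seq_len(nb)], function(l) {
      data.frame(a1 = as.integer(substr(l, 1, 3)), a2 = as.integer(substr(l, 4, 6)),
                 order = as.integer(substr(l, 7, 9)))
    }))
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  mol_record(id, atoms, bonds, provenance = "input_2d")
}

#' Canonical SMILES of a molecule record
#'
#' @param mol A [mol_record()], or a character SMILES string.
#' @return Canonical SMILES string, or `NA_character_` when OpenBabel cannot
#'   interpret the structure (used as a validity probe).
#' @export
canonical_smiles <- function(mol) {
  txt <- if (is.character(mol)) {
    tryCatch(ChemmineOB::convertFormat("SMI", "CAN", paste0(mol, "\n")),
             error = function(e) "")
  } else {
    tryCatch(ChemmineOB::convertFormat("SDF", "CAN", .mol_to_sdf_text(mol)),
             error = function(e) "")
  }
  smi <- strsplit(trimws(txt), "[\t\n ]")[[1]][1]
  if (is.na(smi) || !nzchar(smi)) NA_character_ else smi
}

#' Topological 2D descriptors of a molecule
#'
#' Molecular weight (Da), an atom-contribution (Wildman-Crippen type) logP,
#' and Ertl topological polar surface area (angstrom^2), all computed by
#' OpenBabel from the molecular graph.
#'
#' @param mol A [mol_record()] or SMILES string.
#' @return A tibble with columns `mw`, `clogp`, `psa`.
#' @export
mol_properties <- function(mol) {
  ref <- if (is.character(mol)) {
    ChemmineOB::forEachMol("SMILES", paste0(mol, "\n"), identity)[[1]]
  } else {
    ChemmineOB::forEachMol("SDF", .mol_to_sdf_text(mol), identity)[[1]]
  }
  p <- ChemmineOB::prop_OB(ref)
  tibble(mw = p$MW, clogp = p$logP, psa = p$TPSA)
}

# Tanimoto similarity matrix of FP2 path fingerprints (OpenBabel).
.fp2_similarity_matrix <- function(smiles) {
  sdfset <- ChemmineR::smiles2sdf(stats::setNames(smiles, paste0("m", seq_along(smiles))))
  fp <- ChemmineR::fingerprintOB(sdfset, "FP2")
  n <- length(smiles)
  out <- vapply(seq_len(n), function(i) {
    unname(ChemmineR::fpSim(fp[i], fp, method = "Tanimoto", sorted = FALSE))
  }, numeric(n))
  diag(out) <- 1
  (out + t(out)) / 2
}

# Partial charges from the obabel CLI (mol2 output carries the charge
# column). The molecule must already have explicit hydrogens; atom order is
# preserved by OpenBabel's sdf -> mol2 conversion.
.obabel_charges <- function(mol, model = c("gasteiger", "mmff94")) {
  model <- match.arg(model)
  fin <- tempfile(fileext = ".sdf")
  on.exit(unlink(fin))
  write_molecules(list(mol), fin)
  out <- suppressWarnings(
    system2("obabel", c(fin, "-omol2", "--partialcharge", model),
            stdout = TRUE, stderr = FALSE)
  )
  atom_start <- grep("@<TRIPOS>ATOM", out, fixed = TRUE)
  sections <- grep("@<TRIPOS>", out, fixed = TRUE)
  atom_end <- suppressWarnings(min(sections[sections > atom_start]))
  if (length(atom_start) != 1 || !is.finite(atom_end)) {
    abort(sprintf("obabel failed to assign %s charges for molecule %s.",
                  model, mol$id),
          class = "fragesp_charge_error")
  }
  rows <- out[(atom_start + 1):(atom_end - 1)]
  q <- as.numeric(vapply(strsplit(trimws(rows), "\\s+"),
                         function(f) f[length(f)], character(1)))
  if (length(q) != nrow(mol$atoms) || any(is.na(q))) {
    abort(sprintf("Charge/atom misalignment from obabel for molecule %s.", mol$id),
          class = "fragesp_charge_error")
  }
  q
}
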