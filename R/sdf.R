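# Conversion between mol_record and ChemmineR SDF objects; all SDF/SMILES
# file handling goes through ChemmineR/ChemmineOB (OpenBabel).

# V2000 charge code <-> formal charge (code 4, the radical flag, maps to 0).
.charge_from_code <- function(code) {
  ifelse(code %in% c(1, 2, 3, 5, 6, 7), 4 - code, 0)
}
.code_from_charge <- function(q) ifelse(q == 0, 0, 4 - q)

.sdf_to_mol <- function(sdf, id, provenance = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  atoms <- tibble(
    element = elements,
    x = unname(ab[, 1]), y = unname(ab[, 2]), z = unname(ab[, 3]),
    formal_charge = as.integer(.charge_from_code(unname(ab[, "C6"])))
  )
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    tibble(a1 = integer(), a2 = integer(), order = integer())
  } else {
    tibble(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
           order = as.integer(bb[, 3]))
  }
  if (is.null(provenance)) {
    provenance <- if (all(atoms$z == 0)) "input_2d" else "input_3d"
  }
  mol_record(id, atoms, bonds, provenance = provenance)
}

.mol_to_sdf <- function(mol) {
  n <- nrow(mol$atoms)
  ab <- matrix(0, nrow = n, ncol = 15,
               dimnames = list(
                 paste(mol$atoms$element, seq_len(n), sep = "_"),
                 c("C1", "C2", "C3", "C5", "C6", "C7", "C8", "C9", "C10",
                   "C11", "C12", "C13", "C14", "C15", "C16")
               ))
  # V2000 atom lines carry 4 decimals in 10-char fields; rounding here keeps
  # the writer's columns aligned for any coordinate magnitude
  ab[, 1] <- round(mol$atoms$x, 4); ab[, 2] <- round(mol$atoms$y, 4)
  ab[, 3] <- round(mol$atoms$z, 4)
  ab[, "C6"] <- .code_from_charge(mol$atoms$formal_charge)
  nb <- nrow(mol$bonds)
  bb <- matrix(0, nrow = nb, ncol = 7,
               dimnames = list(if (nb > 0) seq_len(nb) else NULL,
                               c("C1", "C2", "C3", "C4", "C5", "C6", "C7")))
  if (nb > 0) {
    bb[, 1] <- mol$bonds$a1; bb[, 2] <- mol$bonds$a2; bb[, 3] <- mol$bonds$order
  }
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  methods::new("SDF",
               header = c(Molecule_Name = mol$id, Source = " fragesp",
                          Comment = "", Counts_Line = counts),
               atomblock = ab, bondblock = bb, datablock = character(0))
}

.mols_to_sdfset <- function(mols) {
  sdfs <- lapply(mols, .mol_to_sdf)
  names(sdfs) <- vapply(mols, function(m) m$id, character(1))
  methods::new("SDFset", SDF = sdfs, ID = names(sdfs))
}

# Single-molecule SDF text block (V2000), used when piping to OpenBabel.
.mol_to_sdf_text <- function(mol) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  ChemmineR::write.SDF(.mols_to_sdfset(list(mol)), tf)
  # trailing newline: OpenBabel's SDF reader wants a terminated record
  paste0(paste(readLines(tf), collapse = "\n"), "\n")
}

#' Read molecules from a SMILES or SDF file
#'
#' SMILES files hold one molecule per line with an optional whitespace
#' separated name; records that fail to parse are reported (with their line
#' or record index) and skipped, never silently dropped. SDF files keep
#' their 3D coordinates; SMILES records carry no geometry and are flagged
#' `input_2d` until embedded.
#'
#' @param path Input file path.
#' @param format `"smiles"` or `"sdf"`.
#' @return A list of [mol_record()] objects, with an attribute `failures`:
#'   a tibble of (index, input, reason) for unparseable records.
#' @export
read_molecules <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "fragesp_io_error")
  }
  mols <- list()
  failures <- tibble(index = integer(), input = character(), reason = character())
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (i in seq_along(lines)) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      smi <- parts[1]
      nm <- if (length(parts) > 1) paste(parts[-1], collapse = "_") else paste0("mol_", i)
      m <- tryCatch(mol_from_smiles(smi, id = nm), error = function(e) e)
      if (inherits(m, "error")) {
        failures <- bind_rows(failures, tibble(index = i, input = lines[i],
                                               reason = conditionMessage(m)))
      } else {
        mols[[length(mols) + 1]] <- m
      }
    }
  } else {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    valid <- ChemmineR::validSDF(sdfset)
    for (i in seq_along(sdfset)) {
      if (!valid[i]) {
        failures <- bind_rows(failures, tibble(index = i, input = paste0("record ", i),
                                               reason = "invalid SDF record"))
        next
      }
      sdf <- sdfset[[i]]
      nm <- unname(ChemmineR::header(sdf)["Molecule_Name"])
      if (!nzchar(nm)) nm <- paste0("mol_", i)
      m <- tryCatch(.sdf_to_mol(sdf, id = nm), error = function(e) e)
      if (inherits(m, "error")) {
        failures <- bind_rows(failures, tibble(index = i, input = nm,
                                               reason = conditionMessage(m)))
      } else {
        mols[[length(mols) + 1]] <- m
      }
    }
  }
  if (length(mols) == 0) {
    abort("No valid molecule records in file.", class = "fragesp_io_error")
  }
  if (nrow(failures) > 0) {
    warn(sprintf("%d record(s) failed to parse (see attr(, 'failures')).", nrow(failures)))
  }
  attr(mols, "failures") <- failures
  mols
}

#' Write molecules to an SDF file
#'
#' @param mols A list of [mol_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(mols, path) {
  if (inherits(mols, "mol_record")) mols <- list(mols)
  ChemmineR::write.SDF(.mols_to_sdfset(mols), path)
  invisible(path)
}

#' Read a per-atom partial charge file
#'
#' Plain whitespace- or comma-separated numbers, one value per atom in the
#' atom order of the paired molecule file. A length mismatch is a hard
#' error: misaligned charges silently corrupt every downstream ESP value.
#'
#' @param path Charge file path.
#' @param n_atoms Expected number of atoms.
#' @return Numeric vector of length `n_atoms` (elementary charges).
#' @export
read_charges <- function(path, n_atoms) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "fragesp_io_error")
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  txt <- gsub(",", " ", txt)
  vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1]]))
  if (any(is.na(vals))) {
    abort("Charge file contains non-numeric entries.", class = "fragesp_io_error")
  }
  if (length(vals) != n_atoms) {
    abort(sprintf("Charge file has %d values but the molecule has %d atoms.",
                  length(vals), n_atoms),
          class = "fragesp_charge_mismatch")
  }
  vals
}

#' Write a per-atom partial charge file
#' @param charges Numeric vector of partial charges (e).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_charges <- function(charges, path) {
  writeLines(format(charges, digits = 17, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}
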