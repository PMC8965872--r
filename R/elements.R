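# Element tables used across the package. Radii in angstrom.

# Bondi van der Waals radii; bromine pinned to 1.8 (GAMESS/Merz-Kollman-Singh
# convention for ESP work rather than Bondi's 1.85).
.bondi_vdw <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.80, I = 1.98
)

# Covalent radii (Cordero 2008), used for idealized bond lengths and clash
# screening in the built-in embedder.
.covalent_radius <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

# Default valence of the neutral atom (bond-order sum including H).
# "*" is the dummy atom used to mark attachment points in canonical keys;
# it is never embedded or charged.
.default_valence <- c(
  H = 1, C = 4, N = 3, O = 2, F = 1,
  P = 3, S = 2, Cl = 1, Br = 1, I = 1, `*` = 1
)

.known_elements <- names(.default_valence)

#' Van der Waals radii for a vector of element symbols
#'
#' Bondi radii for the light elements handled by the package, with the
#' bromine radius set to 1.8 angstrom (the convention used when bromine
#' appears in ESP work parametrized only up to argon).
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of radii in angstrom.
#' @export
#' @examples
#' vdw_radii(c("C", "H", "Br"))
vdw_radii <- function(elements) {
  unknown <- setdiff(unique(elements), names(.bondi_vdw))
  if (length(unknown) > 0) {
    abort(
      paste0("No van der Waals radius tabulated for element(s): ",
             paste(unknown, collapse = ", ")),
      class = "fragesp_unsupported_element"
    )
  }
  unname(.bondi_vdw[elements])
}

# Idealized length of a bond between two elements: sum of covalent radii,
# shortened slightly for double/triple bonds.
.bond_length <- function(el1, el2, order = 1) {
  len <- .covalent_radius[[el1]] + .covalent_radius[[el2]]
  len * c(`1` = 1, `2` = 0.87, `3` = 0.78)[[as.character(min(order, 3))]]
}
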