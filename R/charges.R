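#' Assign partial charges to a molecule
#'
#' Explicit hydrogens are always added before charging (the potential near
#' polar hydrogens dominates hydrogen-bond electrostatics) and the returned
#' record keeps them. Gasteiger and MMFF94 charges come from OpenBabel;
#' `"user"` attaches a supplied vector verbatim. The quantum and ML
#' backends (`"resp"`, `"am1bcc"`, `"ml"`) are declared extension points
#' and signal a clear not-implemented error - user-supplied charges stand
#' in for them.
#'
#' @param mol A [mol_record()].
#' @param method Charge model.
#' @param user_charges Numeric vector (e), required for `method = "user"`;
#'   must match the atom count of the hydrogen-complete molecule.
#' @return A `charge_assignment`: list with `method`, `charges`,
#'   `total_charge`, and `mol` (the hydrogen-complete record carrying the
#'   charges).
#' @export
#' @examples
#' \dontrun{
#' assign_charges(mol_from_smiles("C", "methane"), "gasteiger")
#' }
assign_charges <- function(mol,
                           method = c("gasteiger", "mmff94", "user",
                                      "resp", "am1bcc", "ml"),
                           user_charges = NULL) {
  method <- match.arg(method)
  if (method %in% c("resp", "am1bcc", "ml")) {
    abort(sprintf(paste0("Charge backend '%s' is not implemented in this ",
                         "package; supply charges via method = 'user'."), method),
          class = "fragesp_not_implemented")
  }
  molh <- add_hydrogens(mol)
  q <- switch(method,
    gasteiger = .obabel_charges(molh, "gasteiger"),
    mmff94 = .obabel_charges(molh, "mmff94"),
    user = {
      if (is.null(user_charges)) {
        abort("method = 'user' requires user_charges.", class = "fragesp_charge_error")
      }
      if (length(user_charges) != nrow(molh$atoms)) {
        abort(sprintf("user_charges has %d values but the molecule has %d atoms (with explicit H).",
                      length(user_charges), nrow(molh$atoms)),
              class = "fragesp_charge_mismatch")
      }
      as.numeric(user_charges)
    }
  )
  target <- formal_charge_total(molh)
  if (method != "user" && abs(sum(q) - target) > 1e-3) {
    warn(sprintf("Charge sum %.4f deviates from formal charge %d for %s.",
                 sum(q), target, mol$id))
  }
  molh$charges <- q
  structure(list(method = method, charges = q, total_charge = sum(q), mol = molh),
            class = "charge_assignment")
}

#' @export
print.charge_assignment <- function(x, ...) {
  cat(sprintf("<charge_assignment> %s: %d charges, total %+0.4f e\n",
              x$method, length(x$charges), x$total_charge))
  invisible(x)
}

#' Mean absolute deviation between two charge vectors
#'
#' The per-atom comparison used to contrast charge models: the mean of the
#' absolute elementwise differences. Hydrogens are included (they carry the
#' charge that dominates the potential at hydrogen-bonding distances).
#'
#' @param q_a,q_b Equal-length numeric vectors of partial charges (e).
#' @return A single non-negative number (e).
#' @export
#' @examples
#' charge_mae(c(0, 0), c(1, -1))
charge_mae <- function(q_a, q_b) {
  if (length(q_a) != length(q_b)) {
    abort("Charge vectors differ in length.", class = "fragesp_charge_mismatch")
  }
  mean(abs(q_a - q_b))
}
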