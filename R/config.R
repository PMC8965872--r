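#' Run configuration
#'
#' Bundles every tunable of the similarity and generation pipelines. All
#' randomness anywhere in the package flows from the single `seed` here.
#'
#' @param charge_method Partial charge backend: `"gasteiger"` (default),
#'   `"mmff94"`, `"user"`, or one of the declared-but-unimplemented
#'   quantum/ML backends (`"resp"`, `"am1bcc"`, `"ml"`).
#' @param integrator ESP overlap integrator: `"gaussian_fit"` (analytic,
#'   default) or `"monte_carlo"`.
#' @param metric ESP similarity metric: `"tanimoto"` (default) or `"carbo"`.
#' @param renormalize Map raw metrics onto `[0, 1]`? Raw values are the
#'   library default; the generator and the combo score renormalize.
#' @param mc_samples Monte Carlo sample count (default 10000).
#' @param mc_margin Outer integration margin beyond the vdW surface, in
#'   angstrom (default 4).
#' @param max_conformers Conformer cap per fragment (default 10).
#' @param seed Integer seed for every stochastic step.
#' @param property_ranges A [reward_spec()].
#' @param epochs Training epochs for the generator (default 60).
#' @param episodes_per_epoch Episodes sampled per epoch (default 200).
#' @return A `run_config` object (a named list).
#' @export
run_config <- function(charge_method = "gasteiger",
                       integrator = c("gaussian_fit", "monte_carlo"),
                       metric = c("tanimoto", "carbo"),
                       renormalize = FALSE,
                       mc_samples = 10000,
                       mc_margin = 4,
                       max_conformers = 10,
                       seed = 1L,
                       property_ranges = reward_spec(),
                       epochs = 60,
                       episodes_per_epoch = 200) {
  integrator <- match.arg(integrator)
  metric <- match.arg(metric)
  charge_method <- match.arg(charge_method,
                             c("gasteiger", "mmff94", "user", "resp", "am1bcc", "ml"))
  stopifnot(mc_margin > 0, max_conformers >= 1, mc_samples >= 100, epochs >= 0)
  structure(
    list(charge_method = charge_method, integrator = integrator,
         metric = metric, renormalize = isTRUE(renormalize),
         mc_samples = as.integer(mc_samples), mc_margin = mc_margin,
         max_conformers = as.integer(max_conformers), seed = as.integer(seed),
         property_ranges = property_ranges, epochs = as.integer(epochs),
         episodes_per_epoch = as.integer(episodes_per_epoch)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in setdiff(names(x), "property_ranges")) {
    cat(sprintf("  %-18s %s\n", nm, as.character(x[[nm]])))
  }
  r <- x$property_ranges
  cat(sprintf("  property_ranges    MW [%g, %g]  clogP [%g, %g]  PSA [%g, %g]\n",
              r$mw_range[1], r$mw_range[2], r$clogp_range[1], r$clogp_range[2],
              r$psa_range[1], r$psa_range[2]))
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error.
#' `property_ranges` may be a mapping with `mw`, `clogp`, `psa` two-element
#' ranges. Values supplied in `overrides` (e.g. parsed CLI flags) take
#' precedence over the file.
#'
#' @param path YAML file path (optional; `NULL` for pure defaults).
#' @param overrides Named list of overriding values.
#' @return A [run_config()].
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("Config file not found: ", path),
                                  class = "fragesp_io_error")
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown configuration key(s): ", paste(bad, collapse = ", ")),
          class = "fragesp_config_error")
  }
  if (!is.null(vals$property_ranges) && !inherits(vals$property_ranges, "reward_spec")) {
    pr <- vals$property_ranges
    vals$property_ranges <- reward_spec(
      mw_range = unlist(pr$mw) %||% c(320, 420),
      clogp_range = unlist(pr$clogp) %||% c(2.3, 4.3),
      psa_range = unlist(pr$psa) %||% c(45, 65)
    )
  }
  do.call(run_config, vals)
}
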