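#' Best-shape conformer pair of two anchored ensembles
#'
#' Scans all conformer pairs (at most `max_conformers` squared) and keeps
#' the pair with the highest shape Tanimoto. Anchor atoms are excluded
#' from the shape computation: the anchor is identical in both ensembles
#' and would only inflate the similarity. Ties break to the lowest
#' (index_a, index_b).
#'
#' @param ens_a,ens_b `conformer_ensemble` objects.
#' @return A list with `conf_a`, `conf_b` (1-based indices) and
#'   `shape_value`.
#' @export
best_shape_pair <- function(ens_a, ens_b) {
  stopifnot(inherits(ens_a, "conformer_ensemble"),
            inherits(ens_b, "conformer_ensemble"))
  va <- vdw_radii(ens_a$mol$atoms$element)
  vb <- vdw_radii(ens_b$mol$atoms$element)
  best <- list(conf_a = 1L, conf_b = 1L, shape_value = -Inf)
  for (i in seq_along(ens_a$conformers)) {
    for (j in seq_along(ens_b$conformers)) {
      s <- shape_tanimoto(
        list(positions = ens_a$conformers[[i]], vdw = va),
        list(positions = ens_b$conformers[[j]], vdw = vb),
        exclude_a = ens_a$anchor, exclude_b = ens_b$anchor
      )
      if (s > best$shape_value + 1e-15) {
        best <- list(conf_a = i, conf_b = j, shape_value = s)
      }
    }
  }
  best
}

# Everything reusable about one fragment in the pipeline: its anchored
# ensemble plus, per conformer, the H-capped (anchor-removed) record, and
# the charge vector of the capped fragment (conformer-independent).
.fragment_profile <- function(frag, cfg, primary = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s (fragment %s)", name, conditionMessage(e), frag$mol$id),
            class = "fragesp_pipeline_error", parent = e)
    })
  }
  anchored <- stage("attach_anchor", attach_anchor(frag, primary))
  ens <- stage("generate_anchored_conformers",
               generate_anchored_conformers(anchored, anchor_template(),
                                            cfg$max_conformers, cfg$seed))
  capped <- stage("remove_anchor", lapply(ens$conformers, function(cc) {
    remove_anchor(.set_coords(ens$mol, cc))
  }))
  charged0 <- stage("assign_charges",
                    assign_charges(capped[[1]], cfg$charge_method))
  list(frag = frag, ensemble = ens, capped = capped, charges = charged0$charges)
}

.profile_point_set <- function(profile, conf) {
  m <- profile$capped[[conf]]
  charged_point_set(.coords(m), profile$charges, elements = m$atoms$element)
}

#' ESP similarity of a fragment pair through the anchored pipeline
#'
#' The full fragment-comparison procedure: attach the anchor, embed both
#' fragments as constrained conformer ensembles in the shared anchor
#' frame, keep the conformer pair with the best shape overlay, strip the
#' anchor (hydrogen cap, surviving coordinates untouched), assign partial
#' charges to the capped fragments, and score the retained pair with the
#' configured ESP integrator and metric. The reported `shape_tanimoto` is
#' recomputed on the final capped conformers so it describes the same
#' structures as the ESP score.
#'
#' @param frag_a,frag_b `fragment` objects with at least one attachment.
#' @param cfg A [run_config()].
#' @return A one-row tibble: keys, retained conformer indices, selection
#'   shape value, and the [esp_similarity()] columns.
#' @export
fragment_pair_similarity <- function(frag_a, frag_b, cfg = run_config()) {
  pa <- .fragment_profile(frag_a, cfg)
  pb <- .fragment_profile(frag_b, cfg)
  .profile_pair_similarity(pa, pb, cfg)
}

.profile_pair_similarity <- function(pa, pb, cfg) {
  sel <- best_shape_pair(pa$ensemble, pb$ensemble)
  A <- .profile_point_set(pa, sel$conf_a)
  B <- .profile_point_set(pb, sel$conf_b)
  shape <- shape_tanimoto(A, B)
  res <- esp_similarity(A, B, cfg, shape = shape)
  bind_rows(tibble(
    key_a = pa$frag$canonical_key, key_b = pb$frag$canonical_key,
    conf_a = sel$conf_a, conf_b = sel$conf_b,
    selection_shape = sel$shape_value
  )) |> dplyr::bind_cols(res)
}
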