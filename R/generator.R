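#' Property target ranges ("sweet spot") and reward weights
#'
#' Default ranges are centered on a known lead: molecular weight 320-420
#' Da, clogP 2.3-4.3, topological polar surface area 45-65 A^2. The
#' reward gives a base validity term plus an equal increment per satisfied
#' range, normalized so that a valid molecule inside all three ranges
#' scores exactly 1.
#'
#' @param mw_range,clogp_range,psa_range Length-2 numeric ranges
#'   (lower < upper).
#' @param validity_weight Weight of the validity term (default 1/4; the
#'   three property increments share the remainder equally).
#' @return A `reward_spec`.
#' @export
reward_spec <- function(mw_range = c(320, 420), clogp_range = c(2.3, 4.3),
                        psa_range = c(45, 65), validity_weight = 0.25) {
  for (r in list(mw_range, clogp_range, psa_range)) {
    stopifnot(length(r) == 2, r[1] < r[2])
  }
  stopifnot(validity_weight > 0, validity_weight <= 1)
  structure(list(mw_range = mw_range, clogp_range = clogp_range,
                 psa_range = psa_range, validity_weight = validity_weight),
            class = "reward_spec")
}

.in_range <- function(x, r) !is.na(x) & x > r[1] & x < r[2]

# Range-satisfaction flags for a property tibble (mw, clogp, psa).
.range_flags <- function(props, spec) {
  tibble(mw_ok = .in_range(props$mw, spec$mw_range),
         clogp_ok = .in_range(props$clogp, spec$clogp_range),
         psa_ok = .in_range(props$psa, spec$psa_range))
}

#' Reward of a generated molecule
#'
#' Invalid molecules score 0. A valid molecule receives the validity
#' weight plus an equal share of the remaining weight per satisfied
#' property range; all three satisfied gives exactly 1.
#'
#' @param mol A [mol_record()], a SMILES string, or `NULL`/`NA` for an
#'   invalid molecule.
#' @param spec A [reward_spec()].
#' @param props Optional precomputed property tibble (columns `mw`,
#'   `clogp`, `psa`) to avoid recomputation.
#' @return Reward in `[0, 1]`.
#' @export
property_reward <- function(mol, spec = reward_spec(), props = NULL) {
  invalid <- is.null(mol) || (length(mol) == 1 && !inherits(mol, "mol_record") && is.na(mol))
  if (invalid) return(0)
  if (is.null(props)) props <- mol_properties(mol)
  flags <- .range_flags(props, spec)
  k <- sum(unlist(flags))
  w <- spec$validity_weight
  w + (1 - w) * k / 3
}

#' Build a fragment library with tree codes
#'
#' Deduplicates fragments by canonical key, computes the pairwise
#' similarity matrix, builds the balanced encoding tree and assigns the
#' per-fragment bitstrings.
#'
#' @param frags List of `fragment` objects.
#' @param cfg A [run_config()].
#' @param metric Similarity metric for the tree (`"esp"` or `"fp"`).
#' @return A `fragment_library`: list with `fragments` (named by key),
#'   `codes` (tibble key/code), `matrix`, `tree`.
#' @export
fragment_library <- function(frags, cfg = run_config(), metric = "esp") {
  keys <- vapply(frags, function(f) f$canonical_key, character(1))
  frags <- frags[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  names(frags) <- keys
  m <- similarity_matrix(frags, cfg, metric = metric)
  tree <- build_encoding_tree(m)
  codes <- encode_fragments(tree)
  codes$n_attachments <- vapply(codes$key, function(k) nrow(frags[[k]]$attachments),
                                integer(1))
  structure(list(fragments = frags, codes = codes, matrix = m, tree = tree),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library> %d fragments, %d-bit codes\n",
              nrow(x$codes), nchar(x$codes$code[1])))
  invisible(x)
}

#' Encode a lead molecule as a fragment-slot state
#'
#' Fragments the lead, maps each fragment to its library code, and
#' records the cut-bond topology so any code assignment can be decoded
#' back into a molecule.
#'
#' @param lead A [mol_record()].
#' @param library A [fragment_library()].
#' @return A `molecule_state`, or an error if a lead fragment is missing
#'   from the library.
#' @export
lead_state <- function(lead, library) {
  frs <- fragment_molecule(lead)
  keys <- vapply(frs, function(f) f$canonical_key, character(1))
  idx <- match(keys, library$codes$key)
  if (any(is.na(idx))) {
    abort(sprintf("Lead %s contains fragment(s) missing from the library: %s",
                  lead$id, paste(keys[is.na(idx)], collapse = ", ")),
          class = "fragesp_input_error")
  }
  slots <- library$codes$code[idx]
  attachments <- lapply(frs, function(f) f$attachments$label)
  structure(list(lead_id = lead$id, codes = slots, attachments = attachments),
            class = "molecule_state")
}

#' Decode a fragment-slot state into a molecule
#'
#' Each slot's code selects a library fragment; fragments are joined at
#' the lead's cut-bond labels (slot attachment i carries label i of that
#' slot). A code absent from the library, an attachment-count mismatch or
#' a valence-violating join makes the state invalid (`NULL` return)
#' rather than an exception.
#'
#' @param state A `molecule_state`.
#' @param library A [fragment_library()].
#' @return A [mol_record()] or `NULL` (invalid).
#' @export
decode_state <- function(state, library) {
  keys <- library$codes$key[match(state$codes, library$codes$code)]
  if (any(is.na(keys))) return(NULL)
  frs <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    f <- library$fragments[[keys[i]]]
    labels <- state$attachments[[i]]
    if (nrow(f$attachments) != length(labels)) {
      return(NULL)
    }
    f$attachments$label <- labels
    frs[[i]] <- f
  }
  out <- tryCatch({
    m <- reassemble_fragments(frs, id = paste0(state$lead_id, "_gen"))
    .check_valences(add_hydrogens(m))
    m
  }, error = function(e) NULL)
  if (is.null(out)) return(out)
  smi <- canonical_smiles(out)
  if (is.na(smi)) return(NULL)
  attr(out, "smiles") <- smi
  out
}

# ---- minimal actor-critic ---------------------------------------------

.mlp_init <- function(d_in, d_hidden, d_out, scale = 0.1) {
  list(W1 = matrix(rnorm(d_hidden * d_in, sd = scale), d_hidden, d_in),
       b1 = numeric(d_hidden),
       W2 = matrix(rnorm(d_out * d_hidden, sd = scale), d_out, d_hidden),
       b2 = numeric(d_out))
}

.mlp_forward <- function(net, x) {
  h <- tanh(net$W1 %*% x + net$b1)
  list(h = h, out = as.numeric(net$W2 %*% h + net$b2))
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Gradient of (-log pi(a) * adv - entropy_coef * H) wrt policy params.
.policy_grad <- function(net, x, fwd, a, adv, entropy_coef) {
  p <- .softmax(fwd$out)
  dz <- p * adv
  dz[a] <- dz[a] - adv
  logp <- log(pmax(p, 1e-12))
  H <- -sum(p * logp)
  dz <- dz + entropy_coef * p * (logp + H)
  dh <- as.numeric(t(net$W2) %*% dz)
  dpre <- dh * (1 - as.numeric(fwd$h)^2)
  list(W1 = outer(dpre, as.numeric(x)), b1 = dpre,
       W2 = outer(dz, as.numeric(fwd$h)), b2 = dz)
}

# Gradient of (v - target)^2 wrt value params (d_out = 1).
.value_grad <- function(net, x, fwd, target) {
  dv <- 2 * (fwd$out - target)
  dz <- dv
  dh <- as.numeric(t(net$W2) %*% dz)
  dpre <- dh * (1 - as.numeric(fwd$h)^2)
  list(W1 = outer(dpre, as.numeric(x)), b1 = dpre,
       W2 = matrix(dz * as.numeric(fwd$h), 1), b2 = dz)
}

.grad_zero <- function(net) lapply(net, function(w) w * 0)
.grad_add <- function(g, dg) Map(`+`, g, dg)

# Adam update on the batch-mean gradient (the conventional reading of a
# deep-RL learning rate).
.adam_init <- function(net) {
  list(m = .grad_zero(net), v = .grad_zero(net), t = 0)
}
.adam_step <- function(net, opt, g, lr, n, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  g <- lapply(g, function(gw) gw / n)
  opt$m <- Map(function(m, gw) beta1 * m + (1 - beta1) * gw, opt$m, g)
  opt$v <- Map(function(v, gw) beta2 * v + (1 - beta2) * gw^2, opt$v, g)
  mh <- lapply(opt$m, function(m) m / (1 - beta1^opt$t))
  vh <- lapply(opt$v, function(v) v / (1 - beta2^opt$t))
  net <- Map(function(w, m, v) w - lr * m / (sqrt(v) + eps), net, mh, vh)
  list(net = net, opt = opt)
}

.state_vector <- function(codes, max_slots, code_len) {
  bits <- integer(max_slots * code_len)
  for (s in seq_along(codes)) {
    v <- as.integer(strsplit(codes[s], "")[[1]])
    bits[((s - 1) * code_len + 1):(s * code_len)] <- v
  }
  bits
}

# Apply one action. A flip that would leave the slot on a code with no
# library fragment, or on a fragment whose attachment count does not fit
# the slot, is a blocked move: the state is unchanged (the action space
# means "move to a similar fragment", and there is none there).
.apply_action <- function(codes, action, max_slots, k_bits, code_len,
                          allowed = NULL) {
  if (action > length(codes) * k_bits) return(codes)  # no-op or missing slot
  slot <- (action - 1) %/% k_bits + 1
  bit_from_end <- (action - 1) %% k_bits  # 0 = last bit
  if (slot > length(codes)) return(codes)
  pos <- code_len - bit_from_end
  v <- strsplit(codes[slot], "")[[1]]
  v[pos] <- if (v[pos] == "1") "0" else "1"
  new_code <- paste(v, collapse = "")
  if (!is.null(allowed) && !new_code %in% allowed[[slot]]) return(codes)
  codes[slot] <- new_code
  codes
}

#' Train the fragment-swap generator
#'
#' A small actor-critic loop over lead molecules: each episode starts from
#' a lead's fragment-slot state and applies `n_steps` policy actions, each
#' flipping one of the last `k_bits` bits of one slot's code (staying near
#' similar fragments in the encoding tree) or doing nothing. The terminal
#' molecule earns the [property_reward()]; actor and critic are updated by
#' policy gradient with a value baseline. Fully deterministic for a fixed
#' config seed.
#'
#' @param leads List of [mol_record()] leads.
#' @param library A [fragment_library()].
#' @param cfg A [run_config()]; `cfg$epochs`, `cfg$episodes_per_epoch`,
#'   `cfg$property_ranges` and `cfg$seed` drive the loop.
#' @param n_steps Actions per episode (default 5).
#' @param k_bits Flippable low bits per slot code (default 3).
#' @param learning_rate SGD step size (default 1e-3); 0 disables learning
#'   (negative-control mode).
#' @param batch_size Episodes per gradient update (default 32).
#' @param entropy_coef Entropy bonus weight (default 0.01).
#' @param hidden Hidden layer width (default 32).
#' @param tracked_scaffolds Character vector of fragment keys whose
#'   occurrence among each epoch's generated molecules is tracked.
#' @return A `generator_fit`: list with `generated` (tibble of unique
#'   valid molecules with properties and rewards), `stats` (per-epoch
#'   tibble), `library`, `cfg`, and the trained networks.
#' @export
train_generator <- function(leads, library, cfg = run_config(), n_steps = 5,
                            k_bits = 3, learning_rate = 1e-3, batch_size = 32,
                            entropy_coef = 0.01, hidden = 32,
                            tracked_scaffolds = character()) {
  if (length(library$fragments) == 0) {
    abort("Empty fragment library.", class = "fragesp_input_error")
  }
  states <- list()
  for (ld in leads) {
    st <- tryCatch(lead_state(ld, library), error = function(e) NULL)
    if (!is.null(st)) states[[length(states) + 1]] <- st
  }
  if (length(states) == 0) {
    abort("No fragmentable leads covered by the library.", class = "fragesp_input_error")
  }
  spec <- cfg$property_ranges
  code_len <- nchar(library$codes$code[1])
  k_bits <- min(k_bits, code_len)
  max_slots <- max(vapply(states, function(s) length(s$codes), integer(1)))
  d_in <- max_slots * code_len
  n_actions <- max_slots * k_bits + 1

  # per-lead, per-slot sets of codes whose fragment fits the slot's
  # attachment count (blocked-move bookkeeping)
  allowed_codes <- lapply(states, function(s) {
    lapply(s$attachments, function(labels) {
      library$codes$code[library$codes$n_attachments == length(labels)]
    })
  })

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  actor <- .mlp_init(d_in, hidden, n_actions)
  critic <- .mlp_init(d_in, hidden, 1)
  opt_a <- .adam_init(actor)
  opt_c <- .adam_init(critic)

  # reward memoisation: decoding + descriptor computation per unique state
  cache <- new.env(parent = emptyenv())
  eval_state <- function(st) {
    key <- paste(st$codes, collapse = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    mol <- decode_state(st, library)
    rec <- if (is.null(mol)) {
      list(valid = FALSE, smiles = NA_character_, reward = 0,
           props = tibble(mw = NA_real_, clogp = NA_real_, psa = NA_real_),
           flags = tibble(mw_ok = FALSE, clogp_ok = FALSE, psa_ok = FALSE),
           keys = NA_character_)
    } else {
      props <- mol_properties(attr(mol, "smiles"))
      flags <- .range_flags(props, spec)
      list(valid = TRUE, smiles = attr(mol, "smiles"),
           reward = property_reward(mol, spec, props = props),
           props = props, flags = flags,
           keys = library$codes$key[match(st$codes, library$codes$code)])
    }
    cache[[key]] <- rec
    rec
  }

  stats <- list()
  generated <- new.env(parent = emptyenv())
  if (cfg$epochs == 0) {
    return(structure(list(generated = .collect_generated(generated),
                          stats = tibble(), library = library, cfg = cfg,
                          actor = actor, critic = critic),
                     class = "generator_fit"))
  }
  for (epoch in seq_len(cfg$epochs)) {
    ep_valid <- ep_sweet <- 0
    ep_flags <- c(mw_ok = 0, clogp_ok = 0, psa_ok = 0)
    ep_scaff <- stats::setNames(numeric(length(tracked_scaffolds)), tracked_scaffolds)
    ga <- .grad_zero(actor); gc <- .grad_zero(critic); nb <- 0
    batch <- list()
    for (ep in seq_len(cfg$episodes_per_epoch)) {
      si <- sample.int(length(states), 1)
      st <- states[[si]]
      allowed <- allowed_codes[[si]]
      traj <- vector("list", n_steps)
      for (t in seq_len(n_steps)) {
        x <- .state_vector(st$codes, max_slots, code_len)
        fa <- .mlp_forward(actor, x)
        p <- .softmax(fa$out)
        a <- sample.int(n_actions, 1, prob = p)
        traj[[t]] <- list(x = x, fwd = fa, a = a)
        st$codes <- .apply_action(st$codes, a, max_slots, k_bits, code_len, allowed)
      }
      res <- eval_state(st)
      R <- res$reward
      if (learning_rate > 0) {
        batch[[length(batch) + 1]] <- list(traj = traj, R = R)
      }
      nb <- nb + 1
      if (nb >= batch_size) {
        if (learning_rate > 0 && length(batch) > 0) {
          # critic forward + raw advantages over the whole batch, then
          # batch-normalized advantages for the policy gradient
          steps <- list()
          for (epi in batch) {
            for (t in seq_along(epi$traj)) {
              x <- epi$traj[[t]]$x
              fv <- .mlp_forward(critic, x)
              steps[[length(steps) + 1]] <- list(x = x, fwd = epi$traj[[t]]$fwd,
                                                 a = epi$traj[[t]]$a,
                                                 fv = fv, adv = epi$R - fv$out,
                                                 R = epi$R)
            }
          }
          advs <- vapply(steps, function(s) s$adv, numeric(1))
          sd_adv <- stats::sd(advs)
          if (!is.finite(sd_adv) || sd_adv < 1e-8) sd_adv <- 1
          for (s in steps) {
            adv_n <- (s$adv - mean(advs)) / sd_adv
            ga <- .grad_add(ga, .policy_grad(actor, s$x, s$fwd, s$a,
                                             adv_n, entropy_coef))
            gc <- .grad_add(gc, .value_grad(critic, s$x, s$fv, s$R))
          }
          sa <- .adam_step(actor, opt_a, ga, learning_rate, length(steps))
          actor <- sa$net; opt_a <- sa$opt
          sc <- .adam_step(critic, opt_c, gc, learning_rate, length(steps))
          critic <- sc$net; opt_c <- sc$opt
        }
        ga <- .grad_zero(actor); gc <- .grad_zero(critic); nb <- 0
        batch <- list()
      }
      if (res$valid) {
        ep_valid <- ep_valid + 1
        fl <- unlist(res$flags)
        ep_flags <- ep_flags + fl
        sweet <- all(fl)
        if (sweet) ep_sweet <- ep_sweet + 1
        for (k in tracked_scaffolds) {
          if (k %in% res$keys) ep_scaff[k] <- ep_scaff[k] + 1
        }
        if (is.null(generated[[res$smiles]])) {
          generated[[res$smiles]] <- c(list(smiles = res$smiles, epoch = epoch,
                                            reward = res$reward, sweet_spot = sweet),
                                       as.list(res$props))
        }
      }
    }
    ne <- cfg$episodes_per_epoch
    row <- tibble(epoch = epoch, frac_valid = ep_valid / ne,
                  frac_mw = ep_flags[["mw_ok"]] / ne,
                  frac_clogp = ep_flags[["clogp_ok"]] / ne,
                  frac_psa = ep_flags[["psa_ok"]] / ne,
                  frac_sweet_spot = ep_sweet / ne)
    for (k in tracked_scaffolds) row[[paste0("scaffold_", k)]] <- ep_scaff[k] / ne
    stats[[epoch]] <- row
  }
  structure(list(generated = .collect_generated(generated),
                 stats = bind_rows(stats), library = library, cfg = cfg,
                 actor = actor, critic = critic),
            class = "generator_fit")
}

.collect_generated <- function(env) {
  items <- as.list(env)
  if (length(items) == 0) {
    return(tibble(smiles = character(), epoch = integer(), reward = numeric(),
                  sweet_spot = logical(), mw = numeric(), clogp = numeric(),
                  psa = numeric()))
  }
  bind_rows(lapply(items, as_tibble)) |> arrange(.data$epoch, .data$smiles)
}

#' @export
print.generator_fit <- function(x, ...) {
  cat(sprintf("<generator_fit> %d epochs x %d episodes; %d unique valid molecules (%d sweet spot)\n",
              nrow(x$stats), x$cfg$episodes_per_epoch, nrow(x$generated),
              sum(x$generated$sweet_spot)))
  invisible(x)
}

#' @rdname train_generator
#' @param x A `generator_fit`.
#' @param ... Unused.
#' @export
tidy.generator_fit <- function(x, ...) x$stats

#' @rdname train_generator
#' @export
glance.generator_fit <- function(x, ...) {
  tibble(epochs = nrow(x$stats),
         episodes = nrow(x$stats) * x$cfg$episodes_per_epoch,
         n_generated = nrow(x$generated),
         n_sweet_spot = sum(x$generated$sweet_spot),
         final_frac_valid = tail(x$stats$frac_valid, 1) %||% NA_real_,
         final_frac_sweet_spot = tail(x$stats$frac_sweet_spot, 1) %||% NA_real_)
}

#' @rdname train_generator
#' @param object A `generator_fit`.
#' @export
autoplot.generator_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$stats,
                              cols = dplyr::starts_with("frac_"),
                              names_to = "quantity", values_to = "fraction")
  long$quantity <- sub("^frac_", "", long$quantity)
  ggplot(long, aes(x = .data$epoch, y = .data$fraction, colour = .data$quantity)) +
    geom_line() +
    labs(x = "epoch", y = "fraction of episodes",
         colour = NULL, title = "Generator learning curves") +
    theme_minimal()
}

#' Summarize a generated molecule set against the sweet spot
#'
#' @param generated Tibble as returned in `generator_fit$generated` (or
#'   any tibble with `smiles`, `mw`, `clogp`, `psa`, optionally `epoch`).
#' @param spec A [reward_spec()].
#' @param tracked_scaffolds Fragment keys (canonical SMILES with dummy
#'   attachment marker) counted by substructure-free key membership when a
#'   `keys` list-column is present, otherwise ignored.
#' @return A one-row tibble of counts and fractions.
#' @export
sweet_spot_report <- function(generated, spec = reward_spec(),
                              tracked_scaffolds = character()) {
  n <- nrow(generated)
  if (n == 0) {
    return(tibble(n_molecules = 0L, frac_mw = NA_real_, frac_clogp = NA_real_,
                  frac_psa = NA_real_, frac_sweet_spot = NA_real_))
  }
  flags <- .range_flags(generated, spec)
  out <- tibble(n_molecules = n,
                frac_mw = mean(flags$mw_ok),
                frac_clogp = mean(flags$clogp_ok),
                frac_psa = mean(flags$psa_ok),
                frac_sweet_spot = mean(flags$mw_ok & flags$clogp_ok & flags$psa_ok))
  if (length(tracked_scaffolds) > 0 && "keys" %in% names(generated)) {
    for (k in tracked_scaffolds) {
      out[[paste0("scaffold_", k)]] <-
        mean(vapply(generated$keys, function(v) k %in% v, logical(1)))
    }
  }
  out
}
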