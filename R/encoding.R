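#' Pairwise fragment similarity matrix
#'
#' Runs the anchored ESP pipeline (or, for comparison runs, an FP2 path
#' fingerprint Tanimoto) over every unordered fragment pair. Each pair is
#' computed once, so the matrix is symmetric by construction with unit
#' diagonal. Pipeline failures are recorded per pair, assigned similarity
#' 0, and reported in the `failures` attribute.
#'
#' For the ESP metric the similarity entering the matrix is the
#' renormalized configured metric (tree building needs a common
#' non-negative scale).
#'
#' @param frags List of `fragment` objects (>= 2) with distinct
#'   canonical keys.
#' @param cfg A [run_config()].
#' @param metric `"esp"` (anchored 3D pipeline) or `"fp"` (topological
#'   fingerprints of the methyl-capped fragments).
#' @return A `similarity_matrix`: list with `keys` and `values` (symmetric
#'   numeric matrix), attribute `failures` a tibble.
#' @export
similarity_matrix <- function(frags, cfg = run_config(), metric = c("esp", "fp")) {
  metric <- match.arg(metric)
  n <- length(frags)
  if (n < 2) abort("Need at least two fragments.", class = "fragesp_input_error")
  keys <- vapply(frags, function(f) f$canonical_key, character(1))
  if (anyDuplicated(keys)) {
    abort("Duplicate fragment keys; deduplicate the library first.",
          class = "fragesp_input_error")
  }
  vals <- diag(1, n)
  failures <- tibble(key_a = character(), key_b = character(), stage = character())
  if (metric == "fp") {
    smis <- vapply(frags, function(f) {
      m <- .cap_graph(f, primary = if (nrow(f$attachments) > 0) 1L else 0L,
                      primary_cap = "C")
      canonical_smiles(m)
    }, character(1))
    vals <- .fp2_similarity_matrix(smis)
    diag(vals) <- 1
  } else {
    # one profile per attachment choice: multi-attachment fragments are
    # compared over every pairing of primary attachments and the best
    # value is kept
    profiles <- vector("list", n)
    for (i in seq_len(n)) {
      np <- max(1L, nrow(frags[[i]]$attachments))
      profiles[[i]] <- lapply(seq_len(np), function(p) {
        tryCatch(.fragment_profile(frags[[i]], cfg, primary = p),
                 error = function(e) e)
      })
    }
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        best <- NA_real_
        err <- NULL
        for (pa in profiles[[i]]) {
          for (pb in profiles[[j]]) {
            if (inherits(pa, "error") || inherits(pb, "error")) {
              err <- if (inherits(pa, "error")) pa else pb
              next
            }
            row <- tryCatch(.profile_pair_similarity(pa, pb, cfg),
                            error = function(e) e)
            if (inherits(row, "error")) {
              err <- row
              next
            }
            s <- renormalize_similarity(
              if (cfg$metric == "carbo") row$carbo else row$tanimoto, cfg$metric)
            if (is.na(best) || s > best) best <- s
          }
        }
        if (is.na(best)) {
          vals[i, j] <- vals[j, i] <- 0
          failures <- bind_rows(failures, tibble(key_a = keys[i], key_b = keys[j],
                                                 stage = conditionMessage(err)))
        } else {
          vals[i, j] <- vals[j, i] <- best
        }
      }
    }
  }
  dimnames(vals) <- list(keys, keys)
  structure(list(keys = keys, values = vals),
            class = "similarity_matrix", failures = failures)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d fragments\n", length(x$keys)))
  print(round(x$values, 3))
  invisible(x)
}

#' @rdname similarity_matrix
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(as.data.frame(object$values), key_a = object$keys),
    cols = -dplyr::all_of("key_a"), names_to = "key_b", values_to = "similarity"
  )
  ggplot(long, aes(x = .data$key_a, y = .data$key_b, fill = .data$similarity)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = 0.5, limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "similarity") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
as_tibble.similarity_matrix <- function(x, ...) {
  n <- length(x$keys)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(key_a = x$keys[idx[, 1]], key_b = x$keys[idx[, 2]],
         similarity = x$values[idx])
}

#' Build the balanced similarity encoding tree
#'
#' Fragments are paired greedily bottom-up: the two most similar nodes are
#' merged first, inter-node similarity being the arithmetic mean of all
#' leaf-pair similarities (UPGMA-style), with ties broken by the
#' lexicographically smallest pair of node keys. To guarantee a balanced
#' tree (leaf depths differing by at most one) for any n, the first round
#' merges exactly n - 2^(D-1) pairs (D = ceiling(log2 n)), which reduces
#' the working list to a power of two; every later round pairs all
#' remaining nodes greedily. The globally most similar pair is always the
#' first merge, so maximally similar fragments are siblings.
#'
#' @param m A [similarity_matrix()].
#' @return An `encoding_tree`: recursive list of nodes
#'   (`list(left, right)`) and leaves (fragment keys), with attributes.
#' @export
build_encoding_tree <- function(m) {
  stopifnot(inherits(m, "similarity_matrix"))
  if (any(!is.finite(m$values))) {
    abort("Similarity matrix contains non-finite values.", class = "fragesp_input_error")
  }
  n <- length(m$keys)
  if (n < 2) abort("Need at least two fragments.", class = "fragesp_input_error")
  nodes <- lapply(m$keys, function(k) list(leaf = TRUE, key = k, leaves = k))
  sim <- function(x, y) {
    mean(m$values[x$leaves, y$leaves])
  }
  node_key <- function(x) min(x$leaves)
  # one greedy merge among the nodes still eligible this round; a merged
  # node becomes ineligible until the next round (round discipline is what
  # guarantees the balance invariant)
  merge_best <- function(state) {
    nodes <- state$nodes; avail <- state$avail
    best <- NULL; bi <- bj <- 0
    ii <- which(avail)
    for (i in ii) {
      for (j in ii[ii > i]) {
        s <- sim(nodes[[i]], nodes[[j]])
        pk <- sort(c(node_key(nodes[[i]]), node_key(nodes[[j]])))
        if (is.null(best) || s > best$s + 1e-12 ||
            (abs(s - best$s) <= 1e-12 &&
             (pk[1] < best$pk[1] || (pk[1] == best$pk[1] && pk[2] < best$pk[2])))) {
          best <- list(s = s, pk = pk); bi <- i; bj <- j
        }
      }
    }
    a <- nodes[[bi]]; b <- nodes[[bj]]
    # deterministic child order: smaller node key goes left
    if (node_key(b) < node_key(a)) { tmp <- a; a <- b; b <- tmp }
    nodes[[bi]] <- list(leaf = FALSE, left = a, right = b,
                        leaves = c(a$leaves, b$leaves))
    avail[bi] <- FALSE
    nodes[[bj]] <- NULL
    avail <- avail[-bj]
    list(nodes = nodes, avail = avail)
  }
  D <- ceiling(log2(n))
  # round 1 reduces the list to 2^(D-1) nodes, merging the globally most
  # similar pairs first; later rounds pair everything
  state <- list(nodes = nodes, avail = rep(TRUE, n))
  for (k in seq_len(n - 2^(D - 1))) state <- merge_best(state)
  while (length(state$nodes) > 1) {
    state$avail <- rep(TRUE, length(state$nodes))
    for (k in seq_len(length(state$nodes) / 2)) state <- merge_best(state)
  }
  structure(state$nodes[[1]], class = "encoding_tree", n_leaves = n)
}

#' @export
print.encoding_tree <- function(x, ...) {
  cat(sprintf("<encoding_tree> %d leaves, depth spread %d\n",
              attr(x, "n_leaves"), diff(range(.leaf_depths(x)))))
  invisible(x)
}

.leaf_depths <- function(node, depth = 0) {
  if (isTRUE(node$leaf)) return(stats::setNames(depth, node$key))
  c(.leaf_depths(node$left, depth + 1), .leaf_depths(node$right, depth + 1))
}

#' Read fragment codes off the encoding tree
#'
#' Root-to-leaf paths become bitstrings: branching left appends "1",
#' branching right appends "0" (the last bit is the branching closest to
#' the leaf). Leaves one level shallower than the deepest are padded with
#' a trailing "0" so all codes share the length ceiling(log2 n); because
#' no root-to-leaf path can pass through another leaf, trailing padding
#' keeps the code set collision-free (prefix-freeness), which padding on
#' the root side would not.
#'
#' @param tree An `encoding_tree`.
#' @return A tibble with columns `key` and `code`.
#' @export
encode_fragments <- function(tree) {
  stopifnot(inherits(tree, "encoding_tree"))
  walk <- function(node, path) {
    if (isTRUE(node$leaf)) {
      return(tibble(key = node$key, code = path))
    }
    bind_rows(walk(node$left, paste0(path, "1")),
              walk(node$right, paste0(path, "0")))
  }
  out <- walk(tree, "")
  width <- max(nchar(out$code))
  out$code <- vapply(out$code, function(cc) {
    paste0(cc, strrep("0", width - nchar(cc)))
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(out$code)) abort("Non-unique codes (corrupt tree).")
  out
}

#' Decode a bitstring back to its fragment key
#'
#' @param code Bitstring as emitted by [encode_fragments()].
#' @param codes The code table from [encode_fragments()].
#' @return The fragment key, or `NA_character_` for an unassigned code.
#' @export
decode_code <- function(code, codes) {
  i <- match(code, codes$code)
  if (is.na(i)) NA_character_ else codes$key[i]
}
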