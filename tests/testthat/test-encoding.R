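test_that("similarity matrices are symmetric with unit diagonal", {
  frs <- list(ring_fragment_of("Cc1ccccc1"), ring_fragment_of("Cc1cccnc1"),
              ring_fragment_of("Cc1cncnc1"))
  m <- similarity_matrix(frs, run_config(), metric = "fp")
  expect_equal(diag(m$values), rep(1, 3), ignore_attr = TRUE)
  expect_equal(m$values, t(m$values))
  expect_equal(nrow(as_tibble(m)), 3)  # three unordered pairs for n = 3
  expect_error(similarity_matrix(frs[1], run_config()), class = "fragesp_input_error")
  expect_error(similarity_matrix(c(frs, frs[1]), run_config()),
               class = "fragesp_input_error")  # duplicate keys
})

test_that("fingerprint similarity ranks pyridine closer to benzene than pyrimidine", {
  frs <- list(ring_fragment_of("Cc1ccccc1"), ring_fragment_of("Cc1cccnc1"),
              ring_fragment_of("Cc1cncnc1"))
  m <- similarity_matrix(frs, run_config(), metric = "fp")
  keys <- m$keys
  bz <- which(keys == "*c1ccccc1")
  py <- which(keys == "*c1cccnc1")
  pm <- which(keys == "*c1cncnc1")
  expect_gt(m$values[bz, py], m$values[bz, pm])
})

test_that("greedy pairing makes the most similar fragments siblings", {
  # n = 2: a single root
  m2 <- random_sim_matrix(2, 1)
  t2 <- build_encoding_tree(m2)
  expect_false(isTRUE(t2$leaf))
  expect_true(t2$left$leaf && t2$right$leaf)

  # n = 4 with a planted unique maximum
  m4 <- random_sim_matrix(4, 2)
  m4$values["frag01", "frag03"] <- m4$values["frag03", "frag01"] <- 0.9
  t4 <- build_encoding_tree(m4)
  codes <- encode_fragments(t4)
  c13 <- codes$code[match(c("frag01", "frag03"), codes$key)]
  expect_equal(substr(c13[1], 1, 1), substr(c13[2], 1, 1))
  expect_equal(sum(strsplit(c13[1], "")[[1]] != strsplit(c13[2], "")[[1]]), 1)

  # oracle at n = 4: of the three perfect pairings, the one containing the
  # global best pair is chosen
  best <- which(m4$values == max(m4$values[upper.tri(m4$values)]), arr.ind = TRUE)[1, ]
  sib <- function(tree) {
    if (tree$left$leaf && tree$right$leaf) return(sort(c(tree$left$key, tree$right$key)))
    NULL
  }
  sibs <- list(sib(t4$left), sib(t4$right))
  expect_true(any(vapply(sibs, function(s) {
    !is.null(s) && identical(s, sort(m4$keys[best]))
  }, logical(1))))
})

test_that("trees are balanced with unique fixed-length codes over random matrices", {
  for (i in 1:20) {
    n <- sample(4:16, 1)
    m <- random_sim_matrix(n, 100 + i)
    tree <- build_encoding_tree(m)
    depths <- fragesp:::.leaf_depths(tree)
    expect_lte(diff(range(depths)), 1)
    codes <- encode_fragments(tree)
    expect_equal(nrow(codes), n)
    expect_false(anyDuplicated(codes$code) > 0)
    expect_true(all(nchar(codes$code) == ceiling(log2(n))))
    # bijective decode
    for (j in seq_len(n)) {
      expect_equal(decode_code(codes$code[j], codes), codes$key[j])
    }
  }
})

test_that("trees and codes are deterministic for a fixed matrix", {
  m <- random_sim_matrix(9, 77)
  expect_identical(encode_fragments(build_encoding_tree(m)),
                   encode_fragments(build_encoding_tree(m)))
  bad <- m; bad$values[1, 2] <- NaN
  expect_error(build_encoding_tree(bad), class = "fragesp_input_error")
})

test_that("codes are local: last-bit neighbours are more similar than random pairs", {
  deltas <- numeric(0)
  for (i in 1:15) {
    n <- sample(6:14, 1)
    m <- random_sim_matrix(n, 500 + i)
    codes <- encode_fragments(build_encoding_tree(m))
    flip_last <- function(cc) {
      v <- strsplit(cc, "")[[1]]
      v[length(v)] <- if (v[length(v)] == "1") "0" else "1"
      paste(v, collapse = "")
    }
    sims_near <- c()
    for (j in seq_len(n)) {
      k <- match(flip_last(codes$code[j]), codes$code)
      if (!is.na(k)) sims_near <- c(sims_near, m$values[codes$key[j], codes$key[k]])
    }
    deltas <- c(deltas, mean(sims_near) - mean(m$values[upper.tri(m$values)]))
  }
  expect_gt(mean(deltas), 0)
})
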