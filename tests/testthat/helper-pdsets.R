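# Shared helpers for the suite. Fixtures are generated in code; nothing is
# read from disk except where a test exercises file I/O explicitly.

# order-insensitive comparison of a list of leaf-label sets
expect_same_partition <- function(got, want) {
  norm <- function(p) {
    p <- lapply(p, sort)
    p[order(vapply(p, paste, character(1), collapse = "|"))]
  }
  expect_equal(norm(got), norm(want))
}

# deterministic pool of small random trees exercising ties and multifurcations
random_tree_pool <- function(n_trees, seed = 20260929) {
  withr::with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      n <- sample(4:10, 1)
      random_ultrametric(
        n, seed = sample.int(1e6, 1),
        tie_prob = sample(c(0, 0.3), 1),
        multif_prob = sample(c(0, 0.25), 1)
      )
    })
  })
}

random_phi <- function(tree, seed) {
  withr::with_seed(seed, {
    setNames(sample(-5:5, n_leaves(tree), replace = TRUE), tree$labels)
  })
}

# greedy *minimisation* heuristic (known to be suboptimal; used to show the
# dynamic program is genuinely needed)
greedy_minpd_score <- function(tree, k) {
  labs <- sort(leaf_labels(tree))
  chosen <- character(0)
  for (i in seq_len(k)) {
    rest <- setdiff(labs, chosen)
    gains <- vapply(
      rest,
      function(x) pd_score(tree, c(chosen, x)) - if (length(chosen)) pd_score(tree, chosen) else 0,
      numeric(1)
    )
    chosen <- c(chosen, rest[which.min(gains)])
  }
  pd_score(tree, chosen)
}
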