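test_that("degenerate and small Newick inputs parse as specified", {
  single <- parse_newick("A;")
  expect_equal(n_leaves(single), 1L)
  expect_equal(total_pd(single), 0)
  expect_equal(write_newick(single), "A;")

  # a length on the root carries no diversity and is dropped with a warning
  expect_warning(two <- parse_newick("(A:1,B:2):5;"), "root")
  expect_equal(n_leaves(two), 2L)
  expect_equal(total_pd(two), 3)

  t1 <- tree_T1()
  expect_equal(n_leaves(t1), 7L)
  expect_equal(total_pd(t1), 23)
})

test_that("malformed or invalid Newick is rejected", {
  expect_error(parse_newick("(A:1,B:2"), class = "pdsets_malformed_newick")
  expect_error(parse_newick("(A:1,B);"), class = "pdsets_malformed_newick")
  expect_error(parse_newick("(A:1,B:-2);"), class = "pdsets_malformed_newick")
  expect_error(parse_newick("(A:1,B:0);"), class = "pdsets_malformed_newick")
  expect_error(parse_newick("(A:1,A:2);"), class = "pdsets_malformed_newick")
  expect_error(parse_newick(""), class = "pdsets_malformed_newick")
})

test_that("serialisation round-trips topology, labels and lengths", {
  trees <- c(
    list(tree_T1(), tree_T2(), tree_T3(), tree_mammal_P(), perfect_tree(3)),
    random_tree_pool(200)
  )
  for (tr in trees) {
    back <- parse_newick(write_newick(tr))
    expect_equal(leaf_labels(back), leaf_labels(tr))
    expect_equal(total_pd(back), total_pd(tr), tolerance = 1e-12)
    # canonical child order makes serialisation a normal form, so a fixed
    # point certifies isomorphism with equal lengths
    expect_equal(write_newick(back), write_newick(tr))
  }
})

test_that("suppressing a subdivided edge leaves every PD score unchanged", {
  plain <- parse_newick("((a:1,b:1):2,c:3);")
  subdivided <- parse_newick("((a:1,b:1):2,(c:1.25):1.75);")
  expect_equal(n_leaves(subdivided), 3L)
  subsets <- unlist(
    lapply(1:3, function(k) combn(c("a", "b", "c"), k, simplify = FALSE)),
    recursive = FALSE
  )
  for (s in subsets) {
    expect_equal(pd_score(subdivided, s), pd_score(plain, s))
  }
})

test_that("ultrametric heights follow edge lengths and reject violations", {
  t1 <- tree_T1()
  h <- ultrametric_heights(t1)
  expect_equal(h$root_height, 6)
  # height difference across every edge equals the edge length
  for (v in seq_len(t1$n_vertex)) {
    p <- t1$parent[v]
    if (!is.na(p)) {
      expect_equal(h$height[p] - h$height[v], t1$edge_len[v], tolerance = 1e-9)
    }
  }
  # cherry parents at height 1, root children at height 4
  cherry_parent <- t1$parent[match("x6", t1$labels)]
  expect_equal(h$height[cherry_parent], 1)

  skewed <- parse_newick("((a:1,b:2):1,c:3);")
  err <- tryCatch(ultrametric_heights(skewed), condition = identity)
  expect_s3_class(err, "pdsets_not_ultrametric")
  expect_setequal(err$leaves, c("a", "b"))

  perfect <- perfect_tree(3)
  expect_equal(ultrametric_heights(perfect)$root_height, 3)
})

test_that("clusters report the leaves below a vertex", {
  t1 <- tree_T1()
  expect_equal(tree_cluster(t1, t1$root), paste0("x", 1:7))
  cherry <- t1$parent[match("x6", t1$labels)]
  expect_equal(tree_cluster(t1, cherry), c("x6", "x7"))
  fork <- t1$parent[t1$parent[match("x4", t1$labels)]]
  expect_equal(tree_cluster(t1, fork), c("x4", "x5", "x6", "x7"))
  expect_equal(tree_cluster(t1, match("x3", t1$labels)), "x3")
  expect_error(tree_cluster(t1, 99), class = "pdsets_unknown_vertex")
})
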