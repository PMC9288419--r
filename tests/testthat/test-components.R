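test_that("recent forests of the 11-leaf fixture match the known partitions", {
  t2 <- tree_T2()
  h <- ultrametric_heights(t2)
  prof <- branching_profile(t2, h)

  at4 <- recent_forest(t2, h, prof$d[["4"]])
  expect_same_partition(at4$components, list(
    c("x1", "x2", "x3"), "x4", c("x5", "x6", "x7", "x8"), c("x9", "x10", "x11")
  ))
  at7 <- recent_forest(t2, h, prof$d[["7"]])
  expect_same_partition(at7$components, list(
    c("x1", "x2"), "x3", "x4", c("x5", "x6"), c("x7", "x8"),
    c("x9", "x10"), "x11"
  ))

  # extremes: only leaves are recent at d = 0; everything merges at the root
  expect_equal(length(recent_forest(t2, h, 0)$components), 11L)
  expect_equal(length(recent_forest(t2, h, h$root_height)$components), 1L)
  expect_error(recent_forest(t2, h, -1), class = "pdsets_bad_distance")
})

test_that("branching values record exactly the attainable component counts", {
  t2 <- tree_T2()
  h2 <- ultrametric_heights(t2)
  prof2 <- branching_profile(t2, h2)
  expect_equal(prof2$values, c(1L, 2L, 4L, 7L, 9L, 11L))
  # simultaneous merges skip counts: never 3, 5, 6, 8 or 10 components
  expect_false(any(c(3, 5, 6, 8, 10) %in% prof2$values))

  t1 <- tree_T1()
  prof1 <- branching_profile(t1, ultrametric_heights(t1))
  expect_equal(prof1$values, c(1L, 2L, 4L, 7L))

  cherry <- parse_newick("(a:1,b:1);")
  expect_equal(
    branching_profile(cherry, ultrametric_heights(cherry))$values,
    c(1L, 2L)
  )

  # at each branching distance the forest has exactly that many components,
  # and d_k strictly decreases in k
  for (tr in c(list(t1, t2, tree_T3()), random_tree_pool(10, seed = 21))) {
    h <- ultrametric_heights(tr)
    prof <- branching_profile(tr, h)
    expect_equal(prof$values[1], 1L)
    expect_equal(prof$values[length(prof$values)], n_leaves(tr))
    for (k in prof$values) {
      expect_length(
        recent_forest(tr, h, prof$d[[as.character(k)]])$components, k
      )
    }
    expect_true(all(diff(prof$d[as.character(prof$values)]) < 0))
  }
})

test_that("c(d) is non-increasing in d", {
  for (tr in random_tree_pool(6, seed = 22)) {
    h <- ultrametric_heights(tr)
    grid <- sort(unique(c(h$height, h$height + 1e-6, h$root_height / 2)))
    cc <- vapply(grid, function(d) length(recent_forest(tr, h, d)$components),
                 integer(1))
    expect_true(all(diff(cc) <= 0))
  }
})

test_that("the bracket pins k between its nearest branching values", {
  t2 <- tree_T2()
  prof2 <- branching_profile(t2, ultrametric_heights(t2))
  expect_equal(bracket(prof2, 5), c(k_minus = 4L, k_plus = 7L))
  expect_equal(bracket(prof2, 4), c(k_minus = 4L, k_plus = 4L))
  expect_equal(bracket(prof2, 10), c(k_minus = 9L, k_plus = 11L))

  prof1 <- branching_profile(tree_T1(), ultrametric_heights(tree_T1()))
  expect_equal(bracket(prof1, 3), c(k_minus = 2L, k_plus = 4L))
  expect_error(bracket(prof1, 0), class = "pdsets_bad_k")
  expect_error(bracket(prof1, 8), class = "pdsets_bad_k")
})

test_that("component operations insist on ultrametric input", {
  skewed <- parse_newick("((a:1,b:2):1,c:3);")
  expect_error(ultrametric_heights(skewed), class = "pdsets_not_ultrametric")
  expect_error(count_maxpd(skewed, k = 2), class = "pdsets_not_ultrametric")
  expect_error(
    is_maxpd(skewed, leaves = c("a", "c")),
    class = "pdsets_not_ultrametric"
  )
})
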