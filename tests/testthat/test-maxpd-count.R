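test_that("membership test recognises maxPD sets without enumeration", {
  t1 <- tree_T1()
  h <- ultrametric_heights(t1)
  expect_true(is_maxpd(t1, h, c("x3", "x4", "x7")))
  expect_true(is_maxpd(t1, h, c("x2", "x3", "x6")))
  expect_false(is_maxpd(t1, h, c("x5", "x6", "x7"))) # shares a cherry, skips a side
  expect_true(is_maxpd(t1, h, paste0("x", 1:7))) # the full set, k = n
  expect_error(is_maxpd(t1, h, c("x1", "zz")), class = "pdsets_unknown_label")
})

test_that("counts at branching values are products of component sizes", {
  t2 <- tree_T2()
  h2 <- ultrametric_heights(t2)
  prof2 <- branching_profile(t2, h2)
  expect_equal(count_branching(prof2$partitions[["4"]]), 36)
  expect_equal(sort(as.integer(prof2$partitions[["4"]]$sizes)), c(1L, 3L, 3L, 4L))

  p <- tree_mammal_P()
  hp <- ultrametric_heights(p)
  profp <- branching_profile(p, hp)
  expect_equal(sort(as.integer(profp$partitions[["8"]]$sizes)),
               sort(c(1L, 8L, 3L, 2L, 7L, 3L, 5L, 3L)))
  expect_equal(count_branching(profp$partitions[["8"]]), 15120)
  expect_equal(sort(as.integer(profp$partitions[["16"]]$sizes)),
               sort(c(1L, 2L, 4L, 1L, 1L, 3L, 1L, 1L, 2L, 1L, 4L, 3L, 5L, 1L, 1L, 1L)))
  expect_equal(count_branching(profp$partitions[["16"]]), 2880)

  # all-singleton partition (k = n) counts exactly one set
  expect_equal(count_branching(prof2$partitions[["11"]]), 1)
})

test_that("the component array nests short components inside tall ones", {
  t2 <- tree_T2()
  arr <- component_array(t2, k = 5)
  expect_equal(arr$k_minus, 4L)
  expect_equal(arr$k_plus, 7L)
  sizes <- lapply(arr$sizes, function(s) sort(as.integer(s), decreasing = TRUE))
  expect_same_partition(
    lapply(sizes, as.character),
    lapply(list(c(2L, 1L), 1L, c(2L, 2L), c(2L, 1L)), as.character)
  )
  # the seven entries are exactly the short components
  expect_same_partition(
    unlist(arr$columns, recursive = FALSE),
    list(c("x1", "x2"), "x3", "x4", c("x5", "x6"), c("x7", "x8"),
         c("x9", "x10"), "x11")
  )

  arr3 <- component_array(tree_T3(), k = 8)
  expect_equal(arr3$k_minus, 6L)
  expect_equal(arr3$k_plus, 12L)
  keyed <- vapply(
    arr3$sizes, function(s) paste(sort(as.integer(s)), collapse = ","),
    character(1)
  )
  expect_equal(sort(keyed), sort(c("1,1", "1,1", "1,2", "1,2", "1,2", "1,2")))

  # at a branching value every column holds a single short component
  arr_b <- component_array(t2, k = 4)
  expect_true(all(lengths(arr_b$sizes) == 1L))
})

test_that("the generating polynomial expands to the published coefficients", {
  t2 <- tree_T2()
  poly2 <- generating_polynomial(component_array(t2, k = 5))
  got <- setNames(poly2$coef, seq_along(poly2$coef) - 1L)
  expect_equal(got[as.character(4:7)], c("4" = 36, "5" = 84, "6" = 64, "7" = 16))
  expect_true(all(got[as.character(0:3)] == 0))

  poly3 <- generating_polynomial(component_array(tree_T3(), k = 8))
  expect_equal(poly3$coef[8 + 1L], 1809)
  # cross-check the whole expansion against (x^2+2x)^2 (2x^2+3x)^4 done here
  ref <- 1
  mul <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
    out
  }
  for (rep in 1:2) ref <- mul(ref, c(0, 2, 1))
  for (rep in 1:4) ref <- mul(ref, c(0, 3, 2))
  expect_equal(poly3$coef[seq_along(ref)], ref)

  # single column with one n-leaf set: polynomial n * x
  single <- parse_newick("(a:1,b:1,c:1);")
  hs <- ultrametric_heights(single)
  arr1 <- component_array(single, hs, 1)
  expect_equal(generating_polynomial(arr1)$coef, c(0, 3))
})

test_that("count_maxpd reproduces every published count and the trivial ones", {
  t1 <- tree_T1()
  t2 <- tree_T2()
  expect_equal(count_maxpd(t1, k = 3), 20)
  expect_equal(vapply(4:7, function(k) count_maxpd(t2, k = k), numeric(1)),
               c(36, 84, 64, 16))
  expect_equal(count_maxpd(tree_T3(), k = 8), 1809)
  for (tr in list(t1, t2)) {
    expect_equal(count_maxpd(tr, k = n_leaves(tr)), 1)
    expect_equal(count_maxpd(tr, k = 1), n_leaves(tr))
  }
  tab <- maxpd_count_table(t2, k = 6)
  expect_equal(tab$size, 4:7)
  expect_equal(tab$count, c(36, 84, 64, 16))
})

test_that("counting agrees with the exhaustive oracle on random trees", {
  for (tr in random_tree_pool(30, seed = 31)) {
    h <- ultrametric_heights(tr)
    n <- n_leaves(tr)
    for (k in seq_len(n)) {
      oracle <- brute_force_pd(tr, k, "max")
      expect_equal(count_maxpd(tr, h, k), as.numeric(oracle$n_sets))
      for (s in head(oracle$sets, 3)) expect_true(is_maxpd(tr, h, s))
    }
  }
})

test_that("perfect-tree closed form matches the generating-function pipeline", {
  for (alpha in 1:5) {
    tr <- perfect_tree(alpha)
    h <- ultrametric_heights(tr)
    n <- 2^alpha
    for (k in seq_len(n)) {
      expect_equal(count_maxpd(tr, h, k), perfect_tree_count(alpha, k),
                   info = sprintf("alpha=%d k=%d", alpha, k))
    }
  }
  expect_equal(perfect_tree_count(4, 10), 1792)
  expect_equal(perfect_tree_count(5, 21), 8945664)
  expect_equal(perfect_tree_count(3, 8), 1)
  expect_equal(perfect_tree_count(3, 1), 8)
  expect_error(perfect_tree_count(3, 9), class = "pdsets_bad_k")
})

test_that("optimal subset sizes on perfect trees follow the 2n/3 rule", {
  expect_equal(optimal_k_perfect(16), c(10L, 11L))
  expect_equal(optimal_k_perfect(8), 5L)
  expect_equal(optimal_k_perfect(4), c(2L, 3L))
  expect_error(optimal_k_perfect(12), class = "pdsets_bad_n")
  # published ties: n = 8 has k = 3 and k = 5 level at 32; n = 4 has k = 1
  # joining k = 2, 3 at 4 sets
  expect_equal(perfect_tree_count(3, 3), 32)
  expect_equal(perfect_tree_count(3, 5), 32)
  expect_equal(vapply(1:3, function(k) perfect_tree_count(2, k), numeric(1)),
               c(4, 4, 4))
})

test_that("complementation maps maxPD sets to maxPD sets on perfect trees", {
  tr <- perfect_tree(3)
  h <- ultrametric_heights(tr)
  labs <- leaf_labels(tr)
  for (k in 1:4) {
    for (s in head(brute_force_pd(tr, k, "max")$sets, 5)) {
      expect_true(is_maxpd(tr, h, setdiff(labs, s)))
    }
  }
})

test_that("count bounds are sharp at branching values and can fail otherwise", {
  # caterpillars attain the lower bound n - k + 1 at every branching value
  cat10 <- caterpillar_tree(10)
  h <- ultrametric_heights(cat10)
  prof <- branching_profile(cat10, h)
  expect_equal(prof$values, 1:10)
  for (k in 1:10) {
    b <- count_bounds(10, k)
    m <- count_maxpd(cat10, h, k)
    expect_equal(m, unname(b["lower"]))
    expect_lte(m, b["upper"] + 1e-9)
  }
  # bounds hold at branching values on random binary trees
  for (tr in random_tree_pool(10, seed = 32)) {
    ht <- ultrametric_heights(tr)
    pr <- branching_profile(tr, ht)
    for (k in pr$values) {
      b <- count_bounds(n_leaves(tr), k)
      m <- count_maxpd(tr, ht, k)
      expect_gte(m, unname(b["lower"]))
      expect_lte(m, unname(b["upper"]) * (1 + 1e-12))
    }
  }
  # the upper bound is a branching-value statement only: size 5 on the
  # 11-leaf fixture exceeds (11/5)^5
  expect_gt(count_maxpd(tree_T2(), k = 5), count_bounds(11, 5)["upper"])
  expect_equal(unname(count_bounds(9, 9)), c(1, 1))
})
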