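#' Reference fixture trees
#'
#' Small ultrametric trees with integer edge lengths whose diversity
#' quantities are known exactly; they anchor the test suite and make handy
#' worked examples.
#'
#' * `tree_T1()`: 7 leaves `x1..x7`; a triple `{x1,x2,x3}` and a fork
#'   `{x4..x7}`; cherry heights 1, the two root children at height 4, root at
#'   height 6. PD of `{x3,x4,x7}` is 16, of `{x4,x7}` is 10, of `{x5,x6,x7}`
#'   is 11 (the size-3 minimum); total length 23; twenty size-3 maxPD sets.
#' * `tree_T2()`: 11 leaves `x1..x11`, binary, root height 5, branching
#'   values `{1,2,4,7,9,11}`; 36/84/64/16 maxPD sets of sizes 4/5/6/7.
#' * `tree_T3()`: 16 leaves `x01..x16` whose component array at `k = 8` has
#'   two columns of sizes (1,1) and four of sizes (1,2); it has 1809 size-8
#'   maxPD sets — more than the perfect unit-length 16-leaf tree achieves at
#'   its own best size.
#' * `tree_mammal_P()`: a 32-leaf ultrametric tree (multifurcating) whose
#'   recent forests at the branching distances for 8 and 16 components have
#'   leaf counts 1,8,3,2,7,3,5,3 and 1,2,4,1,1,3,1,1,2,1,4,3,5,1,1,1,
#'   mirroring the published component structure of a 32-family mammal
#'   phylogeny; it has 15120 size-8 and 2880 size-16 maxPD sets. Labels are
#'   generic (`m01..m32`); no published quantity depends on the family names
#'   or on topology finer than the two component partitions.
#'
#' @return a [pd_tree].
#' @name fixture_trees
NULL

#' @rdname fixture_trees
#' @export
tree_T1 <- function() {
  parse_newick("(((x1:1,x2:1):3,x3:4):2,((x4:1,x5:1):3,(x6:1,x7:1):3):2);")
}

#' @rdname fixture_trees
#' @export
tree_T2 <- function() {
  parse_newick(paste0(
    "((((x1:1,x2:1):2,x3:3):1,x4:4):1,",
    "(((x5:1,x6:1):2,(x7:2,x8:2):1):1,((x9:2,x10:2):1,x11:3):1):1);"
  ))
}

#' @rdname fixture_trees
#' @export
tree_T3 <- function() {
  ## two size-2 tall components (cherries at height 2) and four size-3 tall
  ## components (leaf + cherry, completed at height 2); remaining merges at
  ## heights 3..6
  a1 <- "(x01:2,x02:2)"
  a2 <- "(x03:2,x04:2)"
  b1 <- "(x05:2,(x06:1,x07:1):1)"
  b2 <- "(x08:2,(x09:1,x10:1):1)"
  b3 <- "(x11:2,(x12:1,x13:1):1)"
  b4 <- "(x14:2,(x15:1,x16:1):1)"
  d1 <- sprintf("(%s:1,%s:1)", a1, b1) # height 3
  d2 <- sprintf("(%s:1,%s:1)", a2, b2) # height 3
  e1 <- sprintf("(%s:1,%s:2)", d1, b3) # height 4
  f1 <- sprintf("(%s:1,%s:3)", e1, b4) # height 5
  parse_newick(sprintf("(%s:1,%s:3);", f1, d2)) # root, height 6
}

#' @rdname fixture_trees
#' @export
tree_mammal_P <- function() {
  ## groups = components at 8; entries = nested components at 16
  groups <- list(1L, c(2L, 4L, 1L, 1L), 3L, c(1L, 1L), c(2L, 1L, 4L), 3L, 5L,
                 c(1L, 1L, 1L))
  lab <- sprintf("m%02d", seq_len(32L))
  nxt <- 0L
  star <- function(s) { # a component: star at height 1, or a bare leaf
    ls <- lab[nxt + seq_len(s)]
    nxt <<- nxt + s
    if (s == 1L) ls else sprintf("(%s)", paste0(ls, ":1", collapse = ","))
  }
  tops <- vapply(groups, function(sz) {
    parts <- vapply(sz, star, character(1))
    ## edge from a component top (height 1, or a leaf at 0) up to the group
    ## vertex at height 3; single-component groups attach straight to the root
    if (length(parts) == 1L) {
      if (sz == 1L) paste0(parts, ":4") else paste0(parts, ":3")
    } else {
      stems <- ifelse(sz == 1L, paste0(parts, ":3"), paste0(parts, ":2"))
      sprintf("(%s):1", paste(stems, collapse = ","))
    }
  }, character(1))
  parse_newick(sprintf("(%s);", paste(tops, collapse = ",")))
}

#' Perfect unit-length tree
#'
#' The complete binary tree of height `alpha` with every edge length 1 and
#' `2^alpha` leaves `p001, p002, ...` — the fully balanced shape whose maxPD
#' counts admit the closed form [perfect_tree_count()].
#'
#' @param alpha tree height, integer `>= 1`.
#' @return a [pd_tree].
#' @export
perfect_tree <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 1 || alpha != round(alpha)) {
    stop_pdsets("alpha must be a positive integer", "pdsets_bad_alpha")
  }
  n <- 2^alpha
  lab <- sprintf("p%0*d", nchar(n), seq_len(n))
  nxt <- 0L
  grow <- function(h) {
    if (h == 0L) {
      nxt <<- nxt + 1L
      return(lab[nxt])
    }
    sprintf("(%s:1,%s:1)", grow(h - 1L), grow(h - 1L))
  }
  parse_newick(paste0(grow(as.integer(alpha)), ";"))
}

#' Ultrametric caterpillar tree
#'
#' A rooted tree with exactly one cherry: leaf `i + 1` joins the path at
#' height `merge_heights[i]`. With the default strictly increasing heights
#' `1, 2, ..., n - 1` every count `1..n` is a branching value, the number of
#' size-k maxPD sets is `n - k + 1` (the sharp lower bound), and for
#' `k >= 2` the minPD set is unique.
#'
#' @param n leaf count, `>= 2`.
#' @param merge_heights strictly increasing positive heights, length `n - 1`.
#' @return a [pd_tree] with leaves `x01, x02, ...` in joining order.
#' @export
caterpillar_tree <- function(n, merge_heights = seq_len(n - 1)) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop_pdsets("n must be an integer >= 2", "pdsets_bad_n")
  }
  h <- merge_heights
  if (length(h) != n - 1 || any(h <= 0) || any(diff(h) <= 0)) {
    stop_pdsets("merge_heights must be strictly increasing and positive, length n - 1",
                "pdsets_bad_heights")
  }
  lab <- sprintf("x%0*d", nchar(as.integer(n)), seq_len(as.integer(n)))
  s <- sprintf("(%s:%g,%s:%g)", lab[1L], h[1L], lab[2L], h[1L])
  for (i in seq_len(n - 2)) {
    s <- sprintf("(%s:%g,%s:%g)", s, h[i + 1L] - h[i], lab[i + 2L], h[i + 1L])
  }
  parse_newick(paste0(s, ";"))
}

#' Seeded random ultrametric tree
#'
#' Coalescent-style generator: `n` lineages start at height 0 and are merged
#' (uniformly at random) at strictly increasing heights until one remains.
#' With probability `tie_prob` a merge reuses the previous merge height,
#' creating simultaneous events and hence skipped branching values; with
#' probability `multif_prob` three lineages merge at once, creating a
#' multifurcation. The same `(n, seed, tie_prob, multif_prob)` always yields
#' the identical tree; the caller's RNG state is left untouched.
#'
#' @param n leaf count, `>= 2`.
#' @param seed integer seed.
#' @param tie_prob probability in `[0, 1)` of reusing the previous merge
#'   height.
#' @param multif_prob probability in `[0, 1)` of a triple merge.
#' @return a [pd_tree] with leaves `t01, t02, ...`.
#' @export
random_ultrametric <- function(n, seed, tie_prob = 0, multif_prob = 0) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop_pdsets("n must be an integer >= 2", "pdsets_bad_n")
  }
  stopifnot(tie_prob >= 0, tie_prob < 1, multif_prob >= 0, multif_prob < 1)
  withr::with_seed(as.integer(seed), {
    lab <- sprintf("t%0*d", nchar(as.integer(n)), seq_len(as.integer(n)))
    frag <- as.list(lab)
    hgt <- numeric(n)
    h <- 0
    prev <- -Inf
    while (length(frag) > 1L) {
      m <- if (length(frag) >= 3L && runif(1) < multif_prob) 3L else 2L
      tie <- length(frag) > m && is.finite(prev) && runif(1) < tie_prob
      if (tie) {
        ## reuse the previous height; only lineages strictly below it qualify
        cand <- which(hgt < prev - 1e-12)
        if (length(cand) >= m) {
          h <- prev
        } else {
          tie <- FALSE
        }
      }
      if (!tie) {
        h <- h + runif(1, 0.5, 1.5)
        cand <- seq_along(frag)
      }
      pick <- sample(cand, m)
      kids <- paste0(
        unlist(frag[pick]), ":",
        format(h - hgt[pick], digits = 15, scientific = FALSE), collapse = ","
      )
      frag[[pick[1L]]] <- sprintf("(%s)", kids)
      hgt[pick[1L]] <- h
      frag <- frag[-pick[-1L]]
      hgt <- hgt[-pick[-1L]]
      prev <- h
    }
    parse_newick(paste0(frag[[1L]], ";"))
  })
}

#' Brute-force PD optimum by exhaustive enumeration
#'
#' Enumerates every size-`k` subset, scores it, and returns the optimum with
#' *all* optimal sets. This is the independent oracle the test suite uses to
#' validate the counting, greedy, optimisation and dynamic-programming
#' routines on small instances. With a leaf score `phi`, also reports the best
#' phi-sum among the PD-optimal sets.
#'
#' @param tree a [pd_tree].
#' @param k subset size in `[1, n]`; `choose(n, k)` must not exceed `1e6`.
#' @param mode `"max"` or `"min"`.
#' @param phi optional named numeric leaf scores.
#' @param tol absolute tolerance for treating two PD values as equal.
#' @return a list with `score`, `sets` (list of sorted label vectors),
#'   `n_sets`, and (when `phi` is given) `best_phi`.
#' @examples
#' brute_force_pd(tree_T1(), 3, "max")$n_sets # 20
#' @export
brute_force_pd <- function(tree, k, mode = c("max", "min"), phi = NULL,
                           tol = 1e-9) {
  stopifnot(inherits(tree, "pd_tree"))
  mode <- match.arg(mode)
  n <- tree$n_tip
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > n ||
      k != round(k)) {
    stop_bad_k(k, n)
  }
  if (choose(n, k) > 1e6) {
    stop_pdsets("instance too large for exhaustive enumeration", "pdsets_too_large")
  }
  if (!is.null(phi)) phi <- check_phi(tree, phi)
  labs <- sort(tree$labels)
  sets <- combn(labs, k, simplify = FALSE)
  scores <- vapply(sets, function(s) pd_score(tree, s), numeric(1))
  opt <- if (mode == "max") max(scores) else min(scores)
  keep <- abs(scores - opt) <= tol
  out <- list(score = opt, sets = sets[keep], n_sets = sum(keep))
  if (!is.null(phi)) {
    out$best_phi <- max(vapply(out$sets, function(s) sum(phi[s]), numeric(1)))
  }
  out
}
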