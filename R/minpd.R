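#' Dynamic-programming table for minimum PD
#'
#' For every vertex `v` and every budget `j`, computes `phi_v(j)`: the minimum
#' PD (measured in the pendant subtree rooted at `v`) over all size-`j`
#' subsets of the leaves below `v`, with `phi_v(0) = 0` and `phi_leaf(1) = 0`
#' (a single vertex has no edges). Children are combined in canonical order by
#' pairwise min-plus convolution of `phi_child(j) + len_child * [j > 0]`,
#' which realises the joint minimisation over all ways of splitting the budget
#' among any number of children — multifurcations need no special casing and
#' the ultrametric condition is *not* required. Choice indices are recorded so
#' an optimal set can be recovered ([minpd_set()]).
#'
#' Ties are broken by preferring a smaller budget in the left (earlier, in
#' canonical child order) operand, making the recovered set deterministic.
#'
#' @param tree a [pd_tree] (any positive edge lengths).
#' @param k_max largest budget to tabulate (default `n`).
#' @return an object of class `minpd_table` holding the per-vertex vectors and
#'   backpointers. Use [tidy()] for the root profile and [minpd_score()] /
#'   [minpd_set()] for direct answers.
#' @examples
#' tab <- minpd_table(tree_T1())
#' tidy(tab) # min PD for every size k
#' @export
minpd_table <- function(tree, k_max = n_leaves(tree)) {
  stopifnot(inherits(tree, "pd_tree"))
  n <- tree$n_tip
  if (!is.numeric(k_max) || length(k_max) != 1L || is.na(k_max) || k_max < 0 ||
      k_max > n || k_max != round(k_max)) {
    stop_pdsets(sprintf("k_max must be an integer in [0, %d]", n), "pdsets_bad_k")
  }
  k_max <- as.integer(k_max)
  phi <- vector("list", tree$n_vertex)
  choice <- vector("list", tree$n_vertex) # per fold step: left budget per total
  n_below <- integer(tree$n_vertex)
  for (v in tree$postorder) {
    if (v <= tree$n_tip) {
      phi[[v]] <- c(0, if (k_max >= 1L) 0) # budgets 0 and 1
      n_below[v] <- 1L
      next
    }
    kids <- tree$children[[v]]
    g <- function(c) { # child vector with the edge toll on non-empty budgets
      out <- phi[[c]]
      if (length(out) > 1L) out[-1L] <- out[-1L] + tree$edge_len[c]
      out
    }
    acc <- g(kids[1L])
    n_acc <- n_below[kids[1L]]
    steps <- vector("list", length(kids) - 1L)
    for (j in seq_along(kids)[-1L]) {
      gj <- g(kids[j])
      cap <- min(n_acc + n_below[kids[j]], k_max)
      new <- numeric(cap + 1L)
      pick <- integer(cap + 1L)
      for (tot in 0:cap) {
        lo <- max(0L, tot - (length(gj) - 1L))
        hi <- min(tot, length(acc) - 1L)
        cand <- acc[(lo:hi) + 1L] + gj[(tot - lo:hi) + 1L]
        best <- which.min(cand) # first minimum = smallest left budget
        new[tot + 1L] <- cand[best]
        pick[tot + 1L] <- lo + best - 1L
      }
      steps[[j - 1L]] <- pick
      acc <- new
      n_acc <- n_acc + n_below[kids[j]]
    }
    phi[[v]] <- acc
    choice[[v]] <- steps
    n_below[v] <- n_acc
  }
  structure(
    list(tree = tree, k_max = k_max, phi = phi, choice = choice, n_below = n_below),
    class = "minpd_table"
  )
}

#' @export
print.minpd_table <- function(x, ...) {
  cat(sprintf(
    "<minpd_table> %d leaves, budgets 0..%d; min PD at root: %s\n",
    x$tree$n_tip, x$k_max,
    paste(format(x$phi[[x$tree$root]], digits = 6), collapse = " ")
  ))
  invisible(x)
}

#' @method tidy minpd_table
#' @export
tidy.minpd_table <- function(x, ...) {
  root_phi <- x$phi[[x$tree$root]]
  tibble::tibble(k = seq_along(root_phi) - 1L, min_pd = root_phi)
}

#' @method glance minpd_table
#' @export
glance.minpd_table <- function(x, ...) {
  tibble::tibble(
    n = x$tree$n_tip, k_max = x$k_max, total_pd = total_pd(x$tree)
  )
}

#' @method autoplot minpd_table
#' @export
autoplot.minpd_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = k, y = min_pd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "subset size k", y = "minimum PD",
      title = "Minimum PD of k leaves"
    )
}

#' Minimum PD of k leaves
#'
#' The smallest PD attainable by any size-`k` leaf subset, from the dynamic
#' program of [minpd_table()]. Unlike the maximisation problem this is *not*
#' solved by a greedy algorithm.
#'
#' @param tree a [pd_tree].
#' @param k subset size in `[0, n]` (`k = 0` gives 0 by convention).
#' @return a single non-negative number.
#' @examples
#' minpd_score(tree_T1(), 3) # 11
#' @export
minpd_score <- function(tree, k) {
  tab <- minpd_table(tree, k_max = check_minpd_k(tree, k))
  tab$phi[[tab$tree$root]][k + 1L]
}

check_minpd_k <- function(tree, k) {
  n <- n_leaves(tree)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > n ||
      k != round(k)) {
    stop_bad_k(k, n)
  }
  as.integer(k)
}

#' Recover a minimum-PD set
#'
#' Walks the backpointers of the dynamic program to produce one size-`k`
#' subset attaining [minpd_score()]. Ties were resolved deterministically
#' during tabulation, so the same tree and `k` always yield the same set.
#'
#' @param tree a [pd_tree].
#' @param k subset size in `[1, n]`.
#' @return sorted character vector of `k` leaf labels whose PD equals
#'   `minpd_score(tree, k)` exactly.
#' @examples
#' minpd_set(tree_T1(), 3) # a triple with PD 11
#' @export
minpd_set <- function(tree, k) {
  k <- check_minpd_k(tree, k)
  if (k == 0L) return(character(0))
  tab <- minpd_table(tree, k_max = k)
  tree <- tab$tree
  out <- integer(0)
  recover <- function(v, budget) {
    if (budget == 0L) return(invisible())
    if (v <= tree$n_tip) {
      out <<- c(out, v)
      return(invisible())
    }
    kids <- tree$children[[v]]
    budgets <- integer(length(kids))
    b <- budget
    for (j in rev(seq_along(kids)[-1L])) {
      left <- tab$choice[[v]][[j - 1L]][b + 1L]
      budgets[j] <- b - left
      b <- left
    }
    budgets[1L] <- b
    for (j in seq_along(kids)) recover(kids[j], budgets[j])
  }
  recover(tree$root, k)
  sort(tree$labels[out])
}

#' Maximum possible PD loss under t extinctions
#'
#' If `t` of the `n` species go extinct, the greatest possible loss of
#' diversity is `PD(X) - min PD over size-(n - t) subsets`: the worst case is
#' that the survivors form a minimum-PD set. Computed via [minpd_score()] by
#' this duality.
#'
#' @param tree a [pd_tree].
#' @param t number of extinctions, `0 <= t <= n`.
#' @return a single non-negative number.
#' @examples
#' max_pd_loss(tree_T1(), 4) # 23 - 11 = 12
#' @export
max_pd_loss <- function(tree, t) {
  n <- n_leaves(tree)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > n ||
      t != round(t)) {
    stop_pdsets(sprintf("t must be an integer in [0, %d]", n), "pdsets_bad_k")
  }
  total_pd(tree) - minpd_score(tree, n - as.integer(t))
}
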