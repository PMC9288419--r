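#' Phylogenetic diversity of a leaf subset
#'
#' The phylogenetic diversity (PD) of a non-empty subset `Y` of leaves is the
#' sum of edge lengths of the minimal subtree connecting `Y` to the root: an
#' edge contributes iff its cluster intersects `Y`. PD is computed by marking
#' the subtree in one upward traversal per leaf; no tree surgery is performed.
#'
#' @param tree a [pd_tree].
#' @param leaves character vector of distinct leaf labels (non-empty).
#' @return a single non-negative number, in the units of the input lengths.
#' @examples
#' pd_score(tree_T1(), c("x3", "x4", "x7")) # 16
#' @export
pd_score <- function(tree, leaves) {
  stopifnot(inherits(tree, "pd_tree"))
  if (length(leaves) == 0L) {
    stop_pdsets("PD of the empty set is undefined; pass at least one leaf", "pdsets_empty_set")
  }
  tips <- match_labels(tree, leaves)
  if (tree$n_vertex == 1L) return(0)
  marked <- logical(tree$n_vertex)
  total <- 0
  for (v in tips) {
    while (v != tree$root && !marked[v]) {
      marked[v] <- TRUE
      total <- total + tree$edge_len[v]
      v <- tree$parent[v]
    }
  }
  total
}

#' PD loss under extinction
#'
#' The PD loss of a set `Y` is `PD(X) - PD(X - Y)`: the diversity that
#' disappears if exactly the species in `Y` go extinct (also known as
#' exclusive molecular phylodiversity). By convention the loss of the full
#' leaf set is `PD(X)` and the loss of the empty set is 0.
#'
#' @param tree a [pd_tree].
#' @param leaves character vector of leaf labels going extinct (may be empty).
#' @return a single non-negative number.
#' @examples
#' pd_loss(tree_T1(), c("x1", "x2")) # 5
#' @export
pd_loss <- function(tree, leaves) {
  stopifnot(inherits(tree, "pd_tree"))
  if (length(leaves) == 0L) return(0)
  tips <- match_labels(tree, leaves)
  keep <- setdiff(tree$labels, tree$labels[tips])
  if (length(keep) == 0L) return(total_pd(tree))
  total_pd(tree) - pd_score(tree, keep)
}

#' Greedy construction of a maximum-PD set
#'
#' Builds a size-`k` subset by repeatedly adding the leaf with the largest
#' marginal PD gain (ties broken lexicographically by label). On rooted trees
#' with positive edge lengths this greedy procedure is provably optimal: the
#' returned score equals the maximum PD over all size-`k` subsets. Which
#' optimal set is returned depends on the tie-break; use [count_maxpd()] to
#' count all of them and [maximise_linear_sum()] to pick among them.
#'
#' @param tree a [pd_tree] (ultrametricity not required).
#' @param k subset size, `1 <= k <= n`.
#' @return a list with `leaves` (sorted character vector of size `k`) and
#'   `score` (the maximum PD).
#' @examples
#' greedy_maxpd(tree_T1(), 3)$score # 16
#' @export
greedy_maxpd <- function(tree, k) {
  stopifnot(inherits(tree, "pd_tree"))
  n <- tree$n_tip
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > n || k != round(k)) {
    stop_bad_k(k, n)
  }
  k <- as.integer(k)
  if (tree$n_vertex == 1L) return(list(leaves = tree$labels, score = 0))
  ord <- order(tree$labels)
  cand <- (seq_len(n))[ord] # tips in lexicographic label order
  marked <- logical(tree$n_vertex)
  chosen <- integer(0)
  score <- 0
  gain_of <- function(tip) {
    g <- 0
    v <- tip
    while (v != tree$root && !marked[v]) {
      g <- g + tree$edge_len[v]
      v <- tree$parent[v]
    }
    g
  }
  for (step in seq_len(k)) {
    gains <- vapply(cand, gain_of, numeric(1))
    best <- which.max(gains) # first max = lexicographically smallest label
    tip <- cand[best]
    score <- score + gains[best]
    v <- tip
    while (v != tree$root && !marked[v]) {
      marked[v] <- TRUE
      v <- tree$parent[v]
    }
    chosen <- c(chosen, tip)
    cand <- cand[-best]
  }
  list(leaves = sort(tree$labels[chosen]), score = score)
}
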