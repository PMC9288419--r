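#' Maximise a linear leaf score over all maxPD sets
#'
#' Given a real-valued score `phi` on the leaves (a conservation benefit, an
#' IUCN-derived weight, ...), finds a size-`k` maxPD set whose total score is
#' largest among *all* size-`k` maxPD sets, without enumerating them. The
#' algorithm works in four stages on the component structure of the bracket
#' `[k-, k+]`:
#'
#' 1. compute the tall components (at `d[k-]`) and short components (at
#'    `d[k+]`);
#' 2. keep one leaf of maximal score per short component (the "potential"
#'    leaves `P`);
#' 3. put into `A` one maximal-score leaf of `P` per tall component;
#' 4. fill `A` with the `k - k-` highest-scoring remaining leaves of `P`.
#'
#' The output is always a maxPD set and its score is optimal among maxPD sets.
#' All score ties are broken lexicographically by label (any choice is
#' optimal; the fixed rule makes the output deterministic).
#'
#' Note that the seemingly natural shortcut of adding `phi(x)` to each pendant
#' edge and running the greedy maxPD algorithm is *not* correct; it is
#' provided as [naive_pendant_augmentation()] for comparison only.
#'
#' @param tree a [pd_tree] with ultrametric edge lengths.
#' @param heights optional `pd_heights`; `NULL` to compute.
#' @param phi named numeric vector mapping every leaf label to a score (any
#'   sign).
#' @param k subset size in `[1, n]`.
#' @return a list with `leaves` (sorted size-k character vector), `score`
#'   (the phi-sum) and `pd` (its PD, the size-k maximum).
#' @examples
#' tr <- tree_T1()
#' f <- setNames(c(1, 1, 1, 1, 100, 100, 100), paste0("x", 1:7))
#' maximise_linear_sum(tr, phi = f, k = 3)$score # 201
#' @export
maximise_linear_sum <- function(tree, heights = NULL, phi, k) {
  stopifnot(inherits(tree, "pd_tree"))
  if (is.null(heights)) heights <- ultrametric_heights(tree)
  phi <- check_phi(tree, phi)
  n <- tree$n_tip
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > n || k != round(k)) {
    stop_bad_k(k, n)
  }
  arr <- component_array(tree, heights, k)
  ## stage 2: one max-phi leaf per short component (ties: smallest label)
  pick_max <- function(labels) {
    labels[order(-phi[labels], labels)][1L]
  }
  p_by_col <- lapply(arr$columns, function(col) vapply(col, pick_max, character(1)))
  ## stage 3: one max-phi potential leaf per tall component
  a <- vapply(p_by_col, pick_max, character(1))
  ## stage 4: top up with the k - k_minus best remaining potential leaves
  rest <- setdiff(unlist(p_by_col, use.names = FALSE), a)
  need <- k - arr$k_minus
  if (need > 0L) {
    rest <- rest[order(-phi[rest], rest)]
    a <- c(a, rest[seq_len(need)])
  }
  a <- sort(a)
  list(leaves = a, score = sum(phi[a]), pd = pd_score(tree, a))
}

check_phi <- function(tree, phi) {
  if (is.null(names(phi)) || !is.numeric(phi)) {
    stop_pdsets("phi must be a named numeric vector over the leaf labels", "pdsets_bad_phi")
  }
  missing <- setdiff(tree$labels, names(phi))
  if (length(missing)) {
    stop_pdsets(
      sprintf("phi is missing leaf label(s): %s", paste(missing, collapse = ", ")),
      "pdsets_bad_phi"
    )
  }
  unknown <- setdiff(names(phi), tree$labels)
  if (length(unknown)) stop_unknown_label(unknown)
  if (anyNA(phi)) stop_pdsets("phi must not contain NA", "pdsets_bad_phi")
  phi
}

#' Pendant-edge augmentation baseline (incorrect on purpose)
#'
#' Adds each leaf's score to the length of its pendant edge and runs the
#' greedy maxPD construction on the augmented tree. This folkloric shortcut
#' does *not* in general return a maxPD set of the original tree: on the
#' 7-leaf fixture [tree_T1()] with scores 1/1/1/1/100/100/100 it returns the
#' three high-score leaves, which form a *minimum*-PD triple. It is exported
#' solely as a documented baseline for regression tests and comparisons; use
#' [maximise_linear_sum()] for the correct optimisation.
#'
#' @param tree a [pd_tree].
#' @param phi named numeric leaf scores; augmented pendant lengths must stay
#'   positive.
#' @param k subset size.
#' @return a list with `leaves` (sorted) and `augmented_score` (the greedy PD
#'   score on the augmented tree).
#' @export
naive_pendant_augmentation <- function(tree, phi, k) {
  stopifnot(inherits(tree, "pd_tree"))
  phi <- check_phi(tree, phi)
  aug <- tree
  tips <- seq_len(tree$n_tip)
  aug$edge_len[tips] <- aug$edge_len[tips] + phi[aug$labels[tips]]
  if (any(!is.na(aug$edge_len[tips]) & aug$edge_len[tips] <= 0)) {
    stop_pdsets("augmented pendant lengths must remain positive", "pdsets_bad_phi")
  }
  res <- greedy_maxpd(aug, k)
  list(leaves = res$leaves, augmented_score = res$score)
}

#' Read a leaf-score table
#'
#' Two-column tab-separated file: leaf label, numeric score. A header line is
#' detected (and skipped) when the second field is non-numeric.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_leaf_scores <- function(path) {
  if (!file.exists(path)) stop_pdsets(sprintf("no such file: %s", path), "pdsets_io")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("label", "score"),
                          colClasses = c("character", "character"))
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df$score[1L])))) {
    df <- df[-1L, , drop = FALSE]
  }
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score)) stop_pdsets("non-numeric score values in table", "pdsets_bad_phi")
  setNames(score, df$label)
}
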