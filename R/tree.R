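#' Rooted edge-weighted phylogenetic trees
#'
#' `pd_tree` is the tree container used throughout the package: a rooted tree
#' with uniquely labelled leaves and a strictly positive length on every edge.
#' Trees are normally created by [parse_newick()] or [read_newick()], or
#' converted from an [ape::phylo] object with [as_pd_tree()].
#'
#' Internally vertices are integer ids `1..n_vertex`, with tips `1..n_tip`
#' (matching ape's convention). Unifurcations are suppressed at construction,
#' summing the lengths of the two incident edges, so every internal vertex has
#' out-degree at least two. Children of every vertex are held in canonical
#' order: sorted by the lexicographically smallest leaf label below them, which
#' makes all derived collections (components, recovered sets) deterministic.
#'
#' @param x object to convert.
#' @name pd_tree
NULL

new_pd_tree <- function(parent, edge_len, labels, root) {
  n_tip <- length(labels)
  n_vertex <- length(parent)
  tree <- structure(
    list(
      n_tip = n_tip, n_vertex = n_vertex, root = root,
      parent = parent, edge_len = edge_len, labels = labels,
      children = vector("list", n_vertex)
    ),
    class = "pd_tree"
  )
  tree <- index_pd_tree(tree)
  validate_pd_tree(tree)
  tree
}

## Fills children lists (canonical order), a postorder, and the smallest leaf
## label below each vertex.
index_pd_tree <- function(tree) {
  n_vertex <- tree$n_vertex
  kids <- vector("list", n_vertex)
  for (v in seq_len(n_vertex)) kids[[v]] <- integer(0)
  for (v in seq_len(n_vertex)) {
    p <- tree$parent[v]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], v)
  }
  ## postorder: children before parents; depth-descending order suffices
  depth <- integer(n_vertex)
  ord <- order_preorder(tree$parent, tree$root, kids)
  for (v in ord) {
    p <- tree$parent[v]
    depth[v] <- if (is.na(p)) 0L else depth[p] + 1L
  }
  post <- order(depth, decreasing = TRUE)
  minlab <- character(n_vertex)
  for (v in post) {
    minlab[v] <- if (length(kids[[v]]) == 0L) {
      tree$labels[v]
    } else {
      min(minlab[kids[[v]]])
    }
  }
  for (v in seq_len(n_vertex)) {
    if (length(kids[[v]]) > 1L) kids[[v]] <- kids[[v]][order(minlab[kids[[v]]])]
  }
  tree$children <- kids
  tree$postorder <- post
  tree$minlab <- minlab
  tree
}

order_preorder <- function(parent, root, kids) {
  out <- integer(length(parent))
  stack <- root
  i <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    i <- i + 1L
    out[i] <- v
    stack <- c(stack, kids[[v]])
  }
  out
}

validate_pd_tree <- function(tree) {
  labs <- tree$labels
  if (any(!nzchar(labs)) || anyNA(labs)) {
    stop_malformed("every leaf must carry a non-empty label")
  }
  if (anyDuplicated(labs)) {
    stop_malformed(sprintf(
      "duplicate leaf label(s): %s",
      paste(unique(labs[duplicated(labs)]), collapse = ", ")
    ))
  }
  len <- tree$edge_len[-tree$root]
  if (tree$n_vertex > 1L && (anyNA(len) || any(!is.finite(len)) || any(len <= 0))) {
    stop_malformed("every edge must carry a finite, strictly positive length")
  }
  deg <- lengths(tree$children)
  internal <- which(deg > 0L & seq_len(tree$n_vertex) != tree$root)
  if (any(deg[internal] < 2L)) {
    stop_malformed("internal vertices must have out-degree at least 2")
  }
  invisible(tree)
}

#' Number of leaves and leaf labels
#'
#' @param tree a [pd_tree].
#' @return `n_leaves()` returns the leaf count `n`; `leaf_labels()` the sorted
#'   character vector of leaf labels.
#' @export
n_leaves <- function(tree) {
  stopifnot(inherits(tree, "pd_tree"))
  tree$n_tip
}

#' @rdname n_leaves
#' @export
leaf_labels <- function(tree) {
  stopifnot(inherits(tree, "pd_tree"))
  sort(tree$labels)
}

#' Parse a rooted Newick tree
#'
#' Reads a single rooted tree in Newick format. Every non-root edge must carry
#' a strictly positive length; a length attached to the root is ignored with a
#' warning (diversity is measured from the root, so a root edge contributes
#' nothing). Unifurcations are suppressed, summing lengths. Multifurcations are
#' preserved. The degenerate single-leaf tree `"A;"` is representable.
#'
#' @param text a length-one character string containing the tree.
#' @return a [pd_tree].
#' @examples
#' tr <- parse_newick("((a:1,b:1):2,c:3);")
#' n_leaves(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop_malformed("expected a single Newick string")
  }
  txt <- trimws(text)
  if (!nzchar(txt)) stop_malformed("empty Newick string")
  if (!grepl(";", txt, fixed = TRUE)) txt <- paste0(txt, ";")
  if (!grepl("(", txt, fixed = TRUE)) {
    ## single-vertex tree: one labelled leaf, no edges
    lab <- trimws(sub(";.*$", "", txt))
    if (grepl(":", lab, fixed = TRUE)) {
      warning("length on the root of a single-vertex tree ignored")
      lab <- sub(":.*$", "", lab)
    }
    if (!nzchar(lab)) stop_malformed("single-vertex tree must be labelled")
    return(new_pd_tree(
      parent = NA_integer_, edge_len = NA_real_, labels = lab, root = 1L
    ))
  }
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop_malformed("malformed Newick string")
  }
  if (!is.null(phy$root.edge)) {
    warning("edge length on the root ignored")
    phy$root.edge <- NULL
  }
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge)) {
    stop_malformed("every edge must carry a length")
  }
  phy <- ape::collapse.singles(phy)
  as_pd_tree(phy)
}

#' Read a Newick tree from a file
#'
#' @param path path to a file whose first line holds one rooted Newick tree.
#' @return a [pd_tree].
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_pdsets(sprintf("no such file: %s", path), "pdsets_io")
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' @rdname pd_tree
#' @export
as_pd_tree <- function(x) UseMethod("as_pd_tree")

#' @export
as_pd_tree.pd_tree <- function(x) x

#' @export
as_pd_tree.phylo <- function(x) {
  n_tip <- length(x$tip.label)
  n_vertex <- n_tip + x$Nnode
  parent <- rep(NA_integer_, n_vertex)
  edge_len <- rep(NA_real_, n_vertex)
  parent[x$edge[, 2L]] <- x$edge[, 1L]
  if (!is.null(x$edge.length)) edge_len[x$edge[, 2L]] <- x$edge.length
  new_pd_tree(
    parent = parent, edge_len = edge_len,
    labels = as.character(x$tip.label), root = n_tip + 1L
  )
}

#' @export
as_pd_tree.character <- function(x) parse_newick(x)

#' Convert a pd_tree to an ape phylo object
#'
#' The single-vertex tree has no `phylo` representation and raises an error.
#'
#' @param x a [pd_tree].
#' @param ... unused.
#' @method as.phylo pd_tree
#' @export
as.phylo.pd_tree <- function(x, ...) {
  if (x$n_vertex == 1L) {
    stop_pdsets("the single-vertex tree has no phylo representation", "pdsets_degenerate")
  }
  child <- which(!is.na(x$parent))
  edge <- cbind(x$parent[child], child)
  phy <- structure(
    list(
      edge = edge, edge.length = x$edge_len[child],
      tip.label = x$labels, Nnode = x$n_vertex - x$n_tip
    ),
    class = "phylo", order = "cladewise"
  )
  phy
}

#' Serialise a tree to Newick
#'
#' Round-trips with [parse_newick()]: topology, labels and lengths are
#' preserved (lengths to R's default print precision).
#'
#' @param tree a [pd_tree].
#' @param digits number of significant digits for edge lengths.
#' @return a Newick string ending in `";"`.
#' @export
write_newick <- function(tree, digits = 15L) {
  stopifnot(inherits(tree, "pd_tree"))
  if (tree$n_vertex == 1L) return(paste0(tree$labels, ";"))
  fmt <- function(v) {
    if (v <= tree$n_tip) {
      lab <- tree$labels[v]
    } else {
      lab <- paste0(
        "(", paste(vapply(tree$children[[v]], fmt, character(1)), collapse = ","), ")"
      )
    }
    if (v == tree$root) {
      paste0(lab)
    } else {
      paste0(lab, ":", format(tree$edge_len[v], digits = digits, scientific = FALSE))
    }
  }
  paste0(fmt(tree$root), ";")
}

#' Leaf cluster below a vertex
#'
#' The cluster of a vertex `v` is the set of leaf labels descended from it
#' (including `v` itself when `v` is a leaf). The root's cluster is the whole
#' taxon set.
#'
#' @param tree a [pd_tree].
#' @param v integer vertex id (tips are `1..n_leaves(tree)`).
#' @return sorted character vector of leaf labels.
#' @export
tree_cluster <- function(tree, v) {
  stopifnot(inherits(tree, "pd_tree"))
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v > tree$n_vertex) {
    stop_pdsets(sprintf("unknown vertex id: %s", format(v)), "pdsets_unknown_vertex")
  }
  v <- as.integer(v)
  tips <- integer(0)
  stack <- v
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (u <= tree$n_tip) tips <- c(tips, u) else stack <- c(stack, tree$children[[u]])
  }
  sort(tree$labels[tips])
}

## tip ids for a set of labels, with validation
match_labels <- function(tree, labels) {
  idx <- match(labels, tree$labels)
  if (anyNA(idx)) stop_unknown_label(labels[is.na(idx)])
  if (anyDuplicated(labels)) {
    stop_pdsets("leaf labels must be distinct", "pdsets_duplicate_label")
  }
  idx
}

## leaf tip ids below each vertex, as a list (used by several modules)
tips_below <- function(tree) {
  below <- vector("list", tree$n_vertex)
  for (v in tree$postorder) {
    below[[v]] <- if (v <= tree$n_tip) v else unlist(below[tree$children[[v]]], use.names = FALSE)
  }
  below
}

#' @export
print.pd_tree <- function(x, ...) {
  cat(sprintf(
    "<pd_tree> %d leaves, %d vertices, total edge length %g\n",
    x$n_tip, x$n_vertex, total_pd(x)
  ))
  labs <- leaf_labels(x)
  cat("  leaves:", paste(head(labs, 8L), collapse = ", "),
      if (length(labs) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Total tree length
#'
#' The sum of all edge lengths, i.e. the phylogenetic diversity of the full
#' taxon set.
#'
#' @param tree a [pd_tree].
#' @export
total_pd <- function(tree) {
  stopifnot(inherits(tree, "pd_tree"))
  if (tree$n_vertex == 1L) return(0)
  sum(tree$edge_len[-tree$root])
}
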