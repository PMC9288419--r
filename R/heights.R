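#' Validate the ultrametric condition and compute vertex heights
#'
#' A tree is ultrametric (clock-like) when every root-to-leaf path has the same
#' total length. In that case every vertex has a well-defined height: its
#' distance to any descendant leaf (0 at the leaves). Heights are reported as
#' the mean of the descendant-leaf distances, which coincides with the common
#' value up to the tolerance.
#'
#' The check is relative: two path lengths are considered equal when they
#' differ by at most `tolerance`. The default is `1e-9` times the root height,
#' floored at `1e-12`, which absorbs rounding of decimal lengths in Newick
#' files while rejecting genuinely unequal depths.
#'
#' @param tree a [pd_tree].
#' @param tolerance absolute tolerance for comparing path lengths; `NULL`
#'   (default) uses the relative rule above.
#' @return an object of class `pd_heights`: a list with `height` (numeric, one
#'   entry per vertex id), `root_height`, and the `tolerance` used.
#' @examples
#' tr <- parse_newick("((a:1,b:1):2,c:3);")
#' ultrametric_heights(tr)$root_height
#' @export
ultrametric_heights <- function(tree, tolerance = NULL) {
  stopifnot(inherits(tree, "pd_tree"))
  n_vertex <- tree$n_vertex
  if (n_vertex == 1L) {
    return(structure(
      list(height = 0, root_height = 0, tolerance = 1e-12),
      class = "pd_heights"
    ))
  }
  ## min/max/sum of vertex-to-descendant-leaf distances, plus a witness leaf
  hmin <- hmax <- hsum <- numeric(n_vertex)
  nlf <- integer(n_vertex)
  wmin <- wmax <- integer(n_vertex) # tip id realising hmin/hmax
  for (v in tree$postorder) {
    if (v <= tree$n_tip) {
      hmin[v] <- hmax[v] <- hsum[v] <- 0
      nlf[v] <- 1L
      wmin[v] <- wmax[v] <- v
    } else {
      kids <- tree$children[[v]]
      lo <- hmin[kids] + tree$edge_len[kids]
      hi <- hmax[kids] + tree$edge_len[kids]
      i_lo <- which.min(lo)
      i_hi <- which.max(hi)
      hmin[v] <- lo[i_lo]
      hmax[v] <- hi[i_hi]
      wmin[v] <- wmin[kids[i_lo]]
      wmax[v] <- wmax[kids[i_hi]]
      hsum[v] <- sum(hsum[kids] + tree$edge_len[kids] * nlf[kids])
      nlf[v] <- sum(nlf[kids])
    }
  }
  root_height <- hsum[tree$root] / nlf[tree$root]
  eps <- if (is.null(tolerance)) max(1e-9 * root_height, 1e-12) else tolerance
  spread <- hmax - hmin
  bad <- which(spread > eps)
  if (length(bad)) {
    v <- bad[which.max(spread[bad])]
    stop_not_ultrametric(tree$labels[wmin[v]], tree$labels[wmax[v]], spread[v])
  }
  structure(
    list(height = hsum / nlf, root_height = root_height, tolerance = eps),
    class = "pd_heights"
  )
}

#' @export
print.pd_heights <- function(x, ...) {
  cat(sprintf(
    "<pd_heights> root height %g (tolerance %g)\n", x$root_height, x$tolerance
  ))
  invisible(x)
}
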