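#' Forest of recent vertices
#'
#' For a cut distance `d`, the recent vertices `R(d)` of an ultrametric tree
#' are those within distance `d` of the leaves, i.e. with height at most `d`.
#' The subgraph induced on `R(d)` is a forest; its connected components
#' partition the leaf set and are the combinatorial core of maxPD counting:
#' every size-k maxPD set takes at least one leaf per component of the tall
#' forest and at most one per component of the short forest (see
#' [is_maxpd()]).
#'
#' @param tree a [pd_tree].
#' @param heights a `pd_heights` object from [ultrametric_heights()].
#' @param d non-negative cut distance (heights within the stored tolerance of
#'   `d` count as recent, matching the defining "at most d").
#' @return an object of class `component_partition`: a list with `d`,
#'   `components` (list of sorted leaf-label vectors, ordered by smallest
#'   member), and `sizes` (integer leaf counts).
#' @examples
#' tr <- tree_T1()
#' h <- ultrametric_heights(tr)
#' recent_forest(tr, h, 1)$sizes # 2 1 2 2
#' @export
recent_forest <- function(tree, heights, d) {
  stopifnot(inherits(tree, "pd_tree"), inherits(heights, "pd_heights"))
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0) {
    stop_pdsets("cut distance d must be a single non-negative number", "pdsets_bad_distance")
  }
  eps <- heights$tolerance
  in_r <- heights$height <= d + eps
  ## R(d) is closed under descendants, so components are clusters of the
  ## maximal recent vertices
  tops <- which(in_r & (seq_len(tree$n_vertex) == tree$root | !in_r[tree$parent]))
  comps <- lapply(tops, function(v) tree_cluster(tree, v))
  ord <- order(vapply(comps, `[`, character(1), 1L))
  comps <- comps[ord]
  structure(
    list(d = d, components = comps, sizes = lengths(comps)),
    class = "component_partition"
  )
}

#' @export
print.component_partition <- function(x, ...) {
  cat(sprintf(
    "<component_partition> d = %g: %d component(s), sizes %s\n",
    x$d, length(x$components), paste(x$sizes, collapse = " ")
  ))
  invisible(x)
}

#' @method tidy component_partition
#' @export
tidy.component_partition <- function(x, ...) {
  tibble::tibble(
    component = rep(seq_along(x$components), x$sizes),
    leaf = unlist(x$components, use.names = FALSE)
  )
}

#' Branching values and distances of an ultrametric tree
#'
#' The component count `c(d)` of the recent forest is a non-increasing step
#' function of the cut distance `d`, jumping only at vertex heights. An integer
#' `k` is a *branching value* when `c(d) = k` for some `d`; the *branching
#' distance* `d_k` is the smallest such `d`. Both `1` and `n` are always
#' branching values. Heights equal within the stored tolerance are treated as
#' one simultaneous merge event, which is what makes intermediate counts
#' skippable.
#'
#' @param tree a [pd_tree].
#' @param heights a `pd_heights` object from [ultrametric_heights()].
#' @return an object of class `branching_profile`: a list with `values`
#'   (increasing integer vector), `d` (named numeric, `d[k]`), `partitions`
#'   (named list of `component_partition` at each `d_k`), and `n`.
#' @examples
#' tr <- tree_T2()
#' branching_profile(tr, ultrametric_heights(tr))$values # 1 2 4 7 9 11
#' @export
branching_profile <- function(tree, heights) {
  stopifnot(inherits(tree, "pd_tree"), inherits(heights, "pd_heights"))
  eps <- heights$tolerance
  hs <- sort(heights$height)
  ## group heights equal within eps; the group minimum is the event distance
  reps <- numeric(0)
  for (h in hs) {
    if (length(reps) == 0L || h - reps[length(reps)] > eps) reps <- c(reps, h)
  }
  values <- integer(0)
  d_k <- numeric(0)
  partitions <- list()
  for (d in reps) {
    part <- recent_forest(tree, heights, d)
    cc <- length(part$components)
    if (!(cc %in% values)) { # first (smallest) d attaining this count
      values <- c(values, cc)
      d_k <- c(d_k, d)
      partitions[[as.character(cc)]] <- part
    }
  }
  ord <- order(values)
  structure(
    list(
      values = values[ord], d = setNames(d_k[ord], values[ord]),
      partitions = partitions, n = tree$n_tip
    ),
    class = "branching_profile"
  )
}

#' @export
print.branching_profile <- function(x, ...) {
  cat(sprintf(
    "<branching_profile> n = %d; branching values: %s\n",
    x$n, paste(x$values, collapse = ", ")
  ))
  invisible(x)
}

#' @method tidy branching_profile
#' @export
tidy.branching_profile <- function(x, ...) {
  tibble::tibble(
    k = x$values,
    d = unname(x$d[as.character(x$values)]),
    component_sizes = lapply(
      as.character(x$values),
      function(key) as.integer(x$partitions[[key]]$sizes)
    )
  )
}

#' @method glance branching_profile
#' @export
glance.branching_profile <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_branching_values = length(x$values),
    d_root = unname(x$d[as.character(1L)])
  )
}

#' @method autoplot branching_profile
#' @export
autoplot.branching_profile <- function(object, ...) {
  df <- tidy(object)[, c("k", "d")]
  ggplot2::ggplot(df, ggplot2::aes(x = d, y = k)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "cut distance d", y = "components c(d)",
      title = "Component count of the recent forest"
    )
}

#' Bracketing branching values
#'
#' For any `1 <= k <= n`, `k-` is the largest branching value at most `k` and
#' `k+` the smallest branching value at least `k`. They coincide with `k`
#' exactly when `k` is itself a branching value. Components at `d[k-]` are the
#' "tall" components, those at `d[k+]` the "short" components.
#'
#' @param profile a `branching_profile`.
#' @param k integer in `[1, n]`.
#' @return integer vector `c(k_minus, k_plus)`.
#' @examples
#' tr <- tree_T2()
#' bracket(branching_profile(tr, ultrametric_heights(tr)), 5) # 4 7
#' @export
bracket <- function(profile, k) {
  stopifnot(inherits(profile, "branching_profile"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > profile$n ||
      k != round(k)) {
    stop_bad_k(k, profile$n)
  }
  vals <- profile$values
  c(
    k_minus = max(vals[vals <= k]),
    k_plus = min(vals[vals >= k])
  )
}
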