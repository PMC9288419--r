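#' Test whether a subset is a maxPD set
#'
#' On an ultrametric tree, a size-k subset `A` attains the maximum PD over all
#' size-k subsets iff it contains at least one leaf from every component of the
#' tall forest (at the branching distance `d[k-]`) and at most one leaf from
#' every component of the short forest (at `d[k+]`). This membership test
#' requires no enumeration and no PD evaluation.
#'
#' @param tree a [pd_tree].
#' @param heights a `pd_heights` from [ultrametric_heights()]; `NULL` to
#'   compute it.
#' @param leaves character vector of distinct leaf labels (the candidate set).
#' @return `TRUE` or `FALSE`.
#' @examples
#' tr <- tree_T1()
#' is_maxpd(tr, leaves = c("x3", "x4", "x7")) # TRUE
#' is_maxpd(tr, leaves = c("x5", "x6", "x7")) # FALSE (a minPD set, in fact)
#' @export
is_maxpd <- function(tree, heights = NULL, leaves) {
  stopifnot(inherits(tree, "pd_tree"))
  if (is.null(heights)) heights <- ultrametric_heights(tree)
  tips <- match_labels(tree, leaves)
  k <- length(tips)
  if (k < 1L || k > tree$n_tip) stop_bad_k(k, tree$n_tip)
  prof <- branching_profile(tree, heights)
  br <- bracket(prof, k)
  tall <- prof$partitions[[as.character(br[["k_minus"]])]]$components
  short <- prof$partitions[[as.character(br[["k_plus"]])]]$components
  a <- tree$labels[tips]
  all(vapply(tall, function(cmp) any(cmp %in% a), logical(1))) &&
    all(vapply(short, function(cmp) sum(cmp %in% a) <= 1L, logical(1)))
}

## exact integer-valued product with an overflow guard: counts are held in
## doubles, which represent integers exactly up to 2^53
check_exact <- function(x) {
  if (any(x > 2^53)) {
    warning("count exceeds 2^53; the result may not be exact")
  }
  x
}

#' Count maxPD sets at a branching value
#'
#' When `k` is a branching value the number of size-k maxPD sets is simply the
#' product of the leaf counts of the k components of the recent forest at
#' `d_k`: each maxPD set picks exactly one leaf per component, independently.
#'
#' @param partition a `component_partition` taken at a branching distance.
#' @return the exact count, as an integer-valued double.
#' @export
count_branching <- function(partition) {
  stopifnot(inherits(partition, "component_partition"))
  check_exact(prod(as.numeric(partition$sizes)))
}

#' Component array for a non-branching subset size
#'
#' For a non-branching `k` the counting argument groups the short components
#' (at `d[k+]`) by the tall component (at `d[k-]`) containing them: column `j`
#' of the array holds the short components nested in tall component `j`. The
#' array is kept ragged; conceptual padding entries (empty sets completing a
#' rectangle) have size 0 and contribute a factor 1 to the generating
#' function, so they never need to be materialised.
#'
#' @param tree a [pd_tree].
#' @param heights optional `pd_heights`; `NULL` to compute.
#' @param k integer subset size in `[1, n]`.
#' @return an object of class `component_array`: a list with `k`, `k_minus`,
#'   `k_plus`, `columns` (list of lists of leaf-label vectors) and `sizes`
#'   (list of integer vectors, one per column). Columns and rows are in
#'   canonical order (by smallest leaf label).
#' @examples
#' tr <- tree_T2()
#' component_array(tr, k = 5)$sizes # list(c(2,1), 1, c(2,2), c(2,1))
#' @export
component_array <- function(tree, heights = NULL, k) {
  stopifnot(inherits(tree, "pd_tree"))
  if (is.null(heights)) heights <- ultrametric_heights(tree)
  prof <- branching_profile(tree, heights)
  br <- bracket(prof, k)
  tall <- prof$partitions[[as.character(br[["k_minus"]])]]$components
  short <- prof$partitions[[as.character(br[["k_plus"]])]]$components
  ## each short component lies inside exactly one tall component; membership of
  ## its first leaf decides which
  col_of <- vapply(short, function(cmp) {
    which(vapply(tall, function(t) cmp[1L] %in% t, logical(1)))
  }, integer(1))
  columns <- lapply(seq_along(tall), function(j) short[col_of == j])
  structure(
    list(
      k = as.integer(k),
      k_minus = br[["k_minus"]], k_plus = br[["k_plus"]],
      columns = columns,
      sizes = lapply(columns, lengths)
    ),
    class = "component_array"
  )
}

#' @export
print.component_array <- function(x, ...) {
  cat(sprintf(
    "<component_array> k = %d, bracket (%d, %d), %d column(s)\n",
    x$k, x$k_minus, x$k_plus, length(x$columns)
  ))
  for (j in seq_along(x$sizes)) {
    cat(sprintf("  column %d: sizes %s\n", j, paste(x$sizes[[j]], collapse = " ")))
  }
  invisible(x)
}

## exact convolution of two integer-coefficient polynomials (coef[i] = x^(i-1))
poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] != 0) {
      idx <- i + seq_along(b) - 1L
      out[idx] <- out[idx] + a[i] * b
    }
  }
  check_exact(out)
}

#' Generating polynomial for maxPD counting
#'
#' Expands the product over columns `j` of `(-1 + prod_i (1 + n_ij x))`, where
#' `n_ij` are the short-component sizes of the [component_array()]. The
#' coefficient of `x^m` is the number of size-m maxPD sets for every integer
#' `m` in the bracket `[k-, k+]` (and 0 outside). Factors are multiplied
#' sequentially with exact integer coefficients.
#'
#' @param array a `component_array`.
#' @return an object of class `count_polynomial`: a list with `coef` (numeric
#'   vector, `coef[i]` the coefficient of `x^(i-1)`), `k_minus`, `k_plus`.
#' @examples
#' arr <- component_array(tree_T2(), k = 5)
#' tidy(generating_polynomial(arr)) # counts 36, 84, 64, 16 for sizes 4..7
#' @export
generating_polynomial <- function(array) {
  stopifnot(inherits(array, "component_array"))
  poly <- 1
  for (sizes in array$sizes) {
    colpoly <- 1
    for (s in sizes) colpoly <- poly_mul(colpoly, c(1, s))
    colpoly[1L] <- colpoly[1L] - 1 # the -1 kills the empty-selection term
    poly <- poly_mul(poly, colpoly)
  }
  structure(
    list(coef = poly, k_minus = array$k_minus, k_plus = array$k_plus),
    class = "count_polynomial"
  )
}

#' @export
print.count_polynomial <- function(x, ...) {
  nz <- which(x$coef != 0)
  terms <- sprintf("%.0fx^%d", x$coef[nz], nz - 1L)
  cat("<count_polynomial>", paste(rev(terms), collapse = " + "), "\n")
  invisible(x)
}

#' @method tidy count_polynomial
#' @export
tidy.count_polynomial <- function(x, ...) {
  nz <- which(x$coef != 0)
  tibble::tibble(size = nz - 1L, count = x$coef[nz])
}

#' @method autoplot count_polynomial
#' @export
autoplot.count_polynomial <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(size), y = count)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "subset size k", y = "number of maxPD sets",
      title = "maxPD set counts across the bracket"
    )
}

#' Count the size-k maxPD sets of an ultrametric tree
#'
#' Dispatches on whether `k` is a branching value: if so, the count is the
#' product of component sizes at `d_k` ([count_branching()]); otherwise it is
#' the coefficient of `x^k` in the generating polynomial of the component
#' array ([generating_polynomial()]). Use [maxpd_count_table()] for the whole
#' bracket `[k-, k+]` at once — the polynomial route yields all of those
#' counts in one expansion.
#'
#' @param tree a [pd_tree] with ultrametric edge lengths.
#' @param heights optional `pd_heights`; `NULL` to compute.
#' @param k integer subset size in `[1, n]`.
#' @return the exact count as an integer-valued double.
#' @examples
#' count_maxpd(tree_T2(), k = 5) # 84
#' count_maxpd(tree_T1(), k = 3) # 20
#' @export
count_maxpd <- function(tree, heights = NULL, k) {
  stopifnot(inherits(tree, "pd_tree"))
  if (is.null(heights)) heights <- ultrametric_heights(tree)
  prof <- branching_profile(tree, heights)
  br <- bracket(prof, k)
  if (br[["k_minus"]] == br[["k_plus"]]) {
    return(count_branching(prof$partitions[[as.character(k)]]))
  }
  poly <- generating_polynomial(component_array(tree, heights, k))
  coef_at(poly, k)
}

coef_at <- function(poly, k) {
  if (k + 1L > length(poly$coef)) 0 else poly$coef[k + 1L]
}

#' @rdname count_maxpd
#' @return `maxpd_count_table()` returns a tibble with columns `size` and
#'   `count` covering every size in the bracket of `k`.
#' @export
maxpd_count_table <- function(tree, heights = NULL, k) {
  stopifnot(inherits(tree, "pd_tree"))
  if (is.null(heights)) heights <- ultrametric_heights(tree)
  arr <- component_array(tree, heights, k)
  if (arr$k_minus == arr$k_plus) {
    prof <- branching_profile(tree, heights)
    return(tibble::tibble(
      size = as.integer(k),
      count = count_branching(prof$partitions[[as.character(k)]])
    ))
  }
  poly <- generating_polynomial(arr)
  sizes <- arr$k_minus:arr$k_plus
  tibble::tibble(size = sizes, count = vapply(sizes, coef_at, numeric(1), poly = poly))
}

#' Closed-form counts for perfect unit-length trees
#'
#' For the complete binary tree of height `alpha` with every edge length 1
#' (`n = 2^alpha` leaves), the number of size-k maxPD sets has a closed form.
#' Writing `beta` for the unique integer with `2^(beta-1) < k <= 2^beta`: if
#' `k = 2^beta` (a branching value) the count is `(2^(alpha-beta))^k`;
#' otherwise it is `choose(2^(beta-1), k - 2^(beta-1)) *
#' 2^(2^beta + (alpha-beta-1)k)`.
#'
#' @param alpha tree height (integer `>= 1`).
#' @param k subset size in `[1, 2^alpha]`.
#' @return the exact count as an integer-valued double.
#' @examples
#' perfect_tree_count(4, 10) # 1792
#' @export
perfect_tree_count <- function(alpha, k) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 1 || alpha != round(alpha)) {
    stop_pdsets("alpha must be a positive integer", "pdsets_bad_alpha")
  }
  n <- 2^alpha
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > n || k != round(k)) {
    stop_bad_k(k, n)
  }
  beta <- ceiling(log2(k)) # k = 1 gives beta = 0, a branching value
  if (k == 2^beta) {
    return(check_exact((2^(alpha - beta))^k))
  }
  check_exact(choose(2^(beta - 1), k - 2^(beta - 1)) * 2^(2^beta + (alpha - beta - 1) * k))
}

#' Optimal subset sizes on perfect unit-length trees
#'
#' The sizes `k` that maximise the number of maxPD sets on a perfect
#' unit-length tree with `n = 2^alpha` leaves are `floor(2n/3)`, joined by
#' `floor(2n/3) + 1` exactly when `n = 1 (mod 3)` (the two consecutive counts
#' then tie).
#'
#' @param n leaf count; must be a power of 2.
#' @return integer vector of optimal sizes.
#' @examples
#' optimal_k_perfect(16) # 10 11
#' @export
optimal_k_perfect <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n) ||
      bitwAnd(as.integer(n), as.integer(n) - 1L) != 0L) {
    stop_pdsets("n must be a power of 2 (and at least 2)", "pdsets_bad_n")
  }
  k <- as.integer(floor(2 * n / 3))
  if (n %% 3 == 1) c(k, k + 1L) else k
}

#' Sharp bounds on the number of maxPD sets at a branching value
#'
#' For a rooted binary ultrametric tree with `n` leaves and a branching value
#' `k`, the count satisfies `n - k + 1 <= m(T, k) <= (n/k)^k`. The lower bound
#' is attained by rooted caterpillar trees, the upper by trees whose k
#' components split the leaves as evenly as possible. The upper bound can fail
#' for non-branching `k`.
#'
#' @param n leaf count.
#' @param k subset size in `[1, n]`.
#' @return named numeric vector `c(lower =, upper =)`.
#' @export
count_bounds <- function(n, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > n || k != round(k)) {
    stop_bad_k(k, n)
  }
  c(lower = n - k + 1, upper = (n / k)^k)
}
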