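---
title: "Counting and optimising maximum-diversity subsets on clock-like trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and optimising maximum-diversity subsets on clock-like trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdsets)
```

## The problem

Phylogenetic diversity (PD) is the standard currency of tree-aware
conservation planning: for a subset $Y$ of the species at the tips of a rooted
tree $T$ with positive branch lengths $\ell$,

$$PD_{(T,\ell)}(Y) \;=\; \sum_{e:\; c_T(e)\,\cap\, Y \neq \emptyset} \ell(e),$$

the total length of the minimal subtree connecting $Y$ to the root. A size-$k$
subset attaining the maximum PD over all size-$k$ subsets is a *maxPD set*;
one attaining the minimum is a *minPD set*. MaxPD sets are what a planner
wants to protect; minPD sets describe the worst-case survivors — equivalently
the greatest possible PD loss — if $n-k$ species go extinct.

A greedy algorithm finds *one* maxPD set, but on clock-like trees maxPD sets
are typically far from unique, which is exactly what makes room for secondary
criteria (cost, feasibility, IUCN status). `pdsets` answers three questions:

1. **How many** size-$k$ maxPD sets does a tree have? (exact count,
   `count_maxpd()`; membership test, `is_maxpd()`)
2. Among them all, **which one maximises** a linear score on the leaves?
   (`maximise_linear_sum()`)
3. What is the **minimum PD** of $k$ leaves — the maximum PD loss under
   $n-k$ extinctions — on an arbitrary rooted tree? (`minpd_score()`,
   `minpd_set()`, `max_pd_loss()`)

## Component structure of ultrametric trees

Counting and optimisation (questions 1 and 2) assume the *ultrametric*
condition: all root-to-leaf distances are equal, so every vertex has a height
(its distance to any descendant leaf) and "time runs down the page". For a cut
distance $d \ge 0$ the recent vertices $R(d)$ are those of height at most
$d$; the induced forest $T[R(d)]$ has some number $c(d)$ of connected
components, a non-increasing step function of $d$ that changes only at vertex
heights. When $c(d) = k$ is attained, $k$ is a *branching value* and
$d_k = \min\{d : c(d) = k\}$ its *branching distance*; $1$ and $n$ are always
branching values, but counts can be skipped when several merges happen at the
same height. For general $k$ the *bracket* $(k^-, k^+)$ holds the nearest
branching values below and above; components at $d_{k^-}$ are called *tall*,
those at $d_{k^+}$ *short*.

The structural fact driving everything: a size-$k$ subset $A$ is a maxPD set
**iff** it contains at least one leaf from every tall component and at most
one leaf from every short component. `is_maxpd()` is exactly this test.

```{r}
t2 <- tree_T2()
h2 <- ultrametric_heights(t2)
prof <- branching_profile(t2, h2)
tidy(prof)
bracket(prof, 5)
```

### Exact counting

At a branching value $k$, each maxPD set picks exactly one leaf per component
of $T[R(d_k)]$, so the count $m(T,k)$ is the product of the component leaf
counts. For non-branching $k$ the short components are grouped by the tall
component containing them into an array with sizes $n_{ij}$ (column $j$ = tall
component), and $m(T,k)$ is the coefficient of $x^k$ in

$$p(x) \;=\; \prod_{j=1}^{r}\Bigl(-1 + \prod_{i=1}^{n_j}(1 + n_{ij}\,x)\Bigr).$$

Each factor $(1 + n_{ij}x)$ says "skip this short component, or take one of
its $n_{ij}$ leaves"; the $-1$ removes the choice that leaves a tall component
empty. One expansion yields the counts for *every* size in $[k^-, k^+]$:

```{r}
arr <- component_array(t2, h2, k = 5)
arr
tidy(generating_polynomial(arr))
count_maxpd(t2, h2, 5)
```

Coefficients are expanded by naive sequential convolution — the polynomials
involved have degree at most $n$, so nothing faster is warranted. Counts are
held as integer-valued doubles, exact up to $2^{53}$ (far beyond any count a
tree of practically countable size produces; a warning fires past that
limit). Component and column order is canonical (lexicographic by smallest
leaf label), so printed arrays and polynomials are reproducible.

Two closed-form companions: on perfect unit-length trees (complete binary,
all lengths 1, $n = 2^\alpha$ leaves) the count has the binomial form
implemented in `perfect_tree_count()`, maximised at $k = \lfloor 2n/3
\rfloor$ (`optimal_k_perfect()`); and at any branching value on a binary
ultrametric tree, $n-k+1 \le m(T,k) \le (n/k)^k$ (`count_bounds()`), the
lower bound attained by caterpillars, the upper one only a branching-value
statement — size 5 on the 11-leaf example above beats $(11/5)^5 \approx
51.5$.

### Optimising a second criterion

`maximise_linear_sum()` maximises $\sum_{x \in A}\phi(x)$ over all size-$k$
maxPD sets $A$ for an arbitrary real leaf score $\phi$ (weighted criteria
reduce to this by rescaling $\phi$). It keeps one best-$\phi$ leaf per short
component ("potential" leaves), commits one per tall component, and tops up
with the $k - k^-$ best remaining potential leaves. The output is always a
maxPD set and $\phi$-optimal among them.

The tempting shortcut — add $\phi(x)$ to each pendant edge and run greedy —
is wrong, and `naive_pendant_augmentation()` keeps it around as the
documented failing baseline: on `tree_T1()` with scores 1 on `x1..x4` and 100
on `x5..x7` it returns `{x5, x6, x7}`, which is not a maxPD set of the
original tree (it is in fact the size-3 *minPD* set).

```{r}
t1 <- tree_T1()
f <- setNames(c(1, 1, 1, 1, 100, 100, 100), paste0("x", 1:7))
maximise_linear_sum(t1, phi = f, k = 3)
naive_pendant_augmentation(t1, f, 3)$leaves
```

## Minimum PD by dynamic programming

Minimisation is *not* solved by a greedy exchange argument; `pdsets` uses the
standard tree knapsack recursion instead, and it works on any rooted tree with
positive lengths — clock-likeness is not needed. For a vertex $v$ with child
edges $e_1,\dots,e_t$ of lengths $\ell_i$,

$$\varphi_v(k) \;=\; \min_{k_1+\dots+k_t = k}\;
  \sum_{i=1}^{t}\bigl(\varphi_{v_i}(k_i) + \ell_i\,\mathbb{I}_{k_i>0}\bigr),$$

with $\varphi_v(0) = 0$ and $\varphi_{\text{leaf}}(1) = 0$. Children are
folded pairwise (left to right in canonical order) by min-plus convolution,
which is associative and therefore reproduces the joint minimum over all
budget splits without enumerating compositions — multifurcations of any
degree cost nothing extra. Choice indices recorded during the fold let
`minpd_set()` walk back one optimal subset; ties prefer a smaller budget in
the earlier operand, so the recovered set is deterministic.

```{r}
tidy(minpd_table(t1))
minpd_set(t1, 3)
max_pd_loss(t1, 4) # total PD 23 minus the size-3 minimum 11
```

## Tunable parameters and numerical choices

* **Ultrametric tolerance.** Path lengths are compared with an absolute
  tolerance of $10^{-9} \times$ root height (floor $10^{-12}$), absorbing
  decimal rounding in Newick files. The same tolerance groups vertex heights
  into simultaneous merge events and decides membership of $R(d)$ (the
  defining "$\le d$"). Override via `ultrametric_heights(tree, tolerance =)`.
* **Root edge.** A length on the root is ignored (with a warning): PD is
  measured from the root, so it can contribute to no score.
* **Unifurcations** are suppressed at parse time, summing lengths; this
  leaves every subset's PD unchanged, so it is a pure normalisation.
* **Tie-breaks.** Wherever an arbitrary optimal choice exists (greedy
  additions, score ties in the linear optimiser, DP backpointers), the
  lexicographically smallest label wins. Any choice would be optimal; fixing
  one makes results reproducible and testable. This ordering convention is
  ours, not forced by the mathematics.
* **Degenerate inputs.** The single-leaf tree parses, has PD 0 and count 1;
  $k = n$ and $k = 1$ short-circuit to the trivial answers; `pd_loss()` of
  the full leaf set returns total PD by convention.

## What the random generator emulates — and what it does not

`random_ultrametric()` produces seeded coalescent-style trees: lineages merge
pairwise at strictly increasing heights, with optional probabilities of
reusing the previous merge height (simultaneous merges, hence skipped
branching values) and of triple merges (multifurcations). This exercises
precisely the combinatorial features the algorithms branch on. It does *not*
emulate realistic divergence-time distributions, rate variation, or
near-ultrametric measurement noise: real chronograms pass through the same
code paths but stress the tolerance rather than the combinatorics, so the
randomised tests certify algorithmic correctness, not robustness to badly
calibrated trees (which should be rejected by `ultrametric_heights()` or
re-smoothed upstream).

The test suite validates every routine against brute-force enumeration on 200
such trees with up to 10 leaves and all $k$ (about $2^{10}$ subsets per tree
— sizes chosen so exhaustive enumeration stays trivially cheap), alongside
the fixed small trees with hand-checkable integer answers.

## Known limitations

* Counting, membership and linear-score optimisation require the ultrametric
  condition; non-clock trees raise a `pdsets_not_ultrametric` error rather
  than silently using leaf-specific distances. (The minPD routines have no
  such restriction.)
* MaxPD sets are counted, never enumerated; `brute_force_pd()` enumerates
  only up to $\binom{n}{k} \le 10^6$ and exists for validation.
* Counting minPD sets in general is open; only the caterpillar special case
  (unique for $k \ge 2$, $n$ sets for $k = 1$) is covered, by brute force, in
  the tests.
* Counts beyond $2^{53}$ would lose exactness (a warning fires); an
  arbitrary-precision backend would be needed for trees vastly larger than
  any realistic use.
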