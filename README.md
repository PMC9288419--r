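# pdsets

Exact counting and optimisation of **maximum phylogenetic diversity (maxPD)
sets** on rooted, edge-weighted phylogenetic trees, plus the dual
**minimum-PD / maximum-PD-loss** problem.

Phylogenetic diversity of a leaf subset *Y* is the total branch length of the
minimal subtree connecting *Y* to the root,

    PD(Y) = Σ { ℓ(e) : cluster(e) ∩ Y ≠ ∅ },

the standard measure behind tree-aware conservation prioritisation (EDGE-style
programmes, Noah's-Ark-type planning). A size-*k* subset attaining the
maximum (minimum) PD over all size-*k* subsets is a maxPD (minPD) set. A
greedy algorithm finds *one* maxPD set, but on clock-like (ultrametric) trees
they are usually far from unique. `pdsets` is for the people who need the
whole collection:

* **Counting** — `count_maxpd()` returns the exact number *m(T, k)* of
  size-*k* maxPD sets. At a *branching value* *k* (a count attained by the
  forest of recent vertices `T[R(d)]` as the cut distance *d* varies) it is a
  product of component sizes; otherwise it is a coefficient of the integer
  generating polynomial
  `p(x) = Π_j ( −1 + Π_i (1 + n_ij·x) )`
  over the array of short components nested in tall components
  (`component_array()`, `generating_polynomial()`). `is_maxpd()` tests
  membership without any enumeration; `perfect_tree_count()`,
  `optimal_k_perfect()` and `count_bounds()` give the closed forms and sharp
  bounds for balanced and caterpillar shapes.
* **Optimising** — `maximise_linear_sum()` finds, among *all* size-*k* maxPD
  sets, one maximising a real-valued leaf score (cost–benefit weights,
  extinction risk, ...), in one pass over the component structure.
* **Min PD / max loss** — `minpd_score()`, `minpd_set()` and `max_pd_loss()`
  solve the dual worst-case-extinction problem by a min-plus dynamic program
  on the tree; this part needs no clock assumption and handles
  multifurcations.

Trees come in as Newick (via `ape`); tabular results come out as tibbles via
`tidy()`/`glance()`, with `autoplot()` methods for quick looks. Deterministic
fixture trees (`tree_T1()`, `tree_T2()`, `tree_T3()`, `tree_mammal_P()`,
`perfect_tree()`, `caterpillar_tree()`), a seeded random ultrametric
generator and a brute-force oracle (`brute_force_pd()`) ship with the
package.

## Worked example

An 11-leaf clock-like tree whose branching values are {1, 2, 4, 7, 9, 11} —
size 5 is *not* attainable as a component count, so counting goes through the
generating function:

```r
library(pdsets)

t2 <- tree_T2()
h2 <- ultrametric_heights(t2)
tidy(branching_profile(t2, h2))
#> # A tibble: 6 × 3
#>       k     d component_sizes
#>   <int> <dbl> <list>
#> 1     1     5 <int [1]>
#> 2     2     4 <int [2]>
#> 3     4     3 <int [4]>
#> 4     7     2 <int [7]>
#> 5     9     1 <int [9]>
#> 6    11     0 <int [11]>

arr <- component_array(t2, h2, k = 5)
arr
#> <component_array> k = 5, bracket (4, 7), 4 column(s)
#>   column 1: sizes 2 1
#>   column 2: sizes 2 1
#>   column 3: sizes 1
#>   column 4: sizes 2 2
generating_polynomial(arr)
#> <count_polynomial> 16x^7 + 64x^6 + 84x^5 + 36x^4
count_maxpd(t2, h2, 5)
#> [1] 84
```

So `t2` has 84 maxPD quintets (and, from the same polynomial, 36 quartets, 64
sextets, 16 septets). Picking among the 20 maxPD triples of the 7-leaf
fixture by a secondary score — note the three top-scoring leaves alone are
*not* a maxPD set, so the naive answer `{x5,x6,x7}` would be wrong:

```r
t1 <- tree_T1()
f <- setNames(c(1, 1, 1, 1, 100, 100, 100), paste0("x", 1:7))
maximise_linear_sum(t1, phi = f, k = 3)
#> $leaves
#> [1] "x1" "x5" "x6"
#> $score
#> [1] 201
#> $pd
#> [1] 16

minpd_set(t1, 3)      # worst-case survivors: {x5, x6, x7}, PD 11
max_pd_loss(t1, 4)    # losing any 4 species costs at most 23 - 11 = 12
#> [1] 12
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/pdsets count tree.nwk -k 5 --poly
Rscript inst/scripts/pdsets minpd tree.nwk -k 3 --set
Rscript inst/scripts/pdsets fixture T2
```

See `vignette("maxpd-counting")` for the model, the algorithms and the design
choices in full.

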