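Package: pdsets
Title: Counting and Optimising Maximum Phylogenetic Diversity Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the collection of leaf subsets that
    maximise (or minimise) phylogenetic diversity (PD) on a rooted
    edge-weighted tree. For clock-like (ultrametric) trees the package
    counts the number of size-k maxPD sets exactly via the component
    structure of the forest of recent vertices and an integer generating
    function, tests membership of a given subset, and optimises a linear
    leaf score (e.g. a conservation benefit) over all maxPD sets without
    enumerating them. A dynamic program computes minimum-PD subsets --
    equivalently the greatest possible PD loss under a fixed number of
    extinctions -- on arbitrary rooted trees. Includes closed forms for
    perfect unit-length trees, sharp bounds at branching values,
    deterministic fixture trees, a seeded random ultrametric tree
    generator, and brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
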