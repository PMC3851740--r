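Package: treevasc
Title: Whole-Tree Scaling of Xylem and Phloem Structure and Munch Transport
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Allometric scaling of tree vascular tissues and steady-state
    sugar transport. Fits power laws relating xylem, phloem and bark
    properties to branch/stem diameter, propagates them through pipe-model
    bookkeeping (with optional sapwood-to-heartwood turnover) to axial
    profiles and whole-tree totals of tissue volume, nitrogen content and
    hydraulic conductance, and couples the resulting conductance profiles
    to a steady-state Munch pressure-flow model of phloem transport. Ships
    a synthetic branch/stem measurement generator, a sensitivity sweep over
    the scaling exponents, and drivers for three transport simulations:
    axial pressure/concentration gradients, optimal axial allocation of
    phloem tissue, and the height dependence of the leaf-to-root turgor
    difference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
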