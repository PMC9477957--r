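Package: fbnet
Title: Forest-Based Phylogenetic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiply-rooted phylogenetic networks and the class of
    forest-based networks, which model reticulate evolution (introgression,
    lateral gene transfer) between distinct lineages.  Provides validation and
    vertex-role analysis of multi-rooted networks, exact recognition of
    forest-based and proper forest-based networks with contact-arc
    certificates, class predicates (tree-child, tree-sibling,
    reticulation-visible, tree-based), reconstruction of arboreal networks
    from cluster systems, coloring-based characterizations of proper
    forest-basedness, universality checking against all phylogenetic forests
    on a label set, figure-style fixtures, random network generators, and
    plain-text, extended-Newick and DOT input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
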