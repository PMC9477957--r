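# fbnet — forest-based phylogenetic networks

Reticulate evolution — introgression, lateral gene transfer, hybridization —
cannot be drawn on a single phylogenetic tree. *Tree-based* networks model it
by adding arcs between the edges of one tree; but when genes move between
distinct lineages or sub-families, the natural base object is a
**phylogenetic forest**: leaf-disjoint rooted trees partitioning the taxon
set X. A multiply-rooted network N = (V, A) on X is **forest-based** when
there is an arc subset A′ ⊆ A such that F′ = (V, A′) is a forest with the
same leaf set as N and every *contact arc* in A − A′ joins two different
trees of F′; suppressing subdivision vertices of F′ gives a *base forest*.
An m-rooted network is **proper** forest-based when some base forest has
exactly m trees.

`fbnet` is an exact toolkit for this class, for people working on the
combinatorics of reticulate evolution:

* validation and vertex-role analysis of multi-rooted semi-binary networks
  (roots, hybrids, omnians, first reticulate ancestors γ_v);
* forest-based recognition with certificates, two independent routes: a
  path-partition backtracking decider (a network is forest-based iff the
  trivial forest embeds as chord-free disjoint paths) and an exhaustive
  subset oracle;
* arboreal networks (underlying graph a tree): hybrid-sequence
  recognition, cluster systems, the P1–P3 realizability test, and
  reconstruction of an arboreal network from its cluster system; bad arcs
  and uniqueness;
* proper forest-basedness two ways: per-hybrid arc-deletion search, and the
  coloring characterization on omni-extensions of the gamma graph Γ(N)
  (bipartiteness, for two roots);
* class predicates (tree-child, tree-sibling, reticulation-visible, binary,
  arboreal) and the omnian-matching tree-based test for binary phylogenetic
  networks;
* universality checking (is every phylogenetic forest on X a base forest?)
  with exhaustive forest enumeration, and the forbidden-configuration
  detector that explains why no universal network exists on four or more
  leaves;
* figure-style fixtures, seed-deterministic random generators (general,
  tree-child, arboreal), and plain-text edge-list, extended-Newick and DOT
  input/output.

## Worked example

The two-rooted network below has leaves 1–4, hybrids `h1`, `h2`, and omnians
`v`, `w`:

```r
library(fbnet)
net <- fixture("fig2")
net
#> <fbnet_network: 10 vertices, 10 arcs, 2 roots, 2 hybrids, strict mode>
#>   leaves: 1 2 3 4

is_forest_based(net)$certificate
#> <fbnet_certificate: 4 contact arcs>
#>   rho1 -> v
#>   rho2 -> w
#>   v -> h2
#>   w -> h1
#> <fbnet_forest: 4 trees on {1,2,3,4}>
#>   {1}
#>   {2}
#>   {3}
#>   {4}
```

The decider returns an embedding of the trivial forest: removing the four
contact arcs leaves four disjoint paths, one per leaf — the path-partition
witness that the network is forest-based. The same network is also *proper*
forest-based: a base forest with one tree per root exists,

```r
is_proper_forest_based(net)$certificate$base_forest
#> <fbnet_forest: 2 trees on {1,2,3,4}>
#>   {1} {1,2} {2}
#>   {3} {3,4} {4}
```

i.e. the cherry on {1,2} under the first root and the cherry on {3,4} under
the second — each tree printed as its hierarchy of leaf clusters. Export for
other tools:

```r
write_enewick(net)
#> [1] "(1,((2)#H1,(3)#H2));" "(4,(#H1,#H2));"
```

one extended-Newick statement per root, hybrids shared across statements via
`#H` tags. A command-line wrapper with the same operations lives at
`inst/cli/fbnet.R` (`Rscript $(Rscript -e 'cat(system.file("cli","fbnet.R",package="fbnet"))') forest-based FILE`).

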