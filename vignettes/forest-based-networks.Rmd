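---
title: "Recognizing forest-based phylogenetic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing forest-based phylogenetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbnet)
```

## The model

A multiply-rooted phylogenetic network on a taxon set X is a connected acyclic
digraph whose outdegree-0 vertices carry the labels of X, whose indegree-0
vertices (the roots) have outdegree at least two, and whose hybrid vertices
(indegree two, outdegree one in the semi-binary networks this package calls
*strict*) stand for reticulate events — introgression, lateral gene transfer,
hybridization. A single phylogenetic tree cannot represent such events; a
*tree-based* network adds reticulation arcs between the edges of one tree.
When genetic material moves between different lineages or sub-families, the
natural starting object is instead a *phylogenetic forest*: leaf-disjoint
rooted trees whose leaf sets partition X. A network is **forest-based** when
some subset of its arcs forms a spanning forest with the same leaf set as the
network, such that every remaining arc (a *contact arc*) joins two different
trees of that forest. Suppressing subdivision vertices and unary roots in the
spanning forest gives the *base forest*. An m-rooted network is **proper**
forest-based when some base forest has exactly m trees — one per lineage.

Networks whose underlying undirected graph is a tree are called *arboreal*;
they are the natural habitat of the cluster-system results below, and always
satisfy |H| = |R| − 1 (each extra root must be paid for by a reticulation).

```{r fig2}
net <- fixture("fig2")
net
is_forest_based(net)$certificate
```

## Recognition algorithms and their design

**Path partitions (the main decider).** A network is forest-based exactly
when the *trivial* forest (one isolated vertex per label) embeds as a union
of vertex-disjoint directed paths, one ending at each leaf, with no arc of
the network joining two non-consecutive vertices of one path. This
reformulation makes the search state one successor choice per non-leaf
vertex instead of an arbitrary arc subset: `is_forest_based()` backtracks
over those choices, rejecting a choice as soon as the head already lies on a
chosen path (indegree bound) or the merge of two paths would trap a non-path
arc inside one path (incremental chord detection). Children are tried in
lexicographic order, so the returned partition is deterministic. The search
is still exponential in the worst case — no polynomial algorithm is known
for this recognition problem — but the pruning is strong at the sizes the
package targets (a few dozen vertices).

**The subset oracle.** `oracle_is_forest_based()` is the ground truth the
decider is tested against: it enumerates every arc subset whose removal
leaves all indegrees at most one, keeping a union–find forest to cut
undirected cycles early, and checks leaf preservation and the
component-crossing condition at the leaves of the search. It refuses inputs
above an explicit arc budget (default 18 arcs) rather than degrade silently.
Both routes must agree; the test suite and the acceptance script check this
on hundreds of generated networks.

**Arboreal networks.** For arboreal networks forest-basedness has a local
characterization: every hybrid h must start a sequence of distinct vertices
in which consecutive vertices share a hybrid child and the last vertex has a
non-hybrid child. `arboreal_forest_based()` tests this by reachability in
the share-a-hybrid-child graph μ(N) (vertices: parents of hybrids; one edge
per hybrid). For the constructive half, each component of μ(N) — a tree,
since the host is arboreal — is oriented toward a *good* vertex (one with a
non-hybrid child) chosen as the lexicographically least good vertex of the
component. Orienting every edge toward that root makes every non-root vertex
a tail of some edge, so each omnian keeps an arc to one hybrid child; the
contact arcs are then the arcs from each edge's head into its hybrid. This
is simpler than re-tracing the hybrid sequences edge by edge and achieves
the same invariant (every sink of the orientation is good). Because removing
any arc set from a tree automatically satisfies the crossing condition, the
resulting certificate has exactly one contact arc per hybrid and one base
tree per root — so an arboreal forest-based network with two or more roots
is automatically proper.

**Proper networks by deletion.** A base forest with m trees exists exactly
when deleting one incoming arc per hybrid (and nothing else — deleting a
tree vertex's incoming arc or both arcs of a hybrid would mint an extra
root) leaves a forest with the network's leaf set in which every deleted arc
crosses components. `is_proper_forest_based()` enumerates these 2^|H|
deletion patterns directly. This derived reformulation is cross-checked
against the coloring characterization below on every test run.

**Colorings of the gamma graph.** For every vertex v, γ(v) is its first
root-or-hybrid ancestor, reached by walking up unique tree-vertex parents
(the walk needs no tie-breaking precisely because non-hybrids have one
parent). The gamma graph Γ(N) has vertex set R(N) ∪ H(N) and one edge
{γ(u′), γ(v′)} per hybrid with parents u′, v′ — a loop when the two walks
meet. An *omni-extension* adds, for each omnian v (a vertex all of whose
children are hybrids), an edge joining some hybrid child h of v to γ(u) for
u the other parent of h. An m-rooted network is proper forest-based exactly
when some omni-extension admits a proper coloring with m colors that is a
bijection on the roots (C1) and in which every hybrid sharing a root's color
is reachable from that root through same-colored hybrids (C2). For m = 2
this collapses to: Γ(N) has a bipartite omni-extension.

`minimal_omni_extensions()` enumerates one hybrid-child choice per omnian
and keeps the inclusion-minimal resulting graphs. The reduction to minimal
extensions is this package's own step: a proper coloring of any
omni-extension restricts to a proper coloring of every omni-extension it
contains, and C1/C2 do not mention the extension at all, so a coloring
witness exists on some extension iff it exists on a minimal one. Rather than
being assumed, this is continuously re-verified — the coloring route must
agree with the deletion route on every generated instance. Color symmetry is
broken by assigning color i to the i-th root in sorted order.

```{r fig8}
proper_via_coloring(fixture("fig8"))$coloring
has_bipartite_omni_extension(fixture("fig8"))
```

## Clusters and arboreal reconstruction

The cluster of a vertex is the set of leaves below it; the cluster system
𝒞(N) collects the distinct clusters. For arboreal networks:

* the set-inclusion maximal clusters are exactly the root clusters;
* 𝒞(N) satisfies three properties — each maximal cluster's sub-clusters form
  a hierarchy with all trivial clusters (P1), the intersection graph of the
  maximal clusters is connected (P2), pairwise intersections of maximal
  clusters are clusters or empty (P3);
* `build_arboreal_network()` reconstructs a network from such a system by
  building each maximal cluster's tree from its hierarchy and gluing trees
  one at a time at the unique tree vertex carrying the maximal shared
  cluster, subdividing its incoming arc (the subdivision vertex becomes a
  hybrid). Trees are processed in lexicographic order of their leaf sets,
  the one deterministic choice the gluing leaves open.

P1–P3 are necessary but, as stated, not quite sufficient: the system with
maximal clusters {1,2}, {2,3}, {1,3} (plus trivial clusters) satisfies all
three, yet three pairwise-distinct non-empty intersections would require
three hybrids where a 3-rooted arboreal network has only two. The builder
therefore verifies that its output reproduces the input system and raises a
`not realizable` error otherwise; the round-trip property is asserted on
cluster systems that come from actual networks, where it always holds.

An arc with two hybrid endpoints is *bad*: swapping the external incoming
arcs around a bad arc produces a non-equivalent network with the same
clusters, so an arboreal network is determined by its cluster system exactly
when it has no bad arcs — equivalently, when no three maximal clusters have
equal pairwise non-empty intersections. After contracting all bad arcs
(`collapse_bad_arcs()`, whose output is generally not semi-binary and is
returned as a relaxed graph, never re-validated), equal cluster systems and
equivalence coincide. The test suite verifies the uniqueness criterion
exhaustively against all 366 strict arboreal networks with at least one
hybrid and at most eight vertices, over all leaf labelings; hybrid-free
arboreal networks are plain trees, whose hierarchies cannot collide with any
multi-rooted network's system.

```{r fig6}
f6 <- fixture("fig6N")
bad_arcs(f6)
unlist(same_clusters_iff_collapse_equivalent(f6, fixture("fig6Nprime")))
```

## Universality

A network on X is *universal* when every phylogenetic forest on X is a base
forest. `enumerate_forests()` crosses set partitions (at least two blocks)
with all rooted phylogenetic trees per block — trees need not be binary, only
free of unary internal vertices, which the census on three labels confirms:
four forests (one trivial, three cherry-plus-singleton). On four labels there
are 26. Universality checking is exhaustive over this census and guarded to
at most five leaves. The packaged `fig10` network is universal on three
labels; on four or more labels no universal network exists, which the tests
probe by checking a panel of four-leaf networks. The obstruction is a local
configuration — two hybrid-only chains from one tree vertex or root down to
two distinct leaves — whose detector (`has_forbidden_configuration()`) walks
each hybrid's unique child chain deterministically. Note the configuration
only contradicts universality from four leaves up: universal three-leaf
networks do contain it (embedding a cherry over a label set this small
forces hybrid chains), which is precisely why the nonexistence argument
needs the fourth leaf.

## The generators: what they emulate, and what they do not

`random_network()` grows one random binary tree per root over the leaf
labels and then adds each hybrid as a lateral-transfer event: a donor arc
and a recipient arc are subdivided and joined donor-to-recipient, which
preserves acyclicity (checked by reachability), semi-binarity and binarity,
and keeps the leaf set fixed. The first m − 1 events bridge distinct
components so the result is connected. `tree_child` rejects events that
would leave any vertex with only hybrid children; `arboreal` joins two
components per hybrid so the underlying graph stays a tree and |R| =
|H| + 1 by construction. Identical arguments give identical networks; the
seed is the only source of randomness.

These generators emulate the combinatorial shape of reticulate histories —
where reticulations attach relative to tree arcs — under a uniform-ish
random proposal. They do not emulate branch lengths, rates, population
processes, or any biological preference for recent transfers, and all
generated networks are binary. Consequently, passing tests show the
algorithms are correct on the combinatorial universe they quantify over;
they say nothing about inference from sequence data, which is out of scope.

Default study conditions used by the tests and the acceptance script: leaf
counts 2–7, hybrid counts 0–5, one to three roots, 200–300 instances per
claim, with the subset oracle capped at 18 arcs. These sizes were chosen so
that each exhaustive oracle remains exact; they are documented here as the
package's reference problem sizes.

## Numerical and degenerate-input choices

* All identifiers are strings; leaves *are* the labels of X, so no separate
  label map exists. Arc matrices are kept sorted lexicographically; writers
  are byte-deterministic.
* Forest-basedness of a single-leaf network is undefined (a forest needs at
  least two trees) and reported as an error, never as `FALSE`. A
  single-vertex graph is accepted as a degenerate network whose vertex is
  simultaneously root and leaf.
* Strict mode rejects internal non-root tree vertices of outdegree one; no
  valid network needs them, and admitting them would make equivalence
  classes infinite. Relaxed mode (for diagnostics such as the indegree-3
  counterexample `fig9`) lifts only the hybrid indegree bound and the unary
  rule.
* Equivalence is decided by VF2 isomorphism with each leaf colored by its
  label and all internal vertices sharing one color, so internal identifiers
  never matter.
* Tie-breaks everywhere are lexicographic (successor choices, gluing order,
  orientation roots, color assignment), making every search result
  reproducible.

## Limitations

Recognition of forest-based networks has no known polynomial-time algorithm;
all deciders here are exact exponential searches with explicit budgets, not
heuristics, and report budget overruns as errors. The universality check is
restricted to five leaves by the forest census. The extended-Newick reader
accepts only this package's own export dialect. Overlaid species forests,
unrooted forest-based networks and pedigrees are related notions that the
package deliberately does not model.
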