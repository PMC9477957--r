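#' Enumerate set partitions
#'
#' All partitions of a label set into non-empty blocks, optionally with a
#' minimum block count.  Deterministic order.
#'
#' @param labels character vector.
#' @param min_blocks minimum number of blocks (default 1).
#' @return A list of partitions; each partition is a list of character
#'   vectors.
#' @export
set_partitions <- function(labels, min_blocks = 1L) {
  labels <- sort(labels)
  rec <- function(items) {
    if (length(items) == 0L) return(list(list()))
    first <- items[[1L]]
    rest <- rec(items[-1L])
    out <- list()
    for (p in rest) {
      for (i in seq_along(p)) {
        q <- p
        q[[i]] <- sort(c(q[[i]], first))
        out[[length(out) + 1L]] <- q
      }
      out[[length(out) + 1L]] <- c(p, list(first))
    }
    out
  }
  parts <- rec(labels)
  parts <- Filter(function(p) length(p) >= min_blocks, parts)
  # canonical: blocks sorted by first element; partitions sorted by key
  parts <- lapply(parts, function(p)
    p[order(vapply(p, function(b) b[[1L]], character(1)))])
  keys <- vapply(parts, function(p)
    paste(vapply(p, paste, character(1), collapse = ","), collapse = "|"),
    character(1))
  parts[order(keys)]
}

#' Enumerate rooted phylogenetic trees as hierarchies
#'
#' All rooted phylogenetic trees on a label set, not necessarily binary, with
#' no internal vertex of outdegree one, each represented by its hierarchy.
#'
#' @param labels character vector (non-empty).
#' @return A list of hierarchies (lists of clusters).
#' @export
enumerate_trees <- function(labels) {
  labels <- sort(labels)
  if (length(labels) == 1L) return(list(list(labels)))
  out <- list()
  for (p in set_partitions(labels, min_blocks = 2L)) {
    block_trees <- lapply(p, enumerate_trees)
    idx <- lapply(block_trees, seq_along)
    grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(grid))) {
      clusters <- list(labels)
      for (b in seq_along(p)) {
        clusters <- c(clusters, block_trees[[b]][[grid[r, b]]])
      }
      out[[length(out) + 1L]] <- clusters
    }
  }
  out
}

#' Enumerate all phylogenetic forests on a label set
#'
#' Crosses every set partition of the labels into at least two blocks with
#' every rooted phylogenetic tree on each block.  On three labels this yields
#' the four phylogenetic forests; on four labels, twenty-six.
#'
#' @param labels character vector with 2 to 6 elements.
#' @return A list of [phylo_forest()] objects in deterministic order.
#' @export
enumerate_forests <- function(labels) {
  labels <- sort(labels)
  if (length(labels) < 2L || length(labels) > 6L)
    stop("forest enumeration supports 2 to 6 labels", call. = FALSE)
  out <- list()
  for (p in set_partitions(labels, min_blocks = 2L)) {
    block_trees <- lapply(p, enumerate_trees)
    idx <- lapply(block_trees, seq_along)
    grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(grid))) {
      trees <- lapply(seq_along(p), function(b) block_trees[[b]][[grid[r, b]]])
      out[[length(out) + 1L]] <- phylo_forest(trees, labels = labels)
    }
  }
  keys <- vapply(out, forest_key, character(1))
  ord <- order(keys)
  out <- out[ord]
  out[!duplicated(keys[ord])]
}

# --- random generators ------------------------------------------------------

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# random binary tree on >= 2 labels; internal ids prefixed
random_tree_arcs <- function(labels, prefix, counter) {
  labels <- sample(labels)
  nid <- function() {
    counter$i <- counter$i + 1L
    paste0(prefix, counter$i)
  }
  r <- nid()
  arcs <- rbind(c(r, labels[[1L]]), c(r, labels[[2L]]))
  for (x in labels[-(1:2)]) {
    k <- sample.int(nrow(arcs), 1L)
    u <- arcs[k, 1L]; v <- arcs[k, 2L]
    s <- nid()
    arcs <- arcs[-k, , drop = FALSE]
    arcs <- rbind(arcs, c(u, s), c(s, v), c(s, x))
  }
  arcs
}

arcs_reach <- function(arcs, from) {
  seen <- character(0); stack <- from
  while (length(stack) > 0L) {
    u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (u %in% seen) next
    seen <- c(seen, u)
    stack <- c(stack, setdiff(arcs[arcs[, 1L] == u, 2L], seen))
  }
  seen
}

#' Random networks of a requested kind
#'
#' Grows a forest of random binary trees over the leaf labels `1..n_leaves`,
#' then adds hybrids.  For kinds `general` and `tree_child` each hybrid is a
#' lateral-transfer event: a donor arc and a recipient arc are subdivided and
#' joined by a new arc, which keeps the graph acyclic and semi-binary (the
#' first `n_roots - 1` events bridge distinct components so the result is
#' connected); `tree_child` additionally rejects events that would leave a
#' vertex with only hybrid children.  For kind `arboreal` the network has
#' `n_hybrids + 1` roots and every hybrid joins two components while the
#' underlying graph stays a tree.  Identical arguments produce identical
#' networks.
#'
#' @param n_leaves number of leaves (>= 2 per tree component).
#' @param n_hybrids number of hybrid vertices.
#' @param n_roots number of roots (ignored for `arboreal`, which forces
#'   `n_hybrids + 1`).
#' @param kind `"general"`, `"tree_child"` or `"arboreal"`.
#' @param seed integer seed.
#' @return A strict `fbnet_network`.
#' @export
random_network <- function(n_leaves, n_hybrids, n_roots = 1L,
                           kind = c("general", "tree_child", "arboreal"),
                           seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "arboreal") n_roots <- n_hybrids + 1L
  if (n_leaves < 2L * n_roots)
    stop("need at least two leaves per root component", call. = FALSE)
  if (kind != "arboreal" && n_hybrids < n_roots - 1L)
    stop("need at least n_roots - 1 hybrids to connect the components",
         call. = FALSE)
  with_seed(seed, {
    labels <- as.character(seq_len(n_leaves))
    # random partition into n_roots blocks of size >= 2
    sizes <- rep(2L, n_roots)
    extra <- n_leaves - 2L * n_roots
    if (extra > 0L) {
      add <- table(factor(sample.int(n_roots, extra, replace = TRUE),
                          levels = seq_len(n_roots)))
      sizes <- sizes + as.integer(add)
    }
    shuffled <- sample(labels)
    blocks <- split(shuffled, rep(seq_len(n_roots), times = sizes))
    counter <- new.env()
    counter$i <- 0L
    arcs <- NULL
    comp <- stats::setNames(integer(0), character(0))
    for (b in seq_len(n_roots)) {
      ta <- random_tree_arcs(blocks[[b]], prefix = "v", counter = counter)
      arcs <- rbind(arcs, ta)
      for (u in unique(c(ta))) comp[[u]] <- b
    }
    hyb_ids <- character(0)

    if (kind == "arboreal") {
      for (k in seq_len(n_hybrids)) {
        comps <- unique(comp)
        ab <- sample(comps, 2L)
        in_a <- which(comp[arcs[, 1L]] == ab[[1L]])
        in_b <- which(comp[arcs[, 1L]] == ab[[2L]])
        da <- in_a[[sample.int(length(in_a), 1L)]]
        rb <- in_b[[sample.int(length(in_b), 1L)]]
        d1 <- arcs[da, 1L]; d2 <- arcs[da, 2L]
        u2 <- arcs[rb, 1L]; v2 <- arcs[rb, 2L]
        counter$i <- counter$i + 1L
        s <- paste0("v", counter$i)
        h <- paste0("h", k)
        hyb_ids <- c(hyb_ids, h)
        arcs <- arcs[-c(da, rb), , drop = FALSE]
        arcs <- rbind(arcs, c(d1, s), c(s, d2), c(u2, h), c(h, v2), c(s, h))
        newc <- min(ab)
        comp[comp %in% ab] <- newc
        comp[[s]] <- newc; comp[[h]] <- newc
      }
    } else {
      for (k in seq_len(n_hybrids)) {
        must_bridge <- length(unique(comp)) > 1L
        placed <- FALSE
        for (try in seq_len(500L)) {
          da <- sample.int(nrow(arcs), 1L)
          rb <- sample.int(nrow(arcs), 1L)
          if (da == rb) next
          d1 <- arcs[da, 1L]; d2 <- arcs[da, 2L]
          r1 <- arcs[rb, 1L]; r2 <- arcs[rb, 2L]
          if (must_bridge && comp[[d1]] == comp[[r1]]) next
          # acyclicity: the new arc runs donor -> recipient
          if (d1 %in% arcs_reach(arcs, r2)) next
          if (kind == "tree_child") {
            if (d2 %in% hyb_ids || r2 %in% hyb_ids) next
            if (r1 %in% hyb_ids) next   # would leave r1 with a hybrid-only child
            sib <- setdiff(arcs[arcs[, 1L] == r1, 2L], r2)
            if (length(sib) > 0L && all(sib %in% hyb_ids)) next
          }
          counter$i <- counter$i + 1L
          s <- paste0("v", counter$i)
          h <- paste0("h", k)
          hyb_ids <- c(hyb_ids, h)
          arcs <- arcs[-c(da, rb), , drop = FALSE]
          arcs <- rbind(arcs, c(d1, s), c(s, d2), c(s, h),
                        c(r1, h), c(h, r2))
          newc <- min(comp[[d1]], comp[[r1]])
          comp[comp %in% c(comp[[d1]], comp[[r1]])] <- newc
          comp[[s]] <- newc; comp[[h]] <- newc
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place hybrid ", k, " after bounded retries",
               call. = FALSE)
      }
    }
    network(arcs, mode = "strict")
  })
}

#' Host networks containing the forbidden universal-network configuration
#'
#' Builds a strict binary network in which a tree vertex `w` has two
#' descendant chains of hybrid vertices of lengths `p` and `q` ending at the
#' leaves `x` and `y`; each chain hybrid draws its second parent from a
#' feeder spine so that the network is semi-binary.  With `broken = TRUE` a
#' tree vertex interrupts the first chain, destroying the configuration.
#'
#' @param p,q chain lengths (>= 0).
#' @param broken interrupt the x-chain with a tree vertex.
#' @return A strict `fbnet_network` with leaves `x`, `y` and spine leaves.
#' @export
fig11_configuration <- function(p = 1L, q = 1L, broken = FALSE) {
  arcs <- rbind(c("rho", "w"))
  chain <- function(top, hybrids, leaf) {
    # returns arcs of the chain top -> h_k -> ... -> h_1 -> leaf
    a <- NULL
    prev <- top
    for (h in hybrids) {
      a <- rbind(a, c(prev, h))
      prev <- h
    }
    rbind(a, c(prev, leaf))
  }
  vh <- if (p > 0L) paste0("vx", seq_len(p)) else character(0)
  uh <- if (q > 0L) paste0("uy", seq_len(q)) else character(0)
  if (broken && p > 0L) {
    # interrupt the x-chain with the tree vertex bx below its topmost hybrid
    arcs <- rbind(arcs, c("w", vh[1L]), c(vh[1L], "bx"), c("bx", "bxleaf"),
                  chain("bx", vh[-1L], "x"))
  } else {
    arcs <- rbind(arcs, chain("w", vh, "x"))
  }
  arcs <- rbind(arcs, chain("w", uh, "y"))
  # feeder spine supplying second parents to all chain hybrids
  feeders <- c(vh, uh)
  if (length(feeders) > 0L) {
    prev <- "rho"
    for (i in seq_along(feeders)) {
      t <- paste0("t", i)
      arcs <- rbind(arcs, c(prev, t), c(t, feeders[[i]]))
      prev <- t
    }
    arcs <- rbind(arcs, c(prev, "z"))
  } else {
    arcs <- rbind(arcs, c("rho", "z"))
  }
  network(arcs, mode = "strict")
}

# --- figure-style fixtures --------------------------------------------------

fixture_arcs <- list(
  # 2-rooted forest-based network on {1,2,3,4}; based on the forest
  # {1},{2},cherry{3,4} and proper with base trees on {1,2} and {3,4};
  # the omnians v and w must each send one contact arc in any embedding
  fig2 = rbind(
    c("rho1", "1"), c("rho1", "v"), c("v", "h1"), c("v", "h2"),
    c("rho2", "4"), c("rho2", "w"), c("w", "h1"), c("w", "h2"),
    c("h1", "2"), c("h2", "3")),
  # arboreal 4-rooted network that is not forest-based: one of (h1,h3),
  # (h2,h3) must be a contact arc, making h1 or h2 a forest leaf
  fig5 = rbind(
    c("r1", "l1"), c("r1", "h1"), c("r2", "l2"), c("r2", "h1"),
    c("r3", "l3"), c("r3", "h2"), c("r4", "l4"), c("r4", "h2"),
    c("h1", "h3"), c("h2", "h3"), c("h3", "x")),
  # two arboreal 3-rooted networks with equal cluster systems that are not
  # equivalent; bad arcs (h1,h2) and (h2,h1) respectively
  fig6N = rbind(
    c("r1", "1"), c("r1", "h1"), c("r2", "2"), c("r2", "h1"),
    c("h1", "h2"), c("r3", "3"), c("r3", "h2"), c("h2", "4")),
  fig6Nprime = rbind(
    c("r1", "1"), c("r1", "h2"), c("r3", "3"), c("r3", "h2"),
    c("h2", "h1"), c("r2", "2"), c("r2", "h1"), c("h1", "4")),
  # 3-rooted forest-based network, no omnians, not proper forest-based;
  # gamma graph has a triangle rho1-rho2-h1 and no rho3 -> h1 path exists
  fig7 = rbind(
    c("rho1", "1"), c("rho1", "a1"), c("a1", "h1"), c("a1", "b1"),
    c("b1", "h2"), c("b1", "d1"), c("d1", "h4"), c("d1", "2"),
    c("rho2", "5"), c("rho2", "a2"), c("a2", "h1"), c("a2", "c1"),
    c("c1", "h3"), c("c1", "4"),
    c("rho3", "10"), c("rho3", "d3"), c("d3", "h4"), c("d3", "6"),
    c("h1", "e"), c("e", "b2"), c("e", "c2"),
    c("b2", "h2"), c("b2", "3"), c("c2", "h3"), c("c2", "11"),
    c("h2", "7"), c("h3", "8"), c("h4", "9")),
  # 2-rooted proper forest-based network with omnians v and w and exactly
  # two inclusion-minimal omni-extensions, one of them bipartite
  fig8 = rbind(
    c("rho1", "v"), c("rho1", "z"), c("v", "h1"), c("v", "h2"),
    c("z", "h4"), c("z", "1"),
    c("rho2", "u1"), c("rho2", "w"), c("u1", "h1"), c("u1", "q"),
    c("q", "h3"), c("q", "2"), c("w", "h2"), c("w", "h4"),
    c("h1", "t"), c("t", "p"), c("t", "3"), c("p", "h3"), c("p", "4"),
    c("h2", "5"), c("h3", "6"), c("h4", "7")),
  # universal forest-based network on {1,2,3}: all four phylogenetic
  # forests on three labels are base forests
  fig10 = rbind(
    c("rho", "a"), c("rho", "b"), c("a", "2"), c("a", "h1"),
    c("b", "3"), c("b", "h1"), c("h1", "1")),
  # relaxed 2-rooted graph with an indegree-3 hybrid h2; based on a
  # two-tree forest via three contact arcs; gamma graph has a triangle
  fig9 = rbind(
    c("rho1", "1"), c("rho1", "a"), c("a", "h1"), c("a", "c"),
    c("c", "h2"), c("c", "2"),
    c("rho2", "3"), c("rho2", "b"), c("b", "h1"), c("b", "d"),
    c("d", "h2"), c("d", "4"),
    c("h1", "e"), c("e", "h2"), c("e", "5"), c("h2", "6")),
  # ten binary phylogenetic networks realizing the distinct class-membership
  # regions of the tree / tree-child / forest-based / tree-based /
  # tree-sibling / reticulation-visible diagram; expected flag patterns are
  # recorded in fig4_patterns
  fig4A = rbind(
    c("v1", "3"), c("v1", "v2"), c("v2", "1"), c("v2", "2")),
  fig4B = rbind(
    c("h1", "2"), c("v1", "3"), c("v1", "v3"), c("v2", "1"), c("v2", "h1"),
    c("v3", "h1"), c("v3", "v2")),
  fig4C = rbind(
    c("h1", "3"), c("h2", "v2"), c("v1", "v3"), c("v1", "v4"), c("v2", "2"),
    c("v2", "h1"), c("v3", "h1"), c("v3", "h2"), c("v4", "1"), c("v4", "h2")),
  fig4D = rbind(
    c("h1", "3"), c("h2", "h1"), c("v1", "2"), c("v1", "v4"), c("v2", "1"),
    c("v2", "h2"), c("v3", "h1"), c("v3", "v2"), c("v4", "h2"), c("v4", "v3")),
  fig4E = rbind(
    c("h1", "1"), c("h2", "3"), c("v1", "v2"), c("v1", "v3"), c("v2", "2"),
    c("v2", "v4"), c("v3", "h1"), c("v3", "h2"), c("v4", "h1"), c("v4", "h2")),
  fig4F = rbind(
    c("h1", "v5"), c("h2", "2"), c("h3", "h2"), c("v1", "1"), c("v1", "v3"),
    c("v2", "h1"), c("v2", "h2"), c("v3", "v2"), c("v3", "v4"), c("v4", "h1"),
    c("v4", "h3"), c("v5", "3"), c("v5", "h3")),
  fig4G = rbind(
    c("h1", "1"), c("h2", "h1"), c("h3", "v3"), c("v1", "3"), c("v1", "v5"),
    c("v2", "h1"), c("v2", "v4"), c("v3", "2"), c("v3", "h2"), c("v4", "h2"),
    c("v4", "h3"), c("v5", "h3"), c("v5", "v2")),
  fig4H = rbind(
    c("h1", "v5"), c("h2", "2"), c("h3", "1"), c("v1", "3"), c("v1", "v2"),
    c("v2", "h1"), c("v2", "v3"), c("v3", "h1"), c("v3", "h2"), c("v4", "h2"),
    c("v4", "h3"), c("v5", "h3"), c("v5", "v4")),
  fig4I = rbind(
    c("h1", "h2"), c("h2", "3"), c("v1", "v2"), c("v1", "v4"), c("v2", "1"),
    c("v2", "v3"), c("v3", "2"), c("v3", "h1"), c("v4", "h1"), c("v4", "h2")),
  fig4J = rbind(
    c("h1", "2"), c("h2", "h1"), c("h3", "h1"), c("v1", "1"), c("v1", "v5"),
    c("v2", "3"), c("v2", "h2"), c("v3", "h3"), c("v3", "v2"), c("v4", "h2"),
    c("v4", "v3"), c("v5", "h3"), c("v5", "v4"))
)

#' Documented class-flag patterns of the `fig4A` .. `fig4J` fixtures
#'
#' Each row gives the expected membership of one fixture in the classes
#' tree, tree-child, forest-based, tree-based, tree-sibling and
#' reticulation-visible.  The ten patterns are pairwise distinct and realize
#' the regions of the class-relationship diagram consistent with the known
#' containments (tree-child networks are forest-based, tree-sibling and
#' reticulation-visible; binary forest-based phylogenetic networks are
#' tree-based).
#'
#' @return A data frame with one row per fixture.
#' @export
fig4_patterns <- function() {
  pat <- rbind(
    fig4A = c(1, 1, 1, 1, 1, 1),
    fig4B = c(0, 1, 1, 1, 1, 1),
    fig4C = c(0, 0, 1, 1, 1, 1),
    fig4D = c(0, 0, 1, 1, 1, 0),
    fig4E = c(0, 0, 1, 1, 0, 1),
    fig4F = c(0, 0, 1, 1, 0, 0),
    fig4G = c(0, 0, 0, 1, 1, 0),
    fig4H = c(0, 0, 0, 1, 0, 1),
    fig4I = c(0, 0, 0, 1, 0, 0),
    fig4J = c(0, 0, 0, 0, 0, 0))
  out <- data.frame(fixture = rownames(pat),
                    is_tree = pat[, 1] == 1,
                    is_tree_child = pat[, 2] == 1,
                    is_forest_based = pat[, 3] == 1,
                    is_tree_based = pat[, 4] == 1,
                    is_tree_sibling = pat[, 5] == 1,
                    is_reticulation_visible = pat[, 6] == 1,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

fixture_modes <- list(fig9 = "relaxed")

#' Reference fixture networks
#'
#' Small reference networks, each constructed to exhibit a documented
#' combination of structural facts (root and leaf counts, class memberships,
#' forest-based verdicts, gamma-graph structure).  The arc sets are this
#' package's own synthetic constructions and the tests assert exactly those
#' documented facts.  Available names: `fig2`, `fig5`, `fig6N`, `fig6Nprime`,
#' `fig7`, `fig8`, `fig9` (relaxed), `fig10`, and `fig4A` .. `fig4J`.
#'
#' @param name fixture name.
#' @return A validated `fbnet_network`.
#' @export
fixture <- function(name) {
  if (!name %in% names(fixture_arcs))
    stop("unknown fixture: ", name, call. = FALSE)
  mode <- fixture_modes[[name]]
  if (is.null(mode)) mode <- "strict"
  network(fixture_arcs[[name]], mode = mode)
}

#' @rdname fixture
#' @export
fixture_names <- function() sort(names(fixture_arcs))
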