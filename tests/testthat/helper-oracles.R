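# Independent brute-force oracles used to cross-check the package's
# algorithms.  These deliberately re-derive results from first principles and
# share no code with the implementation paths they test.

# exhaustive base-tree search: a binary phylogenetic network is tree-based
# iff deleting one incoming arc per hybrid can leave a spanning tree with
# leaf set X
brute_tree_based <- function(net) {
  hyb <- sort(hybrids(net))
  A <- net$arcs
  lf <- leaves(net)
  if (length(hyb) == 0L) return(TRUE)
  inc <- lapply(hyb, function(h) which(A[, 2L] == h))
  grid <- expand.grid(inc, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    dropped <- setdiff(unlist(inc), unlist(grid[r, ]))
    kept <- A[-dropped, , drop = FALSE]
    # spanning tree: |V| - 1 arcs (yes: one per non-root vertex), connected,
    # acyclic undirected, leaves preserved
    if (nrow(kept) != length(net$vertices) - 1L) next
    g <- igraph::graph_from_data_frame(
      as.data.frame(kept, stringsAsFactors = FALSE), directed = FALSE,
      vertices = data.frame(name = net$vertices, stringsAsFactors = FALSE))
    if (igraph::count_components(g) != 1L) next
    f_leaves <- sort(net$vertices[!(net$vertices %in% kept[, 1L])])
    if (identical(f_leaves, lf)) return(TRUE)
  }
  FALSE
}

# direct path enumeration: does any root-or-tree vertex have two directed
# paths to x and to y whose internal vertices are all hybrids, leaving w by
# two distinct arcs?
brute_forbidden_config <- function(net, x, y) {
  hyb <- hybrids(net)
  ind <- fbnet:::indegree(net)
  out <- fbnet:::outdegree(net)
  hybrid_only_first <- function(w, target) {
    # children a of w from which a hybrid-only directed path leads to target
    firsts <- character(0)
    for (a in net$kids[[w]]) {
      stack <- list(a)
      repeat {
        if (length(stack) == 0L) break
        v <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (identical(v, target)) { firsts <- c(firsts, a); break }
        if (v %in% hyb) stack <- c(stack, as.list(net$kids[[v]]))
      }
    }
    unique(firsts)
  }
  for (w in net$vertices[ind <= 1L & out >= 2L]) {
    ax <- hybrid_only_first(w, x)
    ay <- hybrid_only_first(w, y)
    if (length(ax) >= 1L && length(ay) >= 1L &&
        length(union(ax, ay)) >= 2L) return(TRUE)
  }
  FALSE
}

# pairwise-subset computation of the set-inclusion maximal clusters
oracle_maximal_clusters <- function(clusters) {
  keep <- vapply(seq_along(clusters), function(i) {
    !any(vapply(seq_along(clusters), function(j) {
      i != j && all(clusters[[i]] %in% clusters[[j]]) &&
        length(clusters[[j]]) > length(clusters[[i]])
    }, logical(1)))
  }, logical(1))
  clusters[keep]
}

# Prop-2-style swap around a bad arc (u,v): exchange the incoming arcs of u
# and v drawn from outside the chain; preserves the cluster system
bad_arc_swap <- function(net) {
  ba <- bad_arcs(net)
  if (nrow(ba) == 0L) return(NULL)
  u <- ba[1L, 1L]; v <- ba[1L, 2L]
  pu <- net$pars[[u]][1L]
  pv <- setdiff(net$pars[[v]], u)[1L]
  A <- net$arcs
  drop <- (A[, 1L] == pu & A[, 2L] == u) | (A[, 1L] == pv & A[, 2L] == v)
  A <- rbind(A[!drop, , drop = FALSE], c(pu, v), c(pv, u))
  network(A, mode = net$mode)
}

# the base forest induced by a C1/C2 coloring: vertices v with the same
# color of gamma(v) form one tree; arcs inside a class are kept
coloring_to_certificate <- function(net, coloring) {
  vr <- vertex_roles(net)
  gam <- stats::setNames(vr$gamma, vr$vertex)
  cls <- stats::setNames(unname(coloring[gam[net$vertices]]), net$vertices)
  A <- net$arcs
  kept <- cls[A[, 1L]] == cls[A[, 2L]]
  contact_certificate(net, A[!kept, , drop = FALSE])
}

# --- exhaustive enumeration of small arboreal networks ----------------------

# all unlabeled trees on n vertices, as integer edge matrices
all_unlabeled_trees <- local({
  cache <- list()
  ahu_key <- function(edges, n) {
    adj <- lapply(seq_len(n), function(v)
      c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L]))
    rooted <- function(v, par) {
      ch <- setdiff(adj[[v]], par)
      if (length(ch) == 0L) return("()")
      paste0("(", paste(sort(vapply(ch, rooted, character(1), par = v)),
                        collapse = ""), ")")
    }
    # centers by leaf pruning
    deg <- vapply(adj, length, integer(1))
    alive <- rep(TRUE, n)
    cnt <- n
    while (cnt > 2L) {
      lv <- which(alive & deg <= 1L)
      for (v in lv) {
        alive[v] <- FALSE
        for (w in adj[[v]]) if (alive[w]) deg[w] <- deg[w] - 1L
      }
      cnt <- cnt - length(lv)
    }
    ctr <- which(alive)
    if (length(ctr) == 1L) return(rooted(ctr, 0L))
    paste(sort(c(rooted(ctr[1L], ctr[2L]), rooted(ctr[2L], ctr[1L]))),
          collapse = "+")
  }
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (n == 1L) {
      res <- list(matrix(integer(0), ncol = 2L))
    } else {
      prev <- all_unlabeled_trees(n - 1L)
      seen <- character(0)
      res <- list()
      for (tr in prev) {
        for (v in seq_len(n - 1L)) {
          edges <- rbind(tr, c(v, n))
          k <- ahu_key(edges, n)
          if (!(k %in% seen)) {
            seen <- c(seen, k)
            res[[length(res) + 1L]] <- edges
          }
        }
      }
    }
    cache[[key]] <<- res
    res
  }
})

# all strict arboreal networks with >= 1 hybrid and at most n_max vertices,
# over all leaf labelings 1..#leaves; returned as fbnet_network objects
enumerate_arboreal_networks <- function(n_max) {
  out <- list()
  for (n in 4:n_max) {
    for (tr in all_unlabeled_trees(n)) {
      ne <- nrow(tr)
      for (mask in 0:(2^ne - 1L)) {
        tails <- ifelse(bitwAnd(2^(seq_len(ne) - 1L), mask) > 0L,
                        tr[, 2L], tr[, 1L])
        heads <- ifelse(bitwAnd(2^(seq_len(ne) - 1L), mask) > 0L,
                        tr[, 1L], tr[, 2L])
        ind <- tabulate(heads, nbins = n)
        outd <- tabulate(tails, nbins = n)
        if (any(ind >= 3L)) next
        if (any(ind == 2L & outd != 1L)) next          # semi-binary
        if (sum(ind == 2L) == 0L) next                 # want hybrids
        if (any(ind == 0L & outd < 2L)) next           # root outdegree
        if (any(ind == 1L & outd == 1L)) next          # unary tree vertex
        if (any(ind == 0L & outd == 0L)) next
        lf <- which(outd == 0L)
        nonlf <- setdiff(seq_len(n), lf)
        for (perm in all_perms(length(lf))) {
          ids <- character(n)
          ids[lf] <- as.character(perm)
          ids[nonlf] <- paste0("n", nonlf)
          A <- cbind(ids[tails], ids[heads])
          out[[length(out) + 1L]] <- fbnet:::new_network(
            ids, fbnet:::normalize_arcs(A), "strict")
        }
      }
    }
  }
  out
}

all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) {
    for (i in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = i)
    }
  }
  out
}

clusters_sig <- function(net) {
  fbnet:::clusters_key(cluster_system(net)$clusters)
}
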