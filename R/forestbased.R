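#' Contact-arc certificates
#'
#' A certificate that a network is forest-based: a set I of contact arcs such
#' that the spanning forest (V, A - I) has the same leaf set as the network
#' and every arc of I joins two different trees of the forest; the base
#' forest is the suppression of the spanning forest.
#'
#' @param net the host `fbnet_network`.
#' @param contact_arcs two-column character matrix of contact arcs.
#' @return An object of class `fbnet_certificate` with fields `contact_arcs`,
#'   `spanning_forest` and `base_forest`.
#' @export
contact_certificate <- function(net, contact_arcs) {
  I <- normalize_arcs(contact_arcs)
  keyI <- paste(I[, 1L], I[, 2L], sep = "\r")
  keyA <- paste(net$arcs[, 1L], net$arcs[, 2L], sep = "\r")
  if (!all(keyI %in% keyA))
    stop("contact arcs must be arcs of the network", call. = FALSE)
  kept <- net$arcs[!(keyA %in% keyI), , drop = FALSE]
  sf <- spanning_forest(net, kept)
  structure(list(contact_arcs = I, spanning_forest = sf,
                 base_forest = suppress(sf)),
            class = "fbnet_certificate")
}

#' @export
print.fbnet_certificate <- function(x, ...) {
  cat(sprintf("<fbnet_certificate: %d contact arc%s>\n", nrow(x$contact_arcs),
              if (nrow(x$contact_arcs) == 1L) "" else "s"))
  if (nrow(x$contact_arcs) > 0L)
    cat(paste0("  ", x$contact_arcs[, 1L], " -> ", x$contact_arcs[, 2L],
               collapse = "\n"), "\n")
  print(x$base_forest)
  invisible(x)
}

#' Re-validate a contact-arc certificate
#'
#' Checks, independently of how the certificate was produced, that the kept
#' arcs form a forest (indegree at most one, no undirected cycle), that its
#' leaf set equals the network's, and that every contact arc has its end
#' vertices in different trees.
#'
#' @param net the host `fbnet_network`.
#' @param cert an `fbnet_certificate`.
#' @return `TRUE` or `FALSE`.
#' @export
validate_contact_certificate <- function(net, cert) {
  keyA <- paste(net$arcs[, 1L], net$arcs[, 2L], sep = "\r")
  keyI <- paste(cert$contact_arcs[, 1L], cert$contact_arcs[, 2L], sep = "\r")
  if (!all(keyI %in% keyA)) return(FALSE)
  kept <- net$arcs[!(keyA %in% keyI), , drop = FALSE]
  if (anyDuplicated(kept[, 2L]) > 0L) return(FALSE)
  sf <- spanning_forest(net, kept)
  # forest: n vertices, k arcs, n - k components (checks undirected acyclicity)
  comp <- forest_components(sf)
  if (length(unique(comp)) != length(net$vertices) - nrow(kept)) return(FALSE)
  # leaf preservation
  f_leaves <- net$vertices[!(net$vertices %in% kept[, 1L])]
  if (!identical(sort(f_leaves), leaves(net))) return(FALSE)
  # crossing condition
  if (nrow(cert$contact_arcs) > 0L) {
    for (k in seq_len(nrow(cert$contact_arcs))) {
      if (comp[[cert$contact_arcs[k, 1L]]] == comp[[cert$contact_arcs[k, 2L]]])
        return(FALSE)
    }
  }
  # base forest consistency
  identical(forest_key(suppress(sf)), forest_key(cert$base_forest))
}

# --- exhaustive spanning-forest enumeration engine ------------------------
#
# Enumerates every arc subset A' of the network with all indegrees <= 1 whose
# underlying graph is a forest, whose leaf set equals L(N), and in which every
# dropped arc joins two different trees.  Vertices are processed in
# topological order, choosing for each vertex which incoming arc (if any) to
# keep; branches are pruned when a kept arc would close an undirected cycle
# or when a non-leaf vertex has irrevocably lost all its outgoing arcs.
# `accept(kept, ncomp)` is called with the logical arc mask and the number of
# trees of the forest; a non-NULL return stops the search and is passed
# through.
enumerate_spanning_forests <- function(net, accept) {
  A <- net$arcs
  nA <- nrow(A)
  verts <- net$vertices
  nV <- length(verts)
  vid <- stats::setNames(seq_len(nV), verts)
  lf <- leaves(net)
  is_leaf <- verts %in% lf
  ord <- topo_order(net)
  inc <- lapply(verts, function(v) which(A[, 2L] == v))
  names(inc) <- verts
  out <- lapply(verts, function(v) which(A[, 1L] == v))
  names(out) <- verts
  # vertices in topological order that have incoming arcs
  todo <- ord[vapply(ord, function(v) length(inc[[v]]) > 0L, logical(1))]

  uf_find <- function(uf, i) {
    while (uf[i] != i) i <- uf[i]
    i
  }

  result <- NULL
  rec <- function(k, uf, kept, kept_out, undec_out) {
    if (!is.null(result)) return(invisible(NULL))
    if (k > length(todo)) {
      # crossing condition for dropped arcs
      for (a in which(!kept)) {
        if (uf_find(uf, vid[[A[a, 1L]]]) == uf_find(uf, vid[[A[a, 2L]]]))
          return(invisible(NULL))
      }
      result <<- accept(kept, nV - sum(kept))
      return(invisible(NULL))
    }
    v <- todo[[k]]
    iv <- vid[[v]]
    choices <- c(0L, inc[[v]])   # 0 = keep no incoming arc
    for (ch in choices) {
      uf2 <- uf; kept2 <- kept; ko2 <- kept_out; un2 <- undec_out
      ok <- TRUE
      if (ch > 0L) {
        tl <- vid[[A[ch, 1L]]]
        ra <- uf_find(uf2, tl); rb <- uf_find(uf2, iv)
        if (ra == rb) next          # undirected cycle
        uf2[ra] <- rb
        kept2[ch] <- TRUE
      }
      # all incoming arcs of v are now decided; update tails' out bookkeeping
      for (a in inc[[v]]) {
        tl <- vid[[A[a, 1L]]]
        un2[tl] <- un2[tl] - 1L
        if (kept2[a]) ko2[tl] <- ko2[tl] + 1L
        if (un2[tl] == 0L && ko2[tl] == 0L && !is_leaf[tl]) { ok <- FALSE; break }
      }
      # leaves must stay leaves automatically (they have no outgoing arcs);
      # but a leaf that keeps no incoming arc is fine (isolated component)
      if (ok) rec(k + 1L, uf2, kept2, ko2, un2)
      if (!is.null(result)) return(invisible(NULL))
    }
    invisible(NULL)
  }

  rec(1L, seq_len(nV), rep(FALSE, nA),
      stats::setNames(rep(0L, nV), NULL),
      vapply(seq_len(nV), function(i) length(out[[verts[i]]]), integer(1)))
  result
}

check_strict_fb_input <- function(net, min_leaves = 2L) {
  if (net$mode != "strict")
    stop("forest-based recognition requires a strict (semi-binary) network",
         call. = FALSE)
  if (length(leaves(net)) < min_leaves)
    stop("forest-basedness is undefined for networks with fewer than two leaves",
         call. = FALSE)
}

#' Exhaustive forest-based oracle
#'
#' Ground-truth decision procedure: enumerates arc subsets I of the network
#' and accepts the first one for which (V, A - I) is a forest with the same
#' leaf set as the network and every arc of I joins two of its trees.  Meant
#' as an oracle for small networks; refuses inputs above the arc budget.
#'
#' @param net a strict `fbnet_network` with at least two leaves.
#' @param arc_budget maximum number of arcs accepted (default 18).
#' @return An `fbnet_certificate`, or `NULL` when the network is not
#'   forest-based.
#' @export
oracle_is_forest_based <- function(net, arc_budget = 18L) {
  check_strict_fb_input(net)
  if (nrow(net$arcs) > arc_budget)
    stop("network exceeds the oracle arc budget (", arc_budget, " arcs)",
         call. = FALSE)
  A <- net$arcs
  res <- enumerate_spanning_forests(net, function(kept, ncomp) {
    if (ncomp < 2L) return(NULL)     # a forest has at least two trees
    contact_certificate(net, A[!kept, , drop = FALSE])
  })
  res
}

#' Forest-based recognition via path partitions
#'
#' A network is forest-based exactly when the trivial forest embeds into it
#' as a union of vertex-disjoint directed paths, one per leaf, such that no
#' arc of the network joins two non-consecutive vertices of the same path.
#' The decider backtracks over one successor choice per non-leaf vertex,
#' pruning on chosen indegree and on chord detection at every path merge.
#'
#' @param net a strict `fbnet_network` with at least two leaves.
#' @return A list with `based` (logical); when `TRUE` also `successor` (the
#'   path partition: named vector mapping each non-leaf vertex to its chosen
#'   child) and `certificate` (the corresponding [contact_certificate()],
#'   whose base forest is the trivial forest).
#' @export
is_forest_based <- function(net) {
  check_strict_fb_input(net)
  A <- net$arcs
  verts <- net$vertices
  nV <- length(verts)
  vid <- stats::setNames(seq_len(nV), verts)
  lf <- leaves(net)
  nonleaf <- setdiff(verts, lf)    # lexicographic processing order
  kids_idx <- lapply(verts, function(v) which(A[, 1L] == v))
  names(kids_idx) <- verts
  # adjacency among vertex ids (either direction, as tail->head index pairs)
  arc_tl <- vid[A[, 1L]]
  arc_hd <- vid[A[, 2L]]

  uf_find <- function(uf, i) {
    while (uf[i] != i) i <- uf[i]
    i
  }

  result <- NULL
  rec <- function(k, uf, succ, chosen_arc, chosen_in) {
    if (!is.null(result)) return(invisible(NULL))
    if (k > length(nonleaf)) {
      result <<- succ
      return(invisible(NULL))
    }
    v <- nonleaf[[k]]
    iv <- vid[[v]]
    for (a in kids_idx[[v]]) {
      w <- arc_hd[[a]]
      if (chosen_in[w]) next
      ra <- uf_find(uf, iv); rb <- uf_find(uf, w)
      # ra == rb cannot happen in a DAG (v is a path end, w a path start).
      # chord check: a non-path arc joining the two merged paths would join
      # two non-consecutive vertices of the combined path
      chord <- FALSE
      for (b in seq_along(arc_tl)) {
        if (b == a || chosen_arc[b]) next
        tb <- uf_find(uf, arc_tl[[b]])
        if (tb != ra && tb != rb) next
        hb <- uf_find(uf, arc_hd[[b]])
        if (hb == ra || hb == rb) { chord <- TRUE; break }
      }
      if (chord) next
      uf2 <- uf; uf2[ra] <- rb
      succ2 <- succ; succ2[[v]] <- A[a, 2L]
      ca2 <- chosen_arc; ca2[a] <- TRUE
      ci2 <- chosen_in; ci2[w] <- TRUE
      rec(k + 1L, uf2, succ2, ca2, ci2)
      if (!is.null(result)) return(invisible(NULL))
    }
    invisible(NULL)
  }

  rec(1L, seq_len(nV),
      stats::setNames(character(length(nonleaf)), nonleaf),
      rep(FALSE, nrow(A)),
      rep(FALSE, nV))

  if (is.null(result)) return(list(based = FALSE))
  chosen <- cbind(nonleaf, unname(result[nonleaf]))
  keyA <- paste(A[, 1L], A[, 2L], sep = "\r")
  keyC <- paste(chosen[, 1L], chosen[, 2L], sep = "\r")
  cert <- contact_certificate(net, A[!(keyA %in% keyC), , drop = FALSE])
  list(based = TRUE, successor = result, certificate = cert)
}

mu_graph <- function(net) {
  hyb <- hybrids(net)
  edges <- NULL
  for (h in hyb) {
    p <- net$pars[[h]]
    edges <- rbind(edges, c(sort(p), h))
  }
  edges   # columns: endpoint1, endpoint2, hybrid label
}

#' Forest-based recognition for arboreal networks
#'
#' An arboreal network (underlying undirected graph a tree) is forest-based
#' exactly when every hybrid vertex h admits a sequence of distinct vertices
#' starting at h in which consecutive vertices share a hybrid child and the
#' last vertex has a non-hybrid child.  When the condition holds, the
#' share-a-hybrid-child graph over parents of hybrids is oriented towards
#' vertices with non-hybrid children and a contact-arc certificate with one
#' removed arc per hybrid is produced; such a certificate has one base-forest
#' component per root, so the network is then proper forest-based whenever it
#' has two or more roots.
#'
#' @param net a strict arboreal `fbnet_network` with at least two leaves.
#' @return A list with `based` (logical); when `TRUE` also `certificate`,
#'   else `witness`, a hybrid admitting no such sequence.
#' @export
arboreal_forest_based <- function(net) {
  check_strict_fb_input(net)
  if (!is_arboreal(net))
    stop("network is not arboreal", call. = FALSE)
  hyb <- hybrids(net)
  if (length(hyb) == 0L) {
    return(list(based = TRUE,
                certificate = contact_certificate(net, NULL)))
  }
  mu <- mu_graph(net)
  mu_vs <- sort(unique(c(mu[, 1L], mu[, 2L])))
  nbr <- lapply(mu_vs, function(v) {
    rows <- mu[, 1L] == v | mu[, 2L] == v
    unique(c(mu[rows, 1L], mu[rows, 2L]))
  })
  names(nbr) <- mu_vs
  good <- vapply(mu_vs, function(v) {
    any(!(net$kids[[v]] %in% hyb))
  }, logical(1))
  names(good) <- mu_vs

  # sequence existence per hybrid = reachability in mu to a good vertex
  reach_good <- function(h) {
    if (any(!(net$kids[[h]] %in% hyb))) return(TRUE)   # k = 1
    seen <- character(0); stack <- h
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (v %in% seen) next
      seen <- c(seen, v)
      if (good[[v]]) return(TRUE)
      stack <- c(stack, setdiff(setdiff(nbr[[v]], v), seen))
    }
    FALSE
  }
  for (h in sort(hyb)) {
    if (!reach_good(h)) return(list(based = FALSE, witness = h))
  }

  # orient each component of mu towards a good root: BFS from the
  # lexicographically least good vertex; every edge points parent-wards
  head_of <- stats::setNames(character(nrow(mu)), mu[, 3L])
  unseen <- mu_vs
  while (length(unseen) > 0L) {
    comp_good <- sort(unseen[vapply(unseen, function(v) isTRUE(good[[v]]),
                                    logical(1))])
    # component of the least good vertex among unseen
    root <- comp_good[[1L]]
    lev <- stats::setNames(0L, root)
    queue <- root
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in setdiff(nbr[[v]], v)) {
        if (!(w %in% names(lev))) {
          lev[[w]] <- lev[[v]] + 1L
          queue <- c(queue, w)
        }
      }
    }
    comp_vs <- names(lev)
    for (k in seq_len(nrow(mu))) {
      if (mu[k, 1L] %in% comp_vs) {
        # orient towards the root: head = endpoint nearer the root
        a <- mu[k, 1L]; b <- mu[k, 2L]
        head_of[[mu[k, 3L]]] <- if (lev[[a]] < lev[[b]]) a else b
      }
    }
    unseen <- setdiff(unseen, comp_vs)
  }

  I <- cbind(unname(head_of[sort(hyb)]), sort(hyb))
  list(based = TRUE, certificate = contact_certificate(net, I))
}

#' Proper forest-based recognition
#'
#' An m-rooted network (m >= 2) is proper forest-based when it has a base
#' forest with exactly m trees.  Equivalently, one incoming arc can be
#' deleted from every hybrid so that the remaining arcs form a forest with
#' the network's leaf set in which every deleted arc joins two different
#' trees: deleting a tree vertex's incoming arc or both arcs of a hybrid
#' would create an extra forest root, so the exactly-one-per-hybrid shape is
#' forced.  The decision enumerates these deletions directly.
#'
#' @param net a strict `fbnet_network` with at least two roots.
#' @return A list with `proper` (logical) and, when `TRUE`, `certificate`.
#' @export
is_proper_forest_based <- function(net) {
  check_strict_fb_input(net)
  m <- length(roots(net))
  if (m < 2L)
    stop("proper forest-basedness is defined for networks with >= 2 roots",
         call. = FALSE)
  hyb <- sort(hybrids(net))
  verts <- net$vertices
  vid <- stats::setNames(seq_along(verts), verts)
  A <- net$arcs
  lf <- leaves(net)

  if (length(hyb) == 0L) return(list(proper = FALSE))  # connected => m == 1

  inc <- lapply(hyb, function(h) which(A[, 2L] == h))
  names(inc) <- hyb

  uf_find <- function(uf, i) {
    while (uf[i] != i) i <- uf[i]
    i
  }

  grid_result <- NULL
  rec <- function(k, drop_idx) {
    if (!is.null(grid_result)) return(invisible(NULL))
    if (k > length(hyb)) {
      kept <- rep(TRUE, nrow(A)); kept[drop_idx] <- FALSE
      # forest check via union-find on kept arcs
      uf <- seq_along(verts)
      for (a in which(kept)) {
        ra <- uf_find(uf, vid[[A[a, 1L]]]); rb <- uf_find(uf, vid[[A[a, 2L]]])
        if (ra == rb) return(invisible(NULL))
        uf[ra] <- rb
      }
      # leaf preservation
      f_leaves <- verts[!(verts %in% A[kept, 1L])]
      if (!identical(sort(f_leaves), lf)) return(invisible(NULL))
      # crossing condition
      for (a in drop_idx) {
        if (uf_find(uf, vid[[A[a, 1L]]]) == uf_find(uf, vid[[A[a, 2L]]]))
          return(invisible(NULL))
      }
      grid_result <<- contact_certificate(net, A[drop_idx, , drop = FALSE])
      return(invisible(NULL))
    }
    for (a in inc[[hyb[[k]]]]) {   # a = the incoming arc this hybrid keeps
      dropped <- setdiff(inc[[hyb[[k]]]], a)
      rec(k + 1L, c(drop_idx, dropped))
      if (!is.null(grid_result)) return(invisible(NULL))
    }
    invisible(NULL)
  }
  rec(1L, integer(0))

  if (is.null(grid_result)) list(proper = FALSE)
  else list(proper = TRUE, certificate = grid_result)
}

#' Is a given phylogenetic forest a base forest of a network?
#'
#' Searches over the spanning forests of the network (drop one or both
#' incoming arcs per hybrid, optionally drop a tree vertex's incoming arc)
#' for one whose suppression equals the given forest.
#'
#' @param net a strict `fbnet_network`.
#' @param forest an `fbnet_forest` on the network's leaf set.
#' @param arc_budget maximum number of arcs accepted (default 24).
#' @return `TRUE` or `FALSE`.
#' @export
is_base_forest <- function(net, forest, arc_budget = 24L) {
  check_strict_fb_input(net)
  if (!identical(attr(forest, "labels"), leaves(net)))
    stop("forest label set does not match the network's leaf set",
         call. = FALSE)
  if (nrow(net$arcs) > arc_budget)
    stop("network exceeds the arc budget (", arc_budget, " arcs)",
         call. = FALSE)
  key <- forest_key(forest)
  A <- net$arcs
  nt <- length(forest)
  res <- enumerate_spanning_forests(net, function(kept, ncomp) {
    if (ncomp != nt) return(NULL)
    sf <- spanning_forest(net, A[kept, , drop = FALSE])
    if (identical(forest_key(suppress(sf)), key)) TRUE else NULL
  })
  isTRUE(res)
}

#' Universality of a forest-based network
#'
#' A network on X is universal forest-based when every phylogenetic forest on
#' X is one of its base forests.  The check is exhaustive over
#' [enumerate_forests()] and is therefore guarded to small label sets.
#'
#' @param net a strict `fbnet_network` with at most 5 leaves.
#' @return `TRUE` or `FALSE`.
#' @export
is_universal_forest_based <- function(net) {
  check_strict_fb_input(net)
  X <- leaves(net)
  if (length(X) > 5L)
    stop("universality check is exhaustive and limited to <= 5 leaves",
         call. = FALSE)
  for (f in enumerate_forests(X)) {
    if (!is_base_forest(net, f, arc_budget = nrow(net$arcs))) return(FALSE)
  }
  TRUE
}

#' Detect the forbidden configuration of universal networks
#'
#' Tests whether two leaves x and y hang below a common root-or-tree vertex w
#' through two chains consisting entirely of hybrid vertices (possibly of
#' length zero).  Universal forest-based networks on four or more labels
#' cannot contain this configuration.
#'
#' @param net a strict `fbnet_network`.
#' @param x,y distinct leaf labels.
#' @return `TRUE` or `FALSE`.
#' @export
has_forbidden_configuration <- function(net, x, y) {
  stopifnot(x != y, x %in% leaves(net), y %in% leaves(net))
  hyb <- hybrids(net)
  # deterministic walk: from a child a of w, follow unique hybrid children;
  # succeeds iff the chain (possibly empty) ends exactly at the target leaf
  chain_reaches <- function(a, target) {
    steps <- 0L
    while (a %in% hyb) {
      a <- net$kids[[a]][1L]
      steps <- steps + 1L
      if (steps > length(net$vertices)) return(FALSE)
    }
    identical(a, target)
  }
  ind <- indegree(net)
  out <- outdegree(net)
  wcand <- net$vertices[(ind <= 1L) & out >= 2L]   # roots and tree vertices
  for (w in wcand) {
    ch <- net$kids[[w]]
    for (a in ch) {
      if (!chain_reaches(a, x)) next
      for (b in setdiff(ch, a)) {
        if (chain_reaches(b, y)) return(TRUE)
      }
    }
  }
  FALSE
}
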