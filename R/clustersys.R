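#' Cluster systems on a label set
#'
#' A cluster system is a collection of non-empty subsets (clusters) of a
#' ground set X of taxon labels.
#'
#' @param labels the ground set X.
#' @param clusters a list of character vectors, each a non-empty subset of
#'   `labels`; duplicates are collapsed.
#' @return An object of class `fbnet_clusters`: the canonical list of
#'   clusters with attribute `labels`.
#' @export
cluster_system_on <- function(labels, clusters) {
  labels <- sort(unique(as.character(labels)))
  clusters <- canon_clusters(clusters)
  if (any(vapply(clusters, length, integer(1)) == 0L))
    stop("clusters must be non-empty", call. = FALSE)
  bad <- !vapply(clusters, function(c) all(c %in% labels), logical(1))
  if (any(bad))
    stop("cluster {", cluster_key(clusters[[which(bad)[1L]]]),
         "} is not a subset of the label set", call. = FALSE)
  structure(clusters, labels = labels, class = "fbnet_clusters")
}

#' @export
print.fbnet_clusters <- function(x, ...) {
  cat(sprintf("<fbnet_clusters: %d clusters on {%s}>\n", length(x),
              paste(attr(x, "labels"), collapse = ",")))
  cat(" ", paste(vapply(x, function(c) paste0("{", cluster_key(c), "}"),
                        character(1)), collapse = " "), "\n")
  invisible(x)
}

clusters_key <- function(cs) {
  paste(sort(vapply(cs, cluster_key, character(1))), collapse = "|")
}

#' Is a cluster system a hierarchy?
#'
#' A hierarchy on X contains all trivial clusters and X itself, and any two of
#' its clusters are nested or disjoint.
#'
#' @param cs an `fbnet_clusters` object.
#' @return `TRUE` or `FALSE`.
#' @export
is_hierarchy <- function(cs) {
  stopifnot(inherits(cs, "fbnet_clusters"))
  labels <- attr(cs, "labels")
  keys <- vapply(cs, cluster_key, character(1))
  if (!all(labels %in% keys)) return(FALSE)
  if (!(cluster_key(labels) %in% keys)) return(FALSE)
  is_hierarchy_clusters(cs)
}

#' Maximal clusters of a cluster system
#'
#' @param cs an `fbnet_clusters` object.
#' @return The set-inclusion maximal clusters, as a plain list.
#' @export
maximal_clusters <- function(cs) {
  n <- length(cs)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && keep[i] &&
          length(cs[[i]]) <= length(cs[[j]]) &&
          all(cs[[i]] %in% cs[[j]]) &&
          !identical(cs[[i]], cs[[j]]))
        keep[i] <- FALSE
    }
  }
  cs[keep]
}

#' Check the realizability properties of a cluster system
#'
#' Evaluates the three properties that characterize cluster systems of
#' arboreal networks: (P1) for every maximal cluster C, the clusters contained
#' in C form a hierarchy on C containing all trivial clusters; (P2) the
#' intersection graph of the maximal clusters is connected; (P3) the
#' intersection of any two maximal clusters is empty or itself a cluster of
#' the system.
#'
#' @param cs an `fbnet_clusters` object.
#' @return A list with logical fields `p1`, `p2`, `p3`, `ok` (their
#'   conjunction), `maximal` (the maximal clusters), and `witnesses`, one
#'   violating tuple per failed property.
#' @export
check_P123 <- function(cs) {
  stopifnot(inherits(cs, "fbnet_clusters"))
  keys <- vapply(cs, cluster_key, character(1))
  cm <- maximal_clusters(cs)
  witnesses <- list()

  p1 <- TRUE
  for (C in cm) {
    sub <- cs[vapply(cs, function(cc) all(cc %in% C), logical(1))]
    subsys <- cluster_system_on(C, sub)
    if (!is_hierarchy(subsys)) {
      p1 <- FALSE
      witnesses$p1 <- C
      break
    }
  }

  m <- length(cm)
  p2 <- TRUE
  if (m > 1L) {
    comp <- seq_len(m)
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        if (length(intersect(cm[[i]], cm[[j]])) > 0L)
          comp[comp == comp[j]] <- comp[i]
      }
    }
    p2 <- length(unique(comp)) == 1L
    if (!p2) witnesses$p2 <- cm
  }

  p3 <- TRUE
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        int <- intersect(cm[[i]], cm[[j]])
        if (length(int) > 0L && !(cluster_key(sort(int)) %in% keys)) {
          p3 <- FALSE
          witnesses$p3 <- list(cm[[i]], cm[[j]], int)
          break
        }
      }
      if (!p3) break
    }
  }

  list(p1 = p1, p2 = p2, p3 = p3, ok = p1 && p2 && p3,
       maximal = cm, witnesses = witnesses)
}

# hierarchy (canonical cluster list incl. trivial + full set) -> tree network
# arcs; internal vertex ids are prefixed to stay unique across glued trees
hierarchy_tree_arcs <- function(clusters, prefix) {
  ids <- vapply(clusters, function(c) {
    if (length(c) == 1L) c else paste0(prefix, "(", cluster_key(c), ")")
  }, character(1))
  names(ids) <- vapply(clusters, cluster_key, character(1))
  sizes <- vapply(clusters, length, integer(1))
  arcs <- NULL
  for (i in seq_along(clusters)) {
    if (sizes[i] == max(sizes)) next
    # parent = smallest strict superset
    sup <- which(vapply(clusters, function(cc)
      length(cc) > sizes[i] && all(clusters[[i]] %in% cc), logical(1)))
    par <- sup[which.min(sizes[sup])]
    arcs <- rbind(arcs, c(ids[[cluster_key(clusters[[par]])]],
                          ids[[cluster_key(clusters[[i]])]]))
  }
  list(arcs = arcs, ids = ids)
}

#' Build an arboreal network realizing a cluster system
#'
#' Reconstructs an arboreal network whose cluster system equals `cs`, by
#' building the phylogenetic tree of each maximal cluster from its hierarchy
#' and then gluing the trees one at a time: the next tree sharing a cluster
#' with the network built so far is attached by subdividing the incoming arc
#' of the unique network vertex carrying the shared maximal cluster and
#' identifying it with the corresponding tree vertex, which turns the
#' subdivision vertex into a hybrid.  Trees are processed in lexicographic
#' order of their leaf sets, ties broken lexicographically, so the
#' construction is deterministic.
#'
#' Not every system satisfying P1-P3 is realizable (three maximal clusters
#' with pairwise equal non-empty intersections require more hybrids than an
#' arboreal network can carry); the builder verifies its output and fails
#' with an error when the system is unrealizable.
#'
#' @param cs an `fbnet_clusters` object containing all trivial clusters on
#'   its label set and satisfying [check_P123()].
#' @return An `fbnet_network` (arboreal, with one root per maximal cluster).
#' @export
build_arboreal_network <- function(cs) {
  stopifnot(inherits(cs, "fbnet_clusters"))
  labels <- attr(cs, "labels")
  keys <- vapply(cs, cluster_key, character(1))
  if (!all(labels %in% keys))
    stop("cluster system must contain all trivial clusters on X", call. = FALSE)
  rep <- check_P123(cs)
  if (!rep$ok)
    stop("cluster system violates P1-P3 (",
         paste(c("P1", "P2", "P3")[!c(rep$p1, rep$p2, rep$p3)], collapse = ", "),
         ")", call. = FALSE)

  cm <- rep$maximal
  cm <- cm[order(vapply(cm, cluster_key, character(1)))]
  m <- length(cm)

  tree_of <- function(i) {
    C <- cm[[i]]
    sub <- cs[vapply(cs, function(cc) all(cc %in% C), logical(1))]
    hierarchy_tree_arcs(canon_clusters(sub), prefix = paste0("t", i, ""))
  }

  if (m == 1L) {
    tr <- tree_of(1L)
    if (is.null(tr$arcs)) {   # single label
      return(network(NULL, vertices = labels, mode = "strict"))
    }
    return(network(tr$arcs, mode = "strict"))
  }

  done <- 1L
  t1 <- tree_of(1L)
  arcs <- t1$arcs
  net_cl <- function(arcs) {
    # vertex -> cluster for current partial network
    vs <- unique(c(arcs[, 1L], arcs[, 2L]))
    kids <- split(arcs[, 2L], factor(arcs[, 1L], levels = vs))
    cl <- vector("list", length(vs)); names(cl) <- vs
    rec <- function(v) {
      if (!is.null(cl[[v]])) return(cl[[v]])
      ch <- kids[[v]]
      val <- if (length(ch) == 0L) v else
        sort(unique(unlist(lapply(ch, rec), use.names = FALSE)))
      cl[[v]] <<- val
      val
    }
    for (v in vs) rec(v)
    cl
  }

  remaining <- setdiff(seq_len(m), done)
  hyb_i <- 0L
  while (length(remaining) > 0L) {
    cl_net <- net_cl(arcs)
    net_keys <- vapply(cl_net, cluster_key, character(1))
    # next tree (lexicographically least) sharing a cluster with the network
    pick <- NULL
    for (i in remaining) {
      shared <- intersect(names(tree_of(i)$ids), net_keys)
      if (length(shared) > 0L) { pick <- i; break }
    }
    if (is.null(pick))
      stop("cluster system is not realizable: intersection graph fell apart",
           call. = FALSE)
    tr <- tree_of(pick)
    shared_keys <- intersect(names(tr$ids), net_keys)
    # the glue cluster is the maximal shared cluster; it must be unique
    shared_cl <- lapply(strsplit(shared_keys, ",", fixed = TRUE), identity)
    sizes <- vapply(shared_cl, length, integer(1))
    top <- shared_cl[sizes == max(sizes)]
    if (length(top) != 1L)
      stop("cluster system is not realizable: no unique gluing cluster",
           call. = FALSE)
    glue_key <- cluster_key(sort(top[[1L]]))

    # the glue point in the current network is the unique tree vertex with
    # that cluster (a hybrid and its child carry the same cluster; the proof's
    # u_i is the tree vertex, and it cannot be a root)
    cand <- names(net_keys)[net_keys == glue_key]
    indeg <- table(factor(arcs[, 2L], levels = unique(c(arcs))))
    cand <- cand[indeg[cand] == 1L]
    if (length(cand) == 0L)
      stop("cluster system is not realizable: gluing point is a root",
           call. = FALSE)
    u <- cand[[1L]]
    pars <- stats::setNames(arcs[, 1L], arcs[, 2L])

    hyb_i <- hyb_i + 1L
    w <- paste0("glue", hyb_i)
    # subdivide incoming arc of u with w
    pu <- pars[[u]]
    arcs <- arcs[!(arcs[, 1L] == pu & arcs[, 2L] == u), , drop = FALSE]
    arcs <- rbind(arcs, c(pu, w), c(w, u))
    # attach the new tree: drop everything below its glue vertex, identify
    v_id <- tr$ids[[glue_key]]
    tarcs <- tr$arcs
    below <- v_id
    repeat {
      nxt <- tarcs[tarcs[, 1L] %in% below, 2L]
      if (all(nxt %in% below)) break
      below <- unique(c(below, nxt))
    }
    keep <- !(tarcs[, 1L] %in% below)
    tarcs <- tarcs[keep, , drop = FALSE]
    tarcs[tarcs == v_id] <- w
    arcs <- rbind(arcs, tarcs)

    remaining <- setdiff(remaining, pick)
    done <- c(done, pick)
  }

  net <- network(arcs, mode = "strict")
  got <- cluster_system(net)$clusters
  if (!identical(clusters_key(got), clusters_key(cs)))
    stop("cluster system is not realizable by an arboreal network",
         call. = FALSE)
  net
}

#' Bad arcs of a network
#'
#' An arc is bad when both of its end vertices are hybrid vertices.  Bad arcs
#' are the obstruction to an arboreal network being determined by its cluster
#' system.
#'
#' @param net an `fbnet_network`.
#' @return Two-column character matrix of bad arcs (possibly zero rows).
#' @export
bad_arcs <- function(net) {
  hyb <- hybrids(net)
  sel <- net$arcs[, 1L] %in% hyb & net$arcs[, 2L] %in% hyb
  net$arcs[sel, , drop = FALSE]
}

#' Collapse all bad arcs of a network
#'
#' Contracts every arc whose endpoints are both hybrids, merging the two
#' endpoints.  The result (often written Comp(N)) is generally not
#' semi-binary, so it is returned as a relaxed-mode graph and is not
#' re-validated against strict rules.
#'
#' @param net an `fbnet_network`.
#' @return An `fbnet_network` in relaxed mode.
#' @export
collapse_bad_arcs <- function(net) {
  ba <- bad_arcs(net)
  if (nrow(ba) == 0L) {
    if (net$mode == "relaxed") return(net)
    return(new_network(net$vertices, net$arcs, "relaxed"))
  }
  # union-find over chains of bad arcs; representative = lexicographic min
  rep_of <- stats::setNames(net$vertices, net$vertices)
  find <- function(v) {
    while (rep_of[[v]] != v) v <- rep_of[[v]]
    v
  }
  for (k in seq_len(nrow(ba))) {
    a <- find(ba[k, 1L]); b <- find(ba[k, 2L])
    if (a != b) {
      lo <- min(a, b); hi <- max(a, b)
      rep_of[[hi]] <- lo
    }
  }
  map <- vapply(net$vertices, find, character(1))
  A <- cbind(unname(map[net$arcs[, 1L]]), unname(map[net$arcs[, 2L]]))
  A <- A[A[, 1L] != A[, 2L], , drop = FALSE]
  A <- unique(A)
  new_network(unique(unname(map)), normalize_arcs(A), "relaxed")
}

#' Is an arboreal network uniquely determined by its clusters?
#'
#' An arboreal network is determined up to label-preserving equivalence by
#' its cluster system exactly when it has no bad arcs.
#'
#' @param net an arboreal `fbnet_network`.
#' @return `TRUE` or `FALSE`.
#' @export
is_uniquely_determined <- function(net) {
  if (!is_arboreal(net))
    stop("network is not arboreal", call. = FALSE)
  nrow(bad_arcs(net)) == 0L
}

#' Compare cluster systems and collapse-equivalence of two arboreal networks
#'
#' Two arboreal networks induce the same cluster system exactly when they are
#' equivalent after collapsing all bad arcs; this diagnostic computes both
#' sides independently.
#'
#' @param n1,n2 arboreal `fbnet_network` objects.
#' @return A list with logical fields `clusters_equal` and
#'   `collapse_equivalent`.
#' @export
same_clusters_iff_collapse_equivalent <- function(n1, n2) {
  if (!is_arboreal(n1) || !is_arboreal(n2))
    stop("both networks must be arboreal", call. = FALSE)
  ce <- identical(clusters_key(cluster_system(n1)$clusters),
                  clusters_key(cluster_system(n2)$clusters)) &&
    identical(leaves(n1), leaves(n2))
  eq <- are_equivalent(collapse_bad_arcs(n1), collapse_bad_arcs(n2))
  list(clusters_equal = ce, collapse_equivalent = eq)
}

is_arboreal <- function(net) {
  nrow(net$arcs) == length(net$vertices) - 1L
}
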