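#' Spanning forests of a network
#'
#' A spanning forest keeps all vertices of the host network and a subset of
#' its arcs in which every vertex has indegree at most one.  Because the host
#' is acyclic, every connected component is then a rooted tree (possibly a
#' single vertex).
#'
#' @param net the host `fbnet_network`.
#' @param kept_arcs two-column character matrix of arcs to keep; must be a
#'   subset of the host's arcs.
#' @return An object of class `fbnet_spanning_forest` with fields `vertices`,
#'   `arcs`, and `host_leaves`.
#' @export
spanning_forest <- function(net, kept_arcs) {
  A <- normalize_arcs(kept_arcs)
  if (nrow(A) > 0L) {
    key <- paste(A[, 1L], A[, 2L], sep = "\r")
    host <- paste(net$arcs[, 1L], net$arcs[, 2L], sep = "\r")
    if (!all(key %in% host))
      stop("kept_arcs must be a subset of the network's arcs", call. = FALSE)
    if (anyDuplicated(A[, 2L]))
      stop("spanning forest has a vertex of indegree > 1", call. = FALSE)
  }
  structure(list(vertices = net$vertices, arcs = A, host_leaves = leaves(net)),
            class = "fbnet_spanning_forest")
}

forest_components <- function(sf) {
  idx <- stats::setNames(seq_along(sf$vertices), sf$vertices)
  parent <- seq_along(sf$vertices)
  findp <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(sf$arcs) > 0L) {
    for (k in seq_len(nrow(sf$arcs))) {
      a <- findp(idx[[sf$arcs[k, 1L]]])
      b <- findp(idx[[sf$arcs[k, 2L]]])
      if (a != b) parent[a] <- b
    }
  }
  stats::setNames(vapply(seq_along(sf$vertices), findp, integer(1)),
                  sf$vertices)
}

#' Suppress a spanning forest to a phylogenetic forest
#'
#' Reduces each tree of a spanning forest to the phylogenetic tree on its
#' leaves by (conceptually) suppressing subdivision vertices and outdegree-one
#' roots.  The result is returned canonically: each tree as its hierarchy, the
#' set of distinct leaf clusters of the component.  A component that is a bare
#' directed path collapses to a single labelled vertex.
#'
#' @param sf an `fbnet_spanning_forest`.
#' @return An [phylo_forest()] object on the host's leaf set.
#' @export
suppress <- function(sf) {
  stopifnot(inherits(sf, "fbnet_spanning_forest"))
  out0 <- !(sf$vertices %in% sf$arcs[, 1L])
  forest_leaves <- sf$vertices[out0]
  extra <- setdiff(forest_leaves, sf$host_leaves)
  if (length(extra) > 0L)
    stop("not a subdivision forest: vertex ", extra[[1L]],
         " is a leaf of the forest but not of the network", call. = FALSE)

  comp <- forest_components(sf)
  kids <- split(sf$arcs[, 2L], factor(sf$arcs[, 1L], levels = sf$vertices))
  # leaf clusters bottom-up; forest arcs form a DAG so process by depth
  cl <- vector("list", length(sf$vertices))
  names(cl) <- sf$vertices
  order_by_height <- sf$vertices[order(vapply(sf$vertices, function(v) {
    d <- 0L
    stack <- list(list(v = v, d = 0L))
    maxd <- 0L
    while (length(stack) > 0L) {
      it <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      ch <- kids[[it$v]]
      if (length(ch) == 0L) maxd <- max(maxd, it$d)
      for (c in ch) stack[[length(stack) + 1L]] <- list(v = c, d = it$d + 1L)
    }
    maxd
  }, integer(1)))]
  for (v in order_by_height) {
    ch <- kids[[v]]
    cl[[v]] <- if (length(ch) == 0L) v else
      sort(unique(unlist(cl[ch], use.names = FALSE)))
  }

  trees <- lapply(split(sf$vertices, comp), function(vs) {
    unique(lapply(unname(cl[vs]), identity))
  })
  phylo_forest(unname(trees), labels = sort(sf$host_leaves),
               allow_single = TRUE)
}

canon_clusters <- function(clusters) {
  clusters <- lapply(clusters, function(c) sort(unique(as.character(c))))
  keys <- vapply(clusters, paste, character(1), collapse = "\r")
  ord <- order(keys)
  clusters <- clusters[ord]
  clusters[!duplicated(keys[ord])]
}

cluster_key <- function(cluster) paste(cluster, collapse = ",")

#' Phylogenetic forests in canonical hierarchy form
#'
#' A phylogenetic forest on X is a set of phylogenetic trees with pairwise
#' disjoint leaf sets whose union is X.  Each tree is stored canonically as
#' its hierarchy: the set of leaf clusters of its vertices.  Since a rooted
#' phylogenetic tree is determined up to equivalence by its hierarchy, this
#' representation makes forest equality a set comparison.
#'
#' @param trees a list of hierarchies; each hierarchy is a list of character
#'   vectors (clusters).  Trivial clusters and the full leaf set of the tree
#'   are added automatically.
#' @param labels the ground set X; defaults to the union of the tree leaves.
#' @param allow_single allow a forest with a single tree (used for base-tree
#'   interoperability); a forest proper has at least two trees.
#' @return An object of class `fbnet_forest`: a list of canonical
#'   hierarchies sorted by leaf set, with attribute `labels`.
#' @export
phylo_forest <- function(trees, labels = NULL, allow_single = FALSE) {
  trees <- lapply(trees, function(tr) {
    tr <- canon_clusters(tr)
    lf <- sort(unique(unlist(tr, use.names = FALSE)))
    tr <- canon_clusters(c(tr, as.list(lf), list(lf)))
    tr
  })
  leafsets <- lapply(trees, function(tr) sort(unique(unlist(tr))))
  all_leaves <- sort(unlist(leafsets, use.names = FALSE))
  if (anyDuplicated(all_leaves))
    stop("tree leaf sets are not pairwise disjoint", call. = FALSE)
  if (is.null(labels)) labels <- all_leaves
  if (!identical(sort(labels), all_leaves))
    stop("tree leaf sets do not partition the label set", call. = FALSE)
  if (!allow_single && length(trees) < 2L)
    stop("a phylogenetic forest has at least two trees", call. = FALSE)
  for (tr in trees) {
    if (!is_hierarchy_clusters(tr))
      stop("a tree's cluster set is not a hierarchy", call. = FALSE)
  }
  ord <- order(vapply(leafsets, paste, character(1), collapse = ","))
  structure(trees[ord], labels = sort(labels), class = "fbnet_forest")
}

# nested-or-disjoint check on an already canonical cluster list
is_hierarchy_clusters <- function(clusters) {
  n <- length(clusters)
  if (n <= 1L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      int <- intersect(clusters[[i]], clusters[[j]])
      if (length(int) == 0L) next
      if (length(int) == length(clusters[[i]]) ||
          length(int) == length(clusters[[j]])) next
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical key of a phylogenetic forest
#'
#' Two forests are identical iff their keys are equal.
#' @param forest an `fbnet_forest`.
#' @return A single string.
#' @export
forest_key <- function(forest) {
  paste(vapply(forest, function(tr) {
    paste(vapply(tr, cluster_key, character(1)), collapse = "|")
  }, character(1)), collapse = " ;; ")
}

#' @export
print.fbnet_forest <- function(x, ...) {
  cat(sprintf("<fbnet_forest: %d tree%s on {%s}>\n", length(x),
              if (length(x) == 1L) "" else "s",
              paste(attr(x, "labels"), collapse = ",")))
  for (tr in x) {
    cat(" ", paste(vapply(tr, function(c) paste0("{", cluster_key(c), "}"),
                          character(1)), collapse = " "), "\n")
  }
  invisible(x)
}

#' The trivial forest on a label set
#'
#' Every component is a single labelled vertex.
#' @param labels character vector of at least two labels.
#' @return An `fbnet_forest`.
#' @export
trivial_forest <- function(labels) {
  stopifnot(length(labels) >= 2L)
  phylo_forest(lapply(sort(labels), function(x) list(x)), labels = labels)
}
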