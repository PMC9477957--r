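#' Multiply-rooted phylogenetic networks
#'
#' A network is a semi-binary, connected, acyclic digraph whose leaves
#' (outdegree-0 vertices) carry the labels of the taxon set X.  Roots are
#' indegree-0 vertices and must have outdegree at least two (unless the whole
#' graph is a single vertex); hybrid vertices are internal vertices of
#' indegree two or more and model reticulate events.  In `strict` mode every
#' hybrid must have indegree exactly two and outdegree one and no internal
#' non-root tree vertex may have outdegree one; `relaxed` mode lifts the
#' indegree bound on hybrids so that non-semi-binary graphs can be analysed
#' diagnostically.
#'
#' @param arcs a two-column character matrix or data frame of arcs
#'   (tail, head), or `NULL` for a single-vertex network.
#' @param vertices optional character vector of vertex identifiers; defaults
#'   to the identifiers appearing in `arcs`.  Required for isolated vertices.
#' @param mode `"strict"` (default) or `"relaxed"`.
#' @return An object of class `fbnet_network` with fields `vertices`, `arcs`,
#'   `mode`, and precomputed child/parent adjacency lists.
#' @seealso [validate_network()] for a non-throwing validator,
#'   [vertex_roles()], [cluster_system()].
#' @examples
#' cherry <- network(rbind(c("r", "1"), c("r", "2")))
#' leaves(cherry)
#' @export
network <- function(arcs = NULL, vertices = NULL, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  rep <- validate_network(arcs, vertices = vertices, mode = mode)
  if (!rep$ok) {
    msgs <- vapply(rep$issues, function(i) paste0("[", i$rule, "] ", i$message),
                   character(1))
    stop("invalid network:\n  ", paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  rep$network
}

normalize_arcs <- function(arcs) {
  if (is.null(arcs) || (is.matrix(arcs) && nrow(arcs) == 0L)) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("tail", "head"))))
  }
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
  if (!is.matrix(arcs) || ncol(arcs) != 2L)
    stop("arcs must be a two-column matrix (tail, head)", call. = FALSE)
  storage.mode(arcs) <- "character"
  arcs <- arcs[order(arcs[, 1L], arcs[, 2L]), , drop = FALSE]
  dimnames(arcs) <- list(NULL, c("tail", "head"))
  arcs
}

# adjacency lists keyed by vertex id; every vertex has an entry
adjacency <- function(vertices, arcs) {
  kids <- split(arcs[, 2L], factor(arcs[, 1L], levels = vertices))
  pars <- split(arcs[, 1L], factor(arcs[, 2L], levels = vertices))
  list(kids = lapply(kids, sort), pars = lapply(pars, sort))
}

new_network <- function(vertices, arcs, mode) {
  adj <- adjacency(vertices, arcs)
  structure(
    list(vertices = sort(vertices), arcs = arcs, mode = mode,
         kids = adj$kids, pars = adj$pars),
    class = "fbnet_network"
  )
}

#' Validate a raw vertex/arc collection as a network
#'
#' Checks all structural rules for a multiply-rooted network and reports every
#' violation rather than stopping at the first.  Each issue names the rule and
#' the offending vertex or arc; rule identifiers are `parallel_arc`, `loop`,
#' `cyclic`, `disconnected`, `leaf_indegree`, `hybrid_degree` (strict only),
#' `root_outdegree`, `unary_tree_vertex` (strict only), and `empty`.
#'
#' @inheritParams network
#' @return A list with elements `ok` (logical), `issues` (list of rule
#'   violations), and — when `ok` — `network`, the validated object.
#' @export
validate_network <- function(arcs = NULL, vertices = NULL,
                             mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  issues <- list()
  note <- function(rule, message) {
    issues[[length(issues) + 1L]] <<- list(rule = rule, message = message)
  }

  A <- normalize_arcs(arcs)
  verts <- sort(unique(c(vertices, A[, 1L], A[, 2L])))
  if (length(verts) == 0L) {
    note("empty", "graph has no vertices")
    return(list(ok = FALSE, issues = issues))
  }

  if (anyDuplicated(paste(A[, 1L], A[, 2L], sep = "\r"))) {
    dup <- A[duplicated(paste(A[, 1L], A[, 2L], sep = "\r")), , drop = FALSE]
    note("parallel_arc", paste0("duplicate arc (", dup[1L, 1L], ",", dup[1L, 2L], ")"))
    A <- unique(A)
  }
  loops <- A[, 1L] == A[, 2L]
  if (any(loops)) {
    note("loop", paste0("loop at vertex ", A[which(loops)[1L], 1L]))
    A <- A[!loops, , drop = FALSE]
  }

  indeg <- table(factor(A[, 2L], levels = verts))
  outdeg <- table(factor(A[, 1L], levels = verts))

  g <- igraph::graph_from_data_frame(
    as.data.frame(A, stringsAsFactors = FALSE), directed = TRUE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  if (!igraph::is_dag(g)) note("cyclic", "graph contains a directed cycle")
  if (igraph::count_components(g, mode = "weak") > 1L)
    note("disconnected", "underlying undirected graph is not connected")

  lf <- verts[outdeg == 0L]
  bad_leaf <- lf[indeg[lf] > 1L]
  for (v in bad_leaf)
    note("leaf_indegree", paste0("leaf ", v, " has indegree ", indeg[[v]]))

  rts <- verts[indeg == 0L]
  if (length(verts) > 1L) {
    for (v in rts[outdeg[rts] < 2L])
      note("root_outdegree", paste0("root ", v, " has outdegree ", outdeg[[v]]))
  }

  hyb <- verts[indeg >= 2L & outdeg >= 1L]
  if (mode == "strict") {
    for (v in hyb) {
      if (indeg[[v]] != 2L || outdeg[[v]] != 1L)
        note("hybrid_degree",
             paste0("hybrid ", v, " has indegree ", indeg[[v]],
                    " and outdegree ", outdeg[[v]], " (semi-binary requires 2/1)"))
    }
    unary <- verts[indeg == 1L & outdeg == 1L]
    for (v in unary)
      note("unary_tree_vertex",
           paste0("internal tree vertex ", v, " has outdegree 1"))
  }

  if (length(issues) > 0L) return(list(ok = FALSE, issues = issues))
  list(ok = TRUE, issues = list(), network = new_network(verts, A, mode))
}

#' @export
print.fbnet_network <- function(x, ...) {
  rt <- roots(x)
  cat(sprintf("<fbnet_network: %d vertices, %d arcs, %d root%s, %d hybrid%s, %s mode>\n",
              length(x$vertices), nrow(x$arcs),
              length(rt), if (length(rt) == 1L) "" else "s",
              length(hybrids(x)), if (length(hybrids(x)) == 1L) "" else "s",
              x$mode))
  cat("  leaves:", paste(leaves(x), collapse = " "), "\n")
  invisible(x)
}

indegree <- function(net) {
  tab <- table(factor(net$arcs[, 2L], levels = net$vertices))
  stats::setNames(as.integer(tab), names(tab))
}

outdegree <- function(net) {
  tab <- table(factor(net$arcs[, 1L], levels = net$vertices))
  stats::setNames(as.integer(tab), names(tab))
}

#' Leaf, root and hybrid sets of a network
#'
#' Leaves are the outdegree-0 vertices and their identifiers are the taxon
#' labels X.  Roots have indegree 0, hybrids indegree at least 2.
#'
#' @param net an `fbnet_network`.
#' @return Sorted character vector of vertex identifiers.
#' @export
leaves <- function(net) net$vertices[outdegree(net) == 0L]

#' @rdname leaves
#' @export
roots <- function(net) net$vertices[indegree(net) == 0L]

#' @rdname leaves
#' @export
hybrids <- function(net) {
  net$vertices[indegree(net) >= 2L]
}

#' Vertex roles, omnian status, and first reticulate ancestors
#'
#' Computes for every vertex its role (`root`, `leaf`, `tree` or `hybrid`),
#' whether it is an omnian (a vertex with at least one child, all of whose
#' children are hybrids), and its gamma vertex: the first ancestor that is a
#' root or hybrid, reached by walking up through (unique) tree-vertex parents;
#' roots and hybrids are their own gamma.  A single isolated vertex is
#' classified as a root.
#'
#' @param net an `fbnet_network`.
#' @return A data frame with columns `vertex`, `role`, `omnian`, `gamma`, and
#'   attribute `rh_set` (the union of roots and hybrids).
#' @export
vertex_roles <- function(net) {
  ind <- indegree(net)
  out <- outdegree(net)
  v <- net$vertices
  role <- ifelse(ind == 0L, "root",
          ifelse(out == 0L, "leaf",
          ifelse(ind == 1L, "tree", "hybrid")))
  names(role) <- v

  hyb <- v[ind >= 2L]
  omn <- vapply(v, function(u) {
    ch <- net$kids[[u]]
    length(ch) > 0L && all(ch %in% hyb)
  }, logical(1))

  rh <- v[ind == 0L | ind >= 2L]
  gam <- character(length(v))
  names(gam) <- v
  for (u in v) {
    w <- u
    while (!(w %in% rh)) w <- net$pars[[w]][1L]
    gam[[u]] <- w
  }

  res <- data.frame(vertex = v, role = unname(role), omnian = unname(omn),
                    gamma = unname(gam), stringsAsFactors = FALSE)
  attr(res, "rh_set") <- rh
  res
}

#' Leaf clusters induced by the vertices of a network
#'
#' The cluster of a vertex u is the set of leaf labels below u (u itself when
#' u is a leaf).  The cluster system of the network is the set of distinct
#' clusters over all vertices.
#'
#' @param net an `fbnet_network`.
#' @return A list with `vertex_clusters` (named list: vertex -> sorted label
#'   vector) and `clusters`, a [cluster_system_on()] object holding the
#'   distinct clusters on the leaf set.
#' @export
cluster_system <- function(net) {
  lf <- leaves(net)
  ord <- topo_order(net)
  cl <- vector("list", length(net$vertices))
  names(cl) <- net$vertices
  for (u in rev(ord)) {
    ch <- net$kids[[u]]
    if (length(ch) == 0L) {
      cl[[u]] <- u
    } else {
      cl[[u]] <- sort(unique(unlist(cl[ch], use.names = FALSE)))
    }
  }
  list(vertex_clusters = cl,
       clusters = cluster_system_on(lf, unname(cl)))
}

topo_order <- function(net) {
  if (nrow(net$arcs) == 0L) return(net$vertices)
  g <- igraph::graph_from_data_frame(
    as.data.frame(net$arcs, stringsAsFactors = FALSE), directed = TRUE,
    vertices = data.frame(name = net$vertices, stringsAsFactors = FALSE))
  names(igraph::topo_sort(g, mode = "out"))
}

# vertices reachable from `from` (included) following arcs forward,
# optionally restricted to an induced vertex subset
reachable_from <- function(net, from, within = NULL) {
  seen <- character(0)
  stack <- intersect(from, if (is.null(within)) net$vertices else within)
  while (length(stack) > 0L) {
    u <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (u %in% seen) next
    seen <- c(seen, u)
    ch <- net$kids[[u]]
    if (!is.null(within)) ch <- intersect(ch, within)
    stack <- c(stack, setdiff(ch, seen))
  }
  seen
}

#' Label-preserving equivalence of networks
#'
#' Two networks on the same label set X are equivalent when some digraph
#' isomorphism between them fixes every leaf label.  The test colours each
#' leaf by its label (shared across both graphs), gives all internal vertices
#' a common colour, and runs VF2 on the directed graphs.
#'
#' @param n1,n2 `fbnet_network` objects (or raw graphs from
#'   [collapse_bad_arcs()]).
#' @return `TRUE` or `FALSE`; `FALSE` when the label sets differ.
#' @export
are_equivalent <- function(n1, n2) {
  x1 <- leaves(n1); x2 <- leaves(n2)
  if (!identical(x1, x2)) return(FALSE)
  if (length(n1$vertices) != length(n2$vertices)) return(FALSE)
  if (nrow(n1$arcs) != nrow(n2$arcs)) return(FALSE)
  colour <- function(net) {
    ifelse(net$vertices %in% x1, match(net$vertices, x1), 0L)
  }
  mk <- function(net) igraph::graph_from_data_frame(
    as.data.frame(net$arcs, stringsAsFactors = FALSE), directed = TRUE,
    vertices = data.frame(name = net$vertices, stringsAsFactors = FALSE))
  igraph::isomorphic(mk(n1), mk(n2), method = "vf2",
                     vertex.color1 = colour(n1), vertex.color2 = colour(n2))
}
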