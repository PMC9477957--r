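#' Class membership of a network
#'
#' Computes the standard class predicates directly from their definitions:
#' * `is_tree`: no hybrid vertices (a connected network without reticulations
#'   has a single root).
#' * `is_semi_binary`: every hybrid has indegree 2 and outdegree 1.
#' * `is_binary`: semi-binary and every root and internal tree vertex has
#'   outdegree 2.
#' * `is_arboreal`: the underlying undirected graph is a tree.
#' * `is_tree_child`: every internal vertex has at least one child of
#'   indegree 1.
#' * `is_tree_sibling`: every hybrid shares a parent with some vertex of
#'   indegree 1.
#' * `is_reticulation_visible`: for every hybrid v some leaf x is such that
#'   every root-to-x path passes through v (checked by deleting v).
#' * `is_phylogenetic`: single-rooted.
#'
#' @param net an `fbnet_network` (strict or relaxed).
#' @return A named logical vector with the above flags.
#' @export
classify <- function(net) {
  ind <- indegree(net)
  out <- outdegree(net)
  v <- net$vertices
  lf <- leaves(net)
  hyb <- hybrids(net)
  rts <- roots(net)
  internal <- setdiff(v, lf)

  semi_binary <- all(ind[hyb] == 2L & out[hyb] == 1L)
  binary <- semi_binary && all(out[setdiff(internal, hyb)] == 2L)

  tree_child <- all(vapply(internal, function(u)
    any(ind[net$kids[[u]]] == 1L), logical(1)))

  tree_sibling <- all(vapply(hyb, function(h) {
    sib <- setdiff(unique(unlist(lapply(net$pars[[h]], function(p)
      net$kids[[p]]))), h)
    any(ind[sib] == 1L)
  }, logical(1)))

  rv <- all(vapply(hyb, function(h) {
    kept <- setdiff(v, h)
    reach <- reachable_from(net, setdiff(rts, h), within = kept)
    length(setdiff(lf, reach)) > 0L
  }, logical(1)))

  c(is_tree = length(hyb) == 0L,
    is_binary = binary,
    is_semi_binary = semi_binary,
    is_arboreal = is_arboreal(net),
    is_tree_child = tree_child,
    is_tree_sibling = tree_sibling,
    is_reticulation_visible = rv,
    is_phylogenetic = length(rts) == 1L)
}

#' Tree-based test for binary phylogenetic networks
#'
#' A binary single-rooted network is tree-based exactly when the bipartite
#' graph linking its omnians U to its hybrids H (one edge per network arc
#' from an omnian to a hybrid) has a matching saturating U.  The matching is
#' returned as a certificate.
#'
#' @param net a binary, single-rooted `fbnet_network`; anything else is an
#'   error, not `FALSE`.
#' @return A list with `tree_based` (logical) and `matching` (two-column
#'   matrix omnian -> hybrid, the saturating matching when `tree_based`).
#' @export
is_tree_based <- function(net) {
  cl <- classify(net)
  if (!cl[["is_phylogenetic"]])
    stop("tree-based test requires a single-rooted network", call. = FALSE)
  if (!cl[["is_binary"]])
    stop("tree-based test requires a binary network", call. = FALSE)

  vr <- vertex_roles(net)
  omn <- sort(vr$vertex[vr$omnian])
  hyb <- sort(hybrids(net))
  if (length(omn) == 0L)
    return(list(tree_based = TRUE,
                matching = matrix(character(0), ncol = 2L)))

  edges <- NULL
  for (u in omn) {
    for (h in intersect(net$kids[[u]], hyb)) {
      edges <- rbind(edges, c(paste0("U\r", u), paste0("H\r", h)))
    }
  }
  vnames <- c(paste0("U\r", omn), paste0("H\r", hyb))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE), directed = FALSE,
    vertices = data.frame(name = vnames, stringsAsFactors = FALSE))
  types <- igraph::V(g)$name %in% paste0("H\r", hyb)
  mm <- igraph::max_bipartite_match(g, types = types)
  saturated <- mm$matching_size == length(omn)
  matching <- matrix(character(0), ncol = 2L)
  if (saturated) {
    mt <- mm$matching[paste0("U\r", omn)]
    matching <- cbind(omn, sub("^H\r", "", unname(mt)))
  }
  list(tree_based = saturated, matching = matching)
}
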