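new_gamma_graph <- function(vertices, edges) {
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2L)
  if (nrow(edges) > 0L) {
    edges <- t(apply(edges, 1L, sort))        # unordered pairs
    edges <- unique(edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE])
  }
  structure(list(vertices = sort(vertices), edges = edges),
            class = "fbnet_gamma")
}

gamma_key <- function(g) paste(g$edges[, 1L], g$edges[, 2L], collapse = "|")

#' @export
print.fbnet_gamma <- function(x, ...) {
  cat(sprintf("<fbnet_gamma: %d vertices, %d edge%s>\n", length(x$vertices),
              nrow(x$edges), if (nrow(x$edges) == 1L) "" else "s"))
  if (nrow(x$edges) > 0L)
    cat(paste0("  {", x$edges[, 1L], ",", x$edges[, 2L], "}", collapse = "\n"),
        "\n")
  invisible(x)
}

#' The gamma graph of a network
#'
#' An undirected graph (loops permitted) on the roots-and-hybrids set RH(N):
#' every hybrid h with parents u' and v' contributes the edge between the
#' first reticulate ancestors of its parents, gamma(u') and gamma(v').  A
#' relaxed network with hybrids of indegree above two contributes one edge
#' per unordered parent pair.
#'
#' @param net an `fbnet_network`.
#' @return An `fbnet_gamma` object.
#' @export
gamma_graph <- function(net) {
  vr <- vertex_roles(net)
  gam <- stats::setNames(vr$gamma, vr$vertex)
  rh <- attr(vr, "rh_set")
  edges <- NULL
  for (h in hybrids(net)) {
    p <- net$pars[[h]]
    if (length(p) == 2L) {
      edges <- rbind(edges, c(gam[[p[1L]]], gam[[p[2L]]]))
    } else {
      for (i in seq_len(length(p) - 1L)) {
        for (j in seq(i + 1L, length(p))) {
          edges <- rbind(edges, c(gam[[p[i]]], gam[[p[j]]]))
        }
      }
    }
  }
  new_gamma_graph(rh, edges)
}

#' Minimal omni-extensions of the gamma graph
#'
#' An omni-extension adds, for every omnian v, an edge between some hybrid
#' child h of v and gamma(u), where u is the other parent of h.  This
#' enumerates one choice of hybrid child per omnian, deduplicates the
#' resulting graphs, and keeps only the inclusion-minimal ones (an extension
#' containing another is redundant: colorings only become harder on
#' supergraphs).  A network without omnians yields its gamma graph alone.
#'
#' @param net a strict `fbnet_network`.
#' @return A list of `fbnet_gamma` objects.
#' @export
minimal_omni_extensions <- function(net) {
  g0 <- gamma_graph(net)
  vr <- vertex_roles(net)
  gam <- stats::setNames(vr$gamma, vr$vertex)
  omn <- sort(vr$vertex[vr$omnian])
  if (length(omn) == 0L) return(list(g0))

  per_omnian <- lapply(omn, function(v) {
    lapply(net$kids[[v]], function(h) {
      u <- setdiff(net$pars[[h]], v)
      # both parents may coincide only through distinct arcs, excluded by
      # the no-parallel-arc rule, so u is the unique other parent
      c(sort(c(gam[[u[1L]]], h)))
    })
  })

  combos <- list(integer(0))
  for (choices in per_omnian) {
    combos <- unlist(lapply(combos, function(pref) {
      lapply(seq_along(choices), function(i) c(pref, i))
    }), recursive = FALSE)
  }
  graphs <- lapply(combos, function(cmb) {
    add <- do.call(rbind, lapply(seq_along(cmb), function(k)
      per_omnian[[k]][[cmb[[k]]]]))
    new_gamma_graph(g0$vertices, rbind(g0$edges, add))
  })
  keys <- vapply(graphs, gamma_key, character(1))
  graphs <- graphs[!duplicated(keys)]
  # inclusion-minimal filter
  edge_sets <- lapply(graphs, function(g)
    paste(g$edges[, 1L], g$edges[, 2L], sep = "\r"))
  keep <- rep(TRUE, length(graphs))
  for (i in seq_along(graphs)) {
    for (j in seq_along(graphs)) {
      if (i != j && keep[i] && length(edge_sets[[j]]) < length(edge_sets[[i]]) &&
          all(edge_sets[[j]] %in% edge_sets[[i]]))
        keep[i] <- FALSE
    }
  }
  graphs[keep]
}

is_omni_extension <- function(net, ext) {
  g0 <- gamma_graph(net)
  if (!identical(g0$vertices, ext$vertices)) return(FALSE)
  base <- paste(g0$edges[, 1L], g0$edges[, 2L], sep = "\r")
  have <- paste(ext$edges[, 1L], ext$edges[, 2L], sep = "\r")
  if (!all(base %in% have)) return(FALSE)
  vr <- vertex_roles(net)
  gam <- stats::setNames(vr$gamma, vr$vertex)
  for (v in vr$vertex[vr$omnian]) {
    ok <- any(vapply(net$kids[[v]], function(h) {
      u <- setdiff(net$pars[[h]], v)
      key <- paste(sort(c(gam[[u[1L]]], h)), collapse = "\r")
      key %in% have
    }, logical(1)))
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Root-anchored colorings witnessing proper forest-basedness
#'
#' Searches for a proper vertex coloring of an omni-extension of the gamma
#' graph with one color per root such that (C1) the roots receive pairwise
#' distinct colors and (C2) every hybrid v shares its color s with a root u
#' only if some directed path from u to v passes exclusively through hybrids
#' colored s.  Such a coloring exists for some omni-extension exactly when
#' the network is proper forest-based; the color classes then induce the
#' trees of a proper base forest.  Color symmetry is broken by assigning
#' color i to the i-th root in sorted order.
#'
#' @param net a strict `fbnet_network` with m >= 2 roots.
#' @param extension an `fbnet_gamma` omni-extension of `gamma_graph(net)`.
#' @return A named character vector mapping RH(N) to colors `s1..sm`, or
#'   `NULL` when no such coloring exists on this extension.
#' @export
find_C1C2_coloring <- function(net, extension) {
  rts <- roots(net)
  m <- length(rts)
  if (m < 2L)
    stop("coloring characterization applies to networks with >= 2 roots",
         call. = FALSE)
  if (!is_omni_extension(net, extension))
    stop("extension is not an omni-extension of the network's gamma graph",
         call. = FALSE)
  if (nrow(extension$edges) > 0L &&
      any(extension$edges[, 1L] == extension$edges[, 2L]))
    return(NULL)                       # loops admit no proper coloring

  hyb <- sort(hybrids(net))
  colors <- paste0("s", seq_len(m))
  col <- stats::setNames(rep(NA_character_, length(extension$vertices)),
                         extension$vertices)
  col[rts] <- colors                  # C1 + symmetry breaking

  E <- extension$edges
  proper_at <- function(v, cl) {
    if (nrow(E) == 0L) return(TRUE)
    rows <- E[, 1L] == v | E[, 2L] == v
    if (!any(rows)) return(TRUE)
    oth <- ifelse(E[rows, 1L] == v, E[rows, 2L], E[rows, 1L])
    !any(!is.na(col[oth]) & col[oth] == cl)
  }
  # C2: hybrid v with color of root u needs a u -> v path through
  # same-colored hybrids only
  c2_ok <- function(colmap) {
    for (i in seq_len(m)) {
      u <- rts[[i]]; s <- colors[[i]]
      same <- names(colmap)[!is.na(colmap) & colmap == s]
      keep <- c(setdiff(net$vertices, hyb), intersect(hyb, same))
      reach <- reachable_from(net, u, within = keep)
      for (v in intersect(hyb, same)) {
        if (!(v %in% reach)) return(FALSE)
      }
    }
    TRUE
  }

  found <- NULL
  rec <- function(k) {
    if (!is.null(found)) return(invisible(NULL))
    if (k > length(hyb)) {
      if (c2_ok(col)) found <<- col
      return(invisible(NULL))
    }
    v <- hyb[[k]]
    for (cl in colors) {
      if (!proper_at(v, cl)) next
      col[[v]] <<- cl
      rec(k + 1L)
      col[[v]] <<- NA_character_
      if (!is.null(found)) return(invisible(NULL))
    }
    invisible(NULL)
  }
  # the pre-assigned root colors must themselves be proper
  for (r in rts) {
    cl <- col[[r]]; col[[r]] <- NA_character_
    ok <- proper_at(r, cl)
    col[[r]] <- cl
    if (!ok) return(NULL)
  }
  rec(1L)
  found
}

#' Proper forest-basedness via colorings
#'
#' Convenience wrapper: tries [find_C1C2_coloring()] on every minimal
#' omni-extension.
#'
#' @param net a strict `fbnet_network` with m >= 2 roots.
#' @return A list with `proper` (logical) and, when `TRUE`, `coloring` and
#'   `extension`.
#' @export
proper_via_coloring <- function(net) {
  for (ext in minimal_omni_extensions(net)) {
    colv <- find_C1C2_coloring(net, ext)
    if (!is.null(colv))
      return(list(proper = TRUE, coloring = colv, extension = ext))
  }
  list(proper = FALSE)
}

#' Bipartite omni-extension test for 2-rooted networks
#'
#' A 2-rooted network is proper forest-based exactly when its gamma graph has
#' a bipartite omni-extension; minimal extensions suffice since adding edges
#' can only destroy bipartiteness.
#'
#' @param net a strict 2-rooted `fbnet_network`.
#' @return `TRUE` or `FALSE`.
#' @export
has_bipartite_omni_extension <- function(net) {
  if (length(roots(net)) != 2L)
    stop("bipartite omni-extension test applies to 2-rooted networks",
         call. = FALSE)
  for (ext in minimal_omni_extensions(net)) {
    if (is_bipartite_graph(ext)) return(TRUE)
  }
  FALSE
}

# BFS 2-coloring; loops make a graph non-bipartite
is_bipartite_graph <- function(g) {
  if (nrow(g$edges) == 0L) return(TRUE)
  if (any(g$edges[, 1L] == g$edges[, 2L])) return(FALSE)
  col <- stats::setNames(rep(NA_integer_, length(g$vertices)), g$vertices)
  nbr <- lapply(g$vertices, function(v) {
    rows <- g$edges[, 1L] == v | g$edges[, 2L] == v
    setdiff(unique(c(g$edges[rows, 1L], g$edges[rows, 2L])), v)
  })
  names(nbr) <- g$vertices
  for (s in g$vertices) {
    if (!is.na(col[[s]])) next
    col[[s]] <- 0L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in nbr[[v]]) {
        if (is.na(col[[w]])) {
          col[[w]] <- 1L - col[[v]]
          queue <- c(queue, w)
        } else if (col[[w]] == col[[v]]) return(FALSE)
      }
    }
  }
  TRUE
}
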