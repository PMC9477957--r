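#' Read a network from a tab-separated edge list
#'
#' The format is one arc per line as `tail<TAB>head`, with `#` comment lines,
#' an optional `!mode strict|relaxed` directive and `!vertex id` lines for
#' isolated vertices.  The parsed graph is validated as a network.
#'
#' @param file path to an edge-list file.
#' @param text alternatively, the document as a character vector of lines.
#' @param mode overrides the mode directive when non-`NULL`.
#' @return An `fbnet_network`.
#' @export
read_network <- function(file = NULL, text = NULL, mode = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  doc_mode <- "strict"
  arcs <- NULL
  extra_vertices <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, "!mode")) {
      val <- trimws(sub("^!mode", "", ln))
      if (!val %in% c("strict", "relaxed"))
        stop("line ", i, ": unknown mode '", val, "'", call. = FALSE)
      doc_mode <- val
      next
    }
    if (startsWith(ln, "!vertex")) {
      extra_vertices <- c(extra_vertices, trimws(sub("^!vertex", "", ln)))
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || any(parts == ""))
      stop("line ", i, ": expected 'tail<TAB>head', got '", ln, "'",
           call. = FALSE)
    arcs <- rbind(arcs, parts)
  }
  if (is.null(mode)) mode <- doc_mode
  network(arcs, vertices = extra_vertices, mode = mode)
}

#' Write a network as a tab-separated edge list
#'
#' Deterministic writer: a mode directive, isolated-vertex directives, then
#' the arcs in lexicographic order.  `read_network(write_network(n))`
#' reproduces the arc set exactly.
#'
#' @param net an `fbnet_network`.
#' @param file optional path; when `NULL` the lines are returned invisibly.
#' @return The document lines, invisibly when written to a file.
#' @export
write_network <- function(net, file = NULL) {
  iso <- net$vertices[!(net$vertices %in% c(net$arcs))]
  lines <- c(paste("!mode", net$mode),
             if (length(iso) > 0L) paste("!vertex", sort(iso)),
             paste(net$arcs[, 1L], net$arcs[, 2L], sep = "\t"))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Read and write cluster systems as plain text
#'
#' One cluster per line, labels comma-separated; duplicate lines collapse on
#' read and empty lines are ignored.  The ground set defaults to the union of
#' all labels.
#'
#' @param file path; or use `text` for lines.
#' @param text character vector of lines.
#' @param labels optional explicit ground set.
#' @return An `fbnet_clusters` object.
#' @export
read_clusters <- function(file = NULL, text = NULL, labels = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  clusters <- lapply(strsplit(lines, ",", fixed = TRUE), trimws)
  if (length(clusters) == 0L)
    stop("cluster document contains no clusters", call. = FALSE)
  if (is.null(labels)) labels <- sort(unique(unlist(clusters)))
  cluster_system_on(labels, clusters)
}

#' @rdname read_clusters
#' @param cs an `fbnet_clusters` object to write.
#' @export
write_clusters <- function(cs, file = NULL) {
  lines <- vapply(cs, cluster_key, character(1))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Export a network as extended Newick
#'
#' Emits one semicolon-terminated statement per root.  Each hybrid vertex
#' carries a `#Hk` tag shared across statements; its subtree is printed at
#' the first occurrence and later occurrences refer to the tag alone.
#' Children are visited in lexicographic order, so the writer is
#' deterministic.  Only strict (semi-binary) networks are supported.
#'
#' @param net a strict `fbnet_network`.
#' @return Character vector with one statement per root.
#' @export
write_enewick <- function(net) {
  if (net$mode != "strict")
    stop("extended Newick export requires a strict network", call. = FALSE)
  hyb <- sort(hybrids(net))
  tag <- stats::setNames(paste0("#H", seq_along(hyb)), hyb)
  seen <- character(0)
  repr <- function(v) {
    if (v %in% hyb) {
      if (v %in% seen) return(tag[[v]])
      seen <<- c(seen, v)
      ch <- net$kids[[v]]
      return(paste0("(", paste(vapply(ch, repr, character(1)), collapse = ","),
                    ")", tag[[v]]))
    }
    ch <- net$kids[[v]]
    if (length(ch) == 0L) return(v)
    paste0("(", paste(vapply(ch, repr, character(1)), collapse = ","), ")")
  }
  unname(vapply(sort(roots(net)), function(r) paste0(repr(r), ";"),
                character(1)))
}

#' Parse the extended Newick dialect written by [write_enewick()]
#'
#' Reads one statement per root and glues hybrid vertices on their shared
#' `#Hk` tags.  This is a reader for the package's own export dialect, not a
#' general extended-Newick importer.
#'
#' @param statements character vector of semicolon-terminated statements.
#' @return An `fbnet_network` equivalent to the exported one.
#' @export
read_enewick <- function(statements) {
  counter <- new.env(); counter$i <- 0L
  arcs <- NULL
  single <- NULL
  parse_node <- function(s, pos) {
    # returns list(id, pos)
    if (substr(s, pos, pos) == "(") {
      pos <- pos + 1L
      children <- character(0)
      repeat {
        res <- parse_node(s, pos)
        children <- c(children, res$id)
        pos <- res$pos
        chr <- substr(s, pos, pos)
        if (chr == ",") { pos <- pos + 1L; next }
        if (chr == ")") { pos <- pos + 1L; break }
        stop("parse error at position ", pos, " in '", s, "'", call. = FALSE)
      }
      # optional #Hk tag
      m <- regmatches(substr(s, pos, nchar(s)),
                      regexpr("^#H[0-9]+", substr(s, pos, nchar(s))))
      if (length(m) == 1L && nzchar(m)) {
        id <- paste0("H", sub("^#H", "", m))
        pos <- pos + nchar(m)
      } else {
        counter$i <- counter$i + 1L
        id <- paste0(".i", counter$i)
      }
      for (c in children) arcs <<- rbind(arcs, c(id, c))
      return(list(id = id, pos = pos))
    }
    m <- regmatches(substr(s, pos, nchar(s)),
                    regexpr("^(#H[0-9]+|[^(),;#]+)", substr(s, pos, nchar(s))))
    if (length(m) == 0L || !nzchar(m))
      stop("parse error at position ", pos, " in '", s, "'", call. = FALSE)
    id <- if (startsWith(m, "#")) sub("^#", "", m) else m
    list(id = id, pos = pos + nchar(m))
  }
  for (stmt in statements) {
    s <- gsub("[[:space:]]", "", stmt)
    s <- sub(";$", "", s)
    if (s == "") next
    res <- parse_node(s, 1L)
    if (res$pos <= nchar(s))
      stop("trailing characters in statement '", stmt, "'", call. = FALSE)
    if (is.null(arcs)) single <- res$id
  }
  if (is.null(arcs)) return(network(NULL, vertices = single, mode = "strict"))
  # deduplicate arcs contributed by repeated tag references
  network(unique(arcs), mode = "strict")
}

#' Export a network in DOT format
#'
#' Writes a Graphviz digraph with leaves drawn as boxes.  When a contact-arc
#' certificate is supplied its contact arcs are styled dashed and the forest
#' arcs solid.
#'
#' @param net an `fbnet_network`.
#' @param certificate optional `fbnet_certificate` whose contact arcs must be
#'   arcs of `net`.
#' @param file optional output path.
#' @return The DOT lines (invisibly when written to a file).
#' @export
write_dot <- function(net, certificate = NULL, file = NULL) {
  dashed <- character(0)
  if (!is.null(certificate)) {
    I <- certificate$contact_arcs
    keyA <- paste(net$arcs[, 1L], net$arcs[, 2L], sep = "\r")
    dashed <- paste(I[, 1L], I[, 2L], sep = "\r")
    if (!all(dashed %in% keyA))
      stop("certificate contains arcs that are not in the network",
           call. = FALSE)
  }
  q <- function(x) paste0("\"", x, "\"")
  lines <- c("digraph network {", "  node [shape=circle];")
  for (v in leaves(net)) lines <- c(lines, paste0("  ", q(v), " [shape=box];"))
  if (nrow(net$arcs) > 0L) {
    for (k in seq_len(nrow(net$arcs))) {
      key <- paste(net$arcs[k, 1L], net$arcs[k, 2L], sep = "\r")
      style <- if (key %in% dashed) " [style=dashed]" else ""
      lines <- c(lines, paste0("  ", q(net$arcs[k, 1L]), " -> ",
                               q(net$arcs[k, 2L]), style, ";"))
    }
  }
  lines <- c(lines, "}")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
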