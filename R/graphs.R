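#' Acyclic directed mixed graphs
#'
#' A `mixed_graph` holds named nodes, directed edges, bidirected edges and a
#' set of latent-node flags.  It is the substrate for every graph-surgical
#' operation in the package: mutilation, d-separation, latent projection,
#' topological ordering and confounded components.  Two disciplines are
#' supported and kept apart: an *explicit-latent DAG* (latent nodes flagged,
#' no bidirected edges) and an *ADMG* (bidirected edges standing for latent
#' confounding between observed nodes, no latent flags).  [latent_project()]
#' converts the former into the latter.
#'
#' @param nodes character vector of node labels.
#' @param directed two-column matrix or data frame of directed edges
#'   (from, to), or `NULL`.
#' @param bidirected two-column matrix or data frame of bidirected edges
#'   (unordered pairs), or `NULL`.
#' @param latent character vector of node labels flagged as unobserved.
#'
#' @return An object of class `mixed_graph` with elements `nodes`, `di`
#'   (directed edge matrix), `bi` (bidirected edge matrix, rows sorted) and
#'   `latent`.
#' @examples
#' g <- mixed_graph(c("U", "X", "Z", "Y"),
#'                  directed = rbind(c("U", "X"), c("U", "Y"),
#'                                   c("X", "Z"), c("Z", "Y")),
#'                  latent = "U")
#' observed_nodes(g)
#' topological_sort(g)
#' @export
mixed_graph <- function(nodes, directed = NULL, bidirected = NULL,
                        latent = character()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node labels: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  di <- normalize_edges(directed, nodes, "directed")
  bi <- normalize_edges(bidirected, nodes, "bidirected")
  if (nrow(bi)) {
    bi <- t(apply(bi, 1, sort))
    bi <- bi[!duplicated(bi), , drop = FALSE]
  }
  latent <- as.character(latent)
  check_nodes_known(latent, nodes, "latent flag")
  if (nrow(di) && any(di[, 1] == di[, 2])) stop("self-loop in directed edges")
  if (nrow(bi) && any(bi[, 1] == bi[, 2])) stop("self-loop in bidirected edges")
  if (nrow(bi) && length(latent)) {
    stop("a graph is either an explicit-latent DAG or an ADMG: ",
         "latent flags and bidirected edges cannot be combined")
  }
  if (nrow(bi) && any(bi %in% latent)) {
    stop("bidirected edges must connect observed nodes only")
  }
  g <- structure(list(nodes = nodes, di = di, bi = bi, latent = latent),
                 class = "mixed_graph")
  ts <- try(topological_sort(g), silent = TRUE)
  if (inherits(ts, "try-error")) stop(attr(ts, "condition")$message)
  g
}

normalize_edges <- function(e, nodes, what) {
  if (is.null(e) || (is.matrix(e) && nrow(e) == 0) || length(e) == 0) {
    return(matrix(character(), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.data.frame(e)) e <- as.matrix(e)
  if (is.character(e) && is.null(dim(e))) e <- matrix(e, ncol = 2, byrow = TRUE)
  storage.mode(e) <- "character"
  colnames(e) <- c("from", "to")
  check_nodes_known(as.vector(e), nodes, paste(what, "edge"))
  e[!duplicated(e), , drop = FALSE]
}

check_nodes_known <- function(labels, nodes, context) {
  bad <- setdiff(labels, nodes)
  if (length(bad)) {
    stop("unknown node label", if (length(bad) > 1) "s", " in ", context,
         ": ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.mixed_graph <- function(x, ...) {
  kind <- if (nrow(x$bi)) "ADMG" else if (length(x$latent))
    "explicit-latent DAG" else "DAG"
  cat(sprintf("<mixed_graph: %s, %d nodes, %d directed, %d bidirected>\n",
              kind, length(x$nodes), nrow(x$di), nrow(x$bi)))
  if (length(x$latent)) cat("latent:", paste(x$latent, collapse = ", "), "\n")
  if (nrow(x$di))
    cat(paste(x$di[, 1], "->", x$di[, 2]), sep = "\n")
  if (nrow(x$bi))
    cat(paste(x$bi[, 1], "<->", x$bi[, 2]), sep = "\n")
  invisible(x)
}

#' @rdname mixed_graph
#' @param graph a `mixed_graph`.
#' @export
observed_nodes <- function(graph) setdiff(graph$nodes, graph$latent)

#' Parents, children, ancestors and descendants
#'
#' Directed-edge relatives of a node set.  `graph_ancestors()` and
#' `graph_descendants()` include the query nodes themselves, the closure
#' convention used throughout the identification machinery.
#'
#' @param graph a `mixed_graph`.
#' @param nodes character vector of node labels.
#' @return Character vector of node labels.
#' @export
graph_parents <- function(graph, nodes) {
  check_nodes_known(nodes, graph$nodes, "graph_parents()")
  unique(graph$di[graph$di[, 2] %in% nodes, 1])
}

#' @rdname graph_parents
#' @export
graph_children <- function(graph, nodes) {
  check_nodes_known(nodes, graph$nodes, "graph_children()")
  unique(graph$di[graph$di[, 1] %in% nodes, 2])
}

#' @rdname graph_parents
#' @export
graph_ancestors <- function(graph, nodes) {
  check_nodes_known(nodes, graph$nodes, "graph_ancestors()")
  out <- nodes
  repeat {
    nxt <- union(out, graph_parents(graph, out))
    if (length(nxt) == length(out)) return(sort(out))
    out <- nxt
  }
}

#' @rdname graph_parents
#' @export
graph_descendants <- function(graph, nodes) {
  check_nodes_known(nodes, graph$nodes, "graph_descendants()")
  out <- nodes
  repeat {
    nxt <- union(out, graph_children(graph, out))
    if (length(nxt) == length(out)) return(sort(out))
    out <- nxt
  }
}

#' Graph mutilation
#'
#' `mutilate_incoming()` simulates an intervention on `targets`: every
#' directed edge into a target and every bidirected edge incident to a
#' target is removed (a bidirected edge encodes an incoming latent arrow,
#' and an intervention cuts all incoming influence).  `mutilate_outgoing()`
#' removes the directed edges out of `sources`, leaving bidirected edges
#' untouched; it builds the premise graphs of do-calculus rules 2 and 3.
#' Both return a new graph and leave the input unmodified.
#'
#' @param graph a `mixed_graph`.
#' @param targets,sources character vector of node labels.
#' @return A `mixed_graph`.
#' @examples
#' g <- mixed_graph(c("U", "X", "Z", "Y"),
#'                  directed = rbind(c("U", "X"), c("U", "Y"),
#'                                   c("X", "Z"), c("Z", "Y")),
#'                  latent = "U")
#' mutilate_incoming(g, "X")
#' @export
mutilate_incoming <- function(graph, targets) {
  check_nodes_known(targets, graph$nodes, "mutilate_incoming()")
  g <- graph
  g$di <- g$di[!(g$di[, 2] %in% targets), , drop = FALSE]
  if (nrow(g$bi))
    g$bi <- g$bi[!(g$bi[, 1] %in% targets | g$bi[, 2] %in% targets), ,
                 drop = FALSE]
  g
}

#' @rdname mutilate_incoming
#' @export
mutilate_outgoing <- function(graph, sources) {
  check_nodes_known(sources, graph$nodes, "mutilate_outgoing()")
  g <- graph
  g$di <- g$di[!(g$di[, 1] %in% sources), , drop = FALSE]
  g
}

#' Topological order of the directed part
#'
#' Kahn's algorithm with a lexicographic tie-break on node labels, so the
#' order (and hence any seeded ancestral-sampling run that walks it) is
#' reproducible.
#'
#' @param graph a `mixed_graph`.
#' @return Character vector: every node appears after all its directed
#'   parents.
#' @export
topological_sort <- function(graph) {
  nodes <- graph$nodes
  di <- graph$di
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(di)) {
    tb <- table(di[, 2])
    indeg[names(tb)] <- as.integer(tb)
  }
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  indeg <- indeg[indeg > 0L]
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    out <- c(out, v)
    ch <- di[di[, 1] == v, 2]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) {
        avail <- sort(c(avail, w))
        indeg <- indeg[names(indeg) != w]
      }
    }
  }
  if (length(out) < length(nodes)) {
    rest <- setdiff(nodes, out)
    cyc <- find_cycle(di, rest)
    stop("directed part has a cycle: ", paste(cyc, collapse = " -> "))
  }
  out
}

find_cycle <- function(di, rest) {
  # walk parents within the unresolvable set until a node repeats
  v <- rest[1]
  path <- v
  repeat {
    p <- di[di[, 2] == v & di[, 1] %in% rest, 1]
    v <- p[1]
    if (v %in% path) {
      i <- match(v, path)
      return(c(rev(path[i:length(path)]), v))
    }
    path <- c(path, v)
  }
}

#' d-separation in a mixed graph
#'
#' Tests whether every path between `set_a` and `set_b` is blocked given
#' `given`.  A path is blocked when a non-collider on it is conditioned on,
#' or when a collider (both adjacent edges pointing into the node) and all
#' its descendants are unconditioned.  Bidirected edges are first expanded
#' into a fresh latent common parent each, after which the standard
#' moralized-ancestral-graph test is applied; this is equivalent to native
#' m-separation on the ADMG.
#'
#' @param graph a `mixed_graph`.
#' @param set_a,set_b,given disjoint character vectors of node labels
#'   (`given` may be empty).
#' @return `TRUE` iff `set_a` and `set_b` are d-separated given `given`.
#' @export
d_separated <- function(graph, set_a, set_b, given = character()) {
  check_nodes_known(c(set_a, set_b, given), graph$nodes, "d_separated()")
  if (length(intersect(set_a, set_b)) || length(intersect(set_a, given)) ||
      length(intersect(set_b, given))) {
    stop("d_separated() requires disjoint node sets")
  }
  if (!length(set_a) || !length(set_b)) return(TRUE)
  g <- expand_bidirected(graph)
  # ancestral subgraph of all involved nodes
  keep <- graph_ancestors(g, c(set_a, set_b, given))
  di <- g$di[g$di[, 1] %in% keep & g$di[, 2] %in% keep, , drop = FALSE]
  # moralize: undirected skeleton + marry parents of each node
  und <- di[, , drop = FALSE]
  for (v in keep) {
    pa <- di[di[, 2] == v, 1]
    if (length(pa) > 1) {
      prs <- utils::combn(pa, 2)
      und <- rbind(und, t(prs))
    }
  }
  # delete conditioning nodes, test connectivity
  keep2 <- setdiff(keep, given)
  und <- und[und[, 1] %in% keep2 & und[, 2] %in% keep2, , drop = FALSE]
  if (!nrow(und)) return(TRUE)
  ig <- igraph::graph_from_edgelist(und, directed = FALSE)
  ig <- igraph::add_vertices(
    ig, length(setdiff(keep2, igraph::V(ig)$name)),
    name = setdiff(keep2, igraph::V(ig)$name))
  comp <- igraph::components(ig)$membership
  a_in <- intersect(set_a, names(comp))
  b_in <- intersect(set_b, names(comp))
  if (!length(a_in) || !length(b_in)) return(TRUE)
  !any(comp[a_in] %in% comp[b_in])
}

# Replace each bidirected edge u <-> v by u <- .l_k -> v with a fresh latent.
expand_bidirected <- function(graph) {
  if (!nrow(graph$bi)) return(graph)
  k <- nrow(graph$bi)
  lat <- paste0(".l", seq_len(k), "_", graph$bi[, 1], "_", graph$bi[, 2])
  di <- rbind(graph$di,
              cbind(lat, graph$bi[, 1]),
              cbind(lat, graph$bi[, 2]))
  colnames(di) <- c("from", "to")
  structure(list(nodes = c(graph$nodes, lat), di = di,
                 bi = graph$bi[0, , drop = FALSE],
                 latent = c(graph$latent, lat)),
            class = "mixed_graph")
}

#' Latent projection of an explicit-latent DAG
#'
#' Applies, to a fixed point, the three latent-variable simplification
#' rules: (1) remove latents with no children; (2) bypass a latent with
#' parents by connecting all its parents to all its children; (3) if two
#' latents `U`, `W` satisfy `children(W)` a subset of `children(U)`, remove
#' `W`.  Each surviving latent is then parentless with two or more observed
#' children and is converted into a clique of bidirected edges among its
#' children; latents left with a single child carry no confounding
#' information and are dropped.  The intermediate simplified DAG is exposed
#' as attribute `"simplified"`.
#'
#' @param graph an explicit-latent `mixed_graph` (no bidirected edges).
#' @return An ADMG over the observed nodes, with the canonical simplified
#'   DAG attached as `attr(, "simplified")`.  Projecting a graph with no
#'   latent nodes returns it unchanged.
#' @export
latent_project <- function(graph) {
  if (nrow(graph$bi)) stop("latent_project() expects an explicit-latent DAG")
  g <- graph
  repeat {
    changed <- FALSE
    # rule 1: latents with no children
    drop1 <- g$latent[!(g$latent %in% g$di[, 1])]
    if (length(drop1)) {
      g <- drop_nodes(g, drop1)
      changed <- TRUE
    }
    # rule 2: bypass one latent that still has parents
    withpa <- g$latent[g$latent %in% g$di[, 2]]
    if (length(withpa)) {
      u <- sort(withpa)[1]
      pa <- graph_parents(g, u)
      ch <- graph_children(g, u)
      add <- expand.grid(from = pa, to = ch, stringsAsFactors = FALSE)
      add <- add[add$from != add$to, , drop = FALSE]
      g$di <- rbind(g$di, as.matrix(add))
      g$di <- g$di[!duplicated(g$di), , drop = FALSE]
      g <- drop_nodes(g, u)
      changed <- TRUE
    }
    # rule 3: children(W) subset of children(U) -> remove W
    lats <- sort(g$latent)
    if (length(lats) > 1) {
      chl <- lapply(lats, function(l) graph_children(g, l))
      names(chl) <- lats
      for (iu in seq_along(lats)) {
        for (iw in seq_along(lats)) {
          if (iu == iw) next
          u <- lats[iu]; w <- lats[iw]
          if (!(u %in% g$latent) || !(w %in% g$latent)) next
          sub <- all(chl[[w]] %in% chl[[u]])
          eqd <- setequal(chl[[w]], chl[[u]])
          # on equal child sets keep the lexicographically smaller latent
          if (sub && (!eqd || u < w)) {
            g <- drop_nodes(g, w)
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  simplified <- g
  # convert surviving latents (parentless) into bidirected cliques
  bi <- matrix(character(), ncol = 2)
  for (l in g$latent) {
    ch <- graph_children(g, l)
    if (length(ch) > 1) bi <- rbind(bi, t(utils::combn(sort(ch), 2)))
  }
  obs <- observed_nodes(g)
  di <- g$di[g$di[, 1] %in% obs & g$di[, 2] %in% obs, , drop = FALSE]
  out <- mixed_graph(obs, directed = di,
                     bidirected = if (nrow(bi)) bi else NULL)
  attr(out, "simplified") <- simplified
  out
}

drop_nodes <- function(g, drop) {
  g$nodes <- setdiff(g$nodes, drop)
  g$latent <- setdiff(g$latent, drop)
  g$di <- g$di[!(g$di[, 1] %in% drop | g$di[, 2] %in% drop), , drop = FALSE]
  if (nrow(g$bi))
    g$bi <- g$bi[!(g$bi[, 1] %in% drop | g$bi[, 2] %in% drop), , drop = FALSE]
  g
}

#' Confounded components (districts)
#'
#' Partitions `subset` into maximal bidirected-connected components of the
#' induced subgraph — the c-components that drive the recursion of the
#' complete identification algorithm.
#'
#' @param graph an ADMG.
#' @param subset character vector of observed nodes (defaults to all
#'   observed nodes).
#' @return A list of character vectors partitioning `subset`, sorted by
#'   first element.
#' @export
districts <- function(graph, subset = observed_nodes(graph)) {
  check_nodes_known(subset, graph$nodes, "districts()")
  bi <- graph$bi[graph$bi[, 1] %in% subset & graph$bi[, 2] %in% subset, ,
                 drop = FALSE]
  memb <- stats::setNames(seq_along(subset), subset)
  if (nrow(bi)) {
    ig <- igraph::graph_from_edgelist(bi, directed = FALSE)
    iso <- setdiff(subset, igraph::V(ig)$name)
    ig <- igraph::add_vertices(ig, length(iso), name = iso)
    memb <- igraph::components(ig)$membership[subset]
  }
  out <- split(sort(subset), memb[sort(subset)])
  out <- unname(out)
  out[order(vapply(out, `[`, "", 1))]
}

#' Induced subgraph
#'
#' @param graph a `mixed_graph`.
#' @param keep node labels to retain.
#' @return The `mixed_graph` induced on `keep`.
#' @export
induced_subgraph_mg <- function(graph, keep) {
  check_nodes_known(keep, graph$nodes, "induced_subgraph_mg()")
  di <- graph$di[graph$di[, 1] %in% keep & graph$di[, 2] %in% keep, ,
                 drop = FALSE]
  bi <- graph$bi[graph$bi[, 1] %in% keep & graph$bi[, 2] %in% keep, ,
                 drop = FALSE]
  mixed_graph(graph$nodes[graph$nodes %in% keep], directed = di,
              bidirected = if (nrow(bi)) bi else NULL,
              latent = intersect(graph$latent, keep))
}

#' Structural equality of two mixed graphs
#'
#' Compares node sets, directed edges, bidirected edges and latent flags,
#' ignoring order.
#'
#' @param a,b `mixed_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
graph_equal <- function(a, b) {
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  setequal(a$nodes, b$nodes) &&
    identical(key(a$di), key(b$di)) &&
    identical(key(a$bi), key(b$bi)) &&
    setequal(a$latent, b$latent)
}

#' Read and write the plain-text graph dialect
#'
#' One statement per line: `A -> B` (directed edge), `A <-> B` (bidirected
#' edge), `latent A` (flag), `node A` (declare an isolated node).  `#`
#' starts a comment.  No standard format carries bidirected edges portably,
#' hence this minimal dialect.
#'
#' @param text character vector of lines, or a file path for `read_graph()`.
#' @param path file path.
#' @param graph a `mixed_graph`.
#' @return `read_graph()`/`parse_graph()` return a `mixed_graph`;
#'   `write_graph_text()` returns the lines invisibly.
#' @examples
#' g <- parse_graph(c("X -> Z", "Z -> Y", "X <-> Y"))
#' @export
parse_graph <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  di <- bi <- matrix(character(), ncol = 2)
  nodes <- latent <- character()
  for (ln in lines) {
    if (grepl("<->", ln, fixed = TRUE)) {
      p <- trimws(strsplit(ln, "<->", fixed = TRUE)[[1]])
      bi <- rbind(bi, p); nodes <- c(nodes, p)
    } else if (grepl("->", ln, fixed = TRUE)) {
      p <- trimws(strsplit(ln, "->", fixed = TRUE)[[1]])
      di <- rbind(di, p); nodes <- c(nodes, p)
    } else if (grepl("^latent\\s+", ln)) {
      v <- trimws(sub("^latent\\s+", "", ln))
      latent <- c(latent, v); nodes <- c(nodes, v)
    } else if (grepl("^node\\s+", ln)) {
      nodes <- c(nodes, trimws(sub("^node\\s+", "", ln)))
    } else {
      stop("cannot parse graph statement: '", ln, "'")
    }
  }
  mixed_graph(unique(nodes),
              directed = if (nrow(di)) di else NULL,
              bidirected = if (nrow(bi)) bi else NULL,
              latent = unique(latent))
}

#' @rdname parse_graph
#' @export
read_graph <- function(path) parse_graph(readLines(path))

#' @rdname parse_graph
#' @export
write_graph_text <- function(graph, path = NULL) {
  lines <- c(
    paste("node", graph$nodes),
    if (length(graph$latent)) paste("latent", graph$latent),
    if (nrow(graph$di)) paste(graph$di[, 1], "->", graph$di[, 2]),
    if (nrow(graph$bi)) paste(graph$bi[, 1], "<->", graph$bi[, 2]))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Export a mixed graph to DOT
#'
#' Bidirected edges are rendered as dashed undirected edges, the usual
#' visual convention for latent confounding; latent nodes are filled grey.
#'
#' @param graph a `mixed_graph`.
#' @param path optional file to write to.
#' @return The DOT source as a character scalar (invisibly if written).
#' @export
graph_to_dot <- function(graph, path = NULL) {
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph G {",
             paste0("  ", q(graph$nodes),
                    ifelse(graph$nodes %in% graph$latent,
                           " [style=filled, fillcolor=grey]", ""), ";"),
             if (nrow(graph$di))
               paste0("  ", q(graph$di[, 1]), " -> ", q(graph$di[, 2]), ";"),
             if (nrow(graph$bi))
               paste0("  ", q(graph$bi[, 1]), " -> ", q(graph$bi[, 2]),
                      " [dir=none, style=dashed];"),
             "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
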