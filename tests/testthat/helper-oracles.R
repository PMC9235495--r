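# Independent oracles used across the suite.  These deliberately avoid the
# package's own graph machinery beyond reading the edge matrices.

# d-separation by exhaustive enumeration of simple paths with the textbook
# blocking rules: a conditioned non-collider blocks; an unconditioned
# collider (no descendant conditioned either) blocks.  Bidirected edges have
# arrowheads at both ends.
oracle_d_separated <- function(graph, A, B, Z = character()) {
  edges <- list()
  if (nrow(graph$di)) {
    for (i in seq_len(nrow(graph$di))) {
      u <- graph$di[i, 1]; v <- graph$di[i, 2]
      edges[[length(edges) + 1]] <- list(a = u, b = v, head_a = FALSE, head_b = TRUE)
    }
  }
  if (nrow(graph$bi)) {
    for (i in seq_len(nrow(graph$bi))) {
      u <- graph$bi[i, 1]; v <- graph$bi[i, 2]
      edges[[length(edges) + 1]] <- list(a = u, b = v, head_a = TRUE, head_b = TRUE)
    }
  }
  # descendants via directed edges only (inclusive)
  desc <- function(v) {
    out <- v
    repeat {
      ch <- unique(graph$di[graph$di[, 1] %in% out, 2])
      nxt <- union(out, ch)
      if (length(nxt) == length(out)) return(out)
      out <- nxt
    }
  }
  incident <- function(v) {
    which(vapply(edges, function(e) e$a == v || e$b == v, logical(1)))
  }
  path_open <- function(nodes, heads_in) {
    # heads_in[i]: c(into-node from previous edge, into-node from next edge)
    if (length(nodes) <= 2) return(TRUE)
    for (i in seq(2, length(nodes) - 1)) {
      m <- nodes[i]
      collider <- heads_in[[i]][1] && heads_in[[i]][2]
      if (!collider && m %in% Z) return(FALSE)
      if (collider && !any(desc(m) %in% Z)) return(FALSE)
    }
    TRUE
  }
  found_open <- FALSE
  dfs <- function(v, target, nodes, heads_in) {
    if (found_open) return()
    for (ei in incident(v)) {
      e <- edges[[ei]]
      w <- if (e$a == v) e$b else e$a
      head_at_v <- if (e$a == v) e$head_a else e$head_b
      head_at_w <- if (e$a == v) e$head_b else e$head_a
      if (w %in% nodes) next
      hi <- heads_in
      hi[[length(nodes)]][2] <- head_at_v
      hi[[length(nodes) + 1]] <- c(head_at_w, NA)
      if (w %in% target) {
        if (path_open(c(nodes, w), hi)) found_open <<- TRUE
      } else {
        dfs(w, target, c(nodes, w), hi)
      }
      if (found_open) return()
    }
  }
  for (a in A) {
    dfs(a, B, a, list(c(NA, NA)))
    if (found_open) return(FALSE)
  }
  TRUE
}

# Random mixed graph: random node order, forward directed edges with
# probability p_di, bidirected pairs with probability p_bi.
random_mixed_graph <- function(n, p_di = 0.3, p_bi = 0.15) {
  labels <- paste0("v", seq_len(n))
  ord <- sample(labels)
  di <- bi <- matrix(character(), ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (stats::runif(1) < p_di) di <- rbind(di, c(ord[i], ord[j]))
      if (stats::runif(1) < p_bi) bi <- rbind(bi, c(ord[i], ord[j]))
    }
  }
  mixed_graph(labels,
              directed = if (nrow(di)) di else NULL,
              bidirected = if (nrow(bi)) bi else NULL)
}

# All DAGs on the given labels (small n only): every orientation/selection
# of edges over a fixed vertex order is acyclic by construction, and every
# DAG arises from some order; deduplicate by edge-set key.
all_dags <- function(labels) {
  n <- length(labels)
  pairs <- t(utils::combn(labels, 2))
  out <- list()
  seen <- character()
  perms <- all_perms(labels)
  for (ord in perms) {
    pos <- stats::setNames(seq_len(n), ord)
    # for this order: each pair can be absent or oriented forward
    m <- nrow(pairs)
    for (mask in 0:(2^m - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      if (length(sel)) {
        e <- pairs[sel, , drop = FALSE]
        flip <- pos[e[, 1]] > pos[e[, 2]]
        e[flip, ] <- e[flip, 2:1]
      } else e <- pairs[0, , drop = FALSE]
      key <- paste(sort(paste(e[, 1], e[, 2])), collapse = ";")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1]] <-
        mixed_graph(labels, directed = if (nrow(e)) e else NULL)
    }
  }
  out
}

all_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  }
  out
}

# three disjoint non-empty set pairs (A, B) plus a conditioning set from the
# remaining nodes, enumerated exhaustively for small node sets
all_disjoint_triples <- function(nodes) {
  out <- list()
  for (a in nodes) {
    for (b in setdiff(nodes, a)) {
      if (a >= b) next
      rest <- setdiff(nodes, c(a, b))
      subsets <- list(character(0))
      for (r in rest) subsets <- c(subsets, lapply(subsets, c, r))
      for (z in subsets) out[[length(out) + 1]] <- list(a = a, b = b, z = z)
    }
  }
  out
}

fig2b_graph <- function() {
  mixed_graph(c("U", "X", "Z", "Y"),
              directed = rbind(c("U", "X"), c("U", "Y"),
                               c("X", "Z"), c("Z", "Y")),
              latent = "U")
}

fig2a_graph <- function() {
  mixed_graph(c("U", "X", "Y"),
              directed = rbind(c("U", "X"), c("U", "Y"), c("X", "Y")),
              latent = "U")
}
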