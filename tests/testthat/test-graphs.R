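test_that("mutilation severs the right edges and leaves the input intact", {
  g <- fig2b_graph()
  gx <- mutilate_incoming(g, "X")
  expect_setequal(paste(gx$di[, 1], gx$di[, 2]),
                  c("U Y", "X Z", "Z Y"))
  # input unmodified
  expect_equal(nrow(g$di), 4)

  gz <- mutilate_outgoing(g, "Z")
  expect_setequal(paste(gz$di[, 1], gz$di[, 2]),
                  c("U X", "U Y", "X Z"))

  # roots with no bidirected edges: incoming mutilation is a no-op
  expect_true(graph_equal(mutilate_incoming(g, "U"), g))
  # all nodes: edgeless
  expect_equal(nrow(mutilate_incoming(g, g$nodes)$di), 0)

  # leaf sources: outgoing mutilation is a no-op
  expect_true(graph_equal(mutilate_outgoing(g, "Y"), g))
  chain <- parse_graph(c("A -> B", "B -> C"))
  expect_equal(nrow(mutilate_outgoing(chain, c("A", "B"))$di), 0)

  # bidirected edges incident to a target are cut by incoming mutilation only
  admg <- parse_graph(c("X -> Y", "X <-> Y"))
  expect_equal(nrow(mutilate_incoming(admg, "X")$bi), 0)
  expect_equal(nrow(mutilate_outgoing(admg, "X")$bi), 1)

  expect_error(mutilate_incoming(g, "nope"), "nope")
})

test_that("mutilations are idempotent and commute on disjoint sets", {
  set.seed(41)
  for (i in 1:20) {
    g <- random_mixed_graph(6)
    tg <- sample(g$nodes, 2)
    sr <- setdiff(g$nodes, tg)[1:2]
    m1 <- mutilate_incoming(g, tg)
    expect_true(graph_equal(m1, mutilate_incoming(m1, tg)))
    ab <- mutilate_outgoing(mutilate_incoming(g, tg), sr)
    ba <- mutilate_incoming(mutilate_outgoing(g, sr), tg)
    expect_true(graph_equal(ab, ba))
  }
})

test_that("topological sort respects edges, breaks ties lexicographically", {
  g <- fig2b_graph()
  ord <- topological_sort(g)
  pos <- match(g$nodes, ord)
  names(pos) <- g$nodes
  expect_lt(pos["U"], pos["X"])
  expect_lt(pos["X"], pos["Z"])
  expect_lt(pos["Z"], pos["Y"])

  free <- mixed_graph(c("b", "a", "c"))
  expect_equal(topological_sort(free), c("a", "b", "c"))

  set.seed(7)
  for (i in 1:30) {
    g <- random_mixed_graph(8, p_di = 0.4, p_bi = 0)
    ord <- match(g$nodes, topological_sort(g))
    names(ord) <- g$nodes
    if (nrow(g$di))
      expect_true(all(ord[g$di[, 1]] < ord[g$di[, 2]]))
  }

  expect_error(
    mixed_graph(c("A", "B"), directed = rbind(c("A", "B"), c("B", "A"))),
    "cycle")

  # intervened nodes are parentless in the mutilated graph, so any
  # topological order of it starts sampling them unconditionally
  set.seed(8)
  for (i in 1:10) {
    g <- random_mixed_graph(7, p_bi = 0)
    x <- sample(g$nodes, 2)
    gm <- mutilate_incoming(g, x)
    expect_equal(length(graph_parents(gm, x)), 0)
  }
})

test_that("d-separation matches exhaustive path enumeration", {
  # exhaustive on all 3-node DAGs, all disjoint (a, b, z) triples
  labels <- c("a", "b", "c")
  for (g in all_dags(labels)) {
    for (tr in all_disjoint_triples(labels)) {
      expect_equal(d_separated(g, tr$a, tr$b, tr$z),
                   oracle_d_separated(g, tr$a, tr$b, tr$z),
                   info = paste(write_graph_text(g), collapse = "; "))
    }
  }
  # randomized coverage on 5-node mixed graphs (bidirected edges included)
  set.seed(11)
  for (i in 1:60) {
    g <- random_mixed_graph(5, p_di = 0.35, p_bi = 0.2)
    for (tr in sample(all_disjoint_triples(g$nodes), 8)) {
      expect_equal(d_separated(g, tr$a, tr$b, tr$z),
                   oracle_d_separated(g, tr$a, tr$b, tr$z))
    }
  }
  # set-valued arguments
  set.seed(12)
  for (i in 1:20) {
    g <- random_mixed_graph(6, p_di = 0.3, p_bi = 0.15)
    sh <- sample(g$nodes)
    A <- sh[1:2]; B <- sh[3:4]; Z <- sh[5]
    expect_equal(d_separated(g, A, B, Z), oracle_d_separated(g, A, B, Z))
  }

  g2 <- mixed_graph(c("p", "q"))
  expect_true(d_separated(g2, "p", "q"))
  expect_error(d_separated(fig2b_graph(), "X", "X", character()), "disjoint")
})

test_that("latent projection applies the three simplification rules", {
  # no latents: identity, no bidirected edges
  g <- parse_graph(c("A -> B", "B -> C"))
  expect_true(graph_equal(latent_project(g), g))

  # latent chain l1 -> l2 -> {A, B} collapses to one bidirected pair
  g <- mixed_graph(c("l1", "l2", "A", "B"),
                   directed = rbind(c("l1", "l2"), c("l2", "A"), c("l2", "B")),
                   latent = c("l1", "l2"))
  p <- latent_project(g)
  expect_setequal(p$nodes, c("A", "B"))
  expect_equal(nrow(p$di), 0)
  expect_equal(paste(p$bi[, 1], p$bi[, 2]), "A B")

  # rule order reaches the same fixed point as hand application:
  # duplicate-children latents collapse to a single bidirected edge
  g <- mixed_graph(c("t1", "t2", "A", "B"),
                   directed = rbind(c("t1", "A"), c("t1", "B"),
                                    c("t2", "A"), c("t2", "B")),
                   latent = c("t1", "t2"))
  p <- latent_project(g)
  expect_equal(nrow(p$bi), 1)

  # re-projecting an ADMG-turned-explicit form is stable: projection of a
  # latent-free graph is the identity, and projecting twice cannot add edges
  p2 <- latent_project(mixed_graph(p$nodes, directed = p$di))
  expect_equal(nrow(p2$bi), 0)

  expect_error(latent_project(parse_graph("A <-> B")), "explicit-latent")
})

test_that("latent projection reproduces the 4-observed/5-latent reduction", {
  # five latents exercising all three rules: T1, T2 duplicate confounders of
  # (X1, X2); T3 bypassed through its observed parent X3; T4 childless;
  # T5's only child is T4, so it dies after T4 does
  g <- mixed_graph(
    c("X1", "X2", "X3", "X4", "T1", "T2", "T3", "T4", "T5"),
    directed = rbind(c("T1", "X1"), c("T1", "X2"),
                     c("T2", "X1"), c("T2", "X2"),
                     c("X3", "T3"), c("T3", "X4"),
                     c("T5", "T4"),
                     c("X1", "X3"), c("X2", "X3")),
    latent = c("T1", "T2", "T3", "T4", "T5"))
  p <- latent_project(g)
  simplified <- attr(p, "simplified")
  # intermediate form: a single latent into X1, X2
  expect_equal(length(simplified$latent), 1)
  expect_setequal(graph_children(simplified, simplified$latent),
                  c("X1", "X2"))
  # final ADMG: observed skeleton plus one bidirected edge X1 <-> X2
  expect_setequal(p$nodes, c("X1", "X2", "X3", "X4"))
  expect_setequal(paste(p$di[, 1], p$di[, 2]),
                  c("X1 X3", "X2 X3", "X3 X4"))
  expect_equal(paste(p$bi[, 1], p$bi[, 2]), "X1 X2")
  # projected graph has no latent nodes left
  expect_equal(length(p$latent), 0)
})

test_that("districts equal bidirected-connected components", {
  # Fig 2a ADMG view: X <-> Y plus X -> Y is one confounded block
  admg <- parse_graph(c("X -> Y", "X <-> Y"))
  expect_equal(districts(admg), list(c("X", "Y")))

  # no bidirected edges: all singletons
  g <- parse_graph(c("A -> B", "B -> C"))
  expect_equal(districts(g), list("A", "B", "C"))

  # random ADMGs vs an independent union-find over bidirected edges
  set.seed(13)
  for (i in 1:25) {
    g <- random_mixed_graph(8, p_di = 0.25, p_bi = 0.2)
    parent <- stats::setNames(g$nodes, g$nodes)
    find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
    if (nrow(g$bi)) for (k in seq_len(nrow(g$bi))) {
      parent[find(g$bi[k, 1])] <- find(g$bi[k, 2])
    }
    key <- vapply(g$nodes, find, "")
    expected <- unname(lapply(split(g$nodes, key), sort))
    got <- districts(g)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(expected, paste, "", collapse = ","))
  }
})

test_that("graph text dialect and DOT export round-trip", {
  g <- mixed_graph(c("A", "B", "C", "L", "solo"),
                   directed = rbind(c("L", "A"), c("A", "B"), c("B", "C")),
                   latent = "L")
  txt <- write_graph_text(g)
  g2 <- parse_graph(txt)
  expect_true(graph_equal(g, g2))

  f <- tempfile(fileext = ".txt")
  write_graph_text(g, f)
  expect_true(graph_equal(read_graph(f), g))

  admg <- parse_graph(c("X -> Y", "X <-> Y  # confounded"))
  dot <- graph_to_dot(admg)
  expect_match(dot, "style=dashed")
  expect_match(dot, '"X" -> "Y"')

  expect_error(parse_graph("A -- B"), "cannot parse")
})
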