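make_net <- function(nodes, from, to, strength = NULL) {
  if (is.null(strength)) strength <- rep(0.8, length(from))
  structure(list(
    nodes = nodes,
    edges = data.frame(from = from, to = to, strength = strength,
                       class = ifelse(strength >= 0.7, "strong",
                                      "weak"),
                       stringsAsFactors = FALSE),
    threshold = 0.4, strong = 0.7), class = "avg_network")
}

test_that("denseness definition and guards", {
  net <- make_net(c("a", "b", "c", "d", "e"), c("a", "b"), c("b", "c"))
  expect_equal(denseness(net), 20)
  full <- make_net(c("a", "b", "c"), c("a", "a", "b"),
                   c("b", "c", "c"))
  expect_equal(denseness(full), 100)
  empty <- make_net(paste0("n", 1:32), character(0), character(0))
  expect_equal(denseness(empty), 0)
  expect_error(denseness(make_net("a", character(0), character(0))),
               "2 nodes")
})

test_that("distance to target: chain, disconnection, errors", {
  net <- make_net(c("A", "B", "sitting", "iso"),
                  c("A", "B"), c("B", "sitting"))
  d <- distance_to_target(net)
  expect_equal(d[["A"]], 2)
  expect_equal(d[["B"]], 1)
  expect_equal(d[["sitting"]], 0)
  expect_identical(d[["iso"]], Inf)
  expect_error(distance_to_target(net, target = "zz"), "target")
})

test_that("distances match the exhaustive path-enumeration oracle", {
  for (s in 1:50) {
    g <- random_test_graph(seed = 500 + s)
    d <- distance_to_target(g, target = "sb")
    oracle <- oracle_distances(g$nodes, g$edges, "sb")
    expect_identical(unname(d[g$nodes]), unname(oracle[g$nodes]))
  }
})

test_that("distances are invariant under node relabelling", {
  g <- random_test_graph(seed = 77)
  set.seed(1)
  new_names <- stats::setNames(
    c("sb", sample(LETTERS, length(g$nodes) - 1)), g$nodes)
  g2 <- g
  g2$nodes <- unname(new_names[g$nodes])
  g2$edges$from <- unname(new_names[g$edges$from])
  g2$edges$to <- unname(new_names[g$edges$to])
  d1 <- distance_to_target(g, "sb")
  d2 <- distance_to_target(g2, "sb")
  expect_identical(unname(d1[g$nodes]),
                   unname(d2[unname(new_names[g$nodes])]))
})

test_that("removing an edge never shortens a distance", {
  for (s in 1:10) {
    g <- random_test_graph(seed = 900 + s)
    d_full <- distance_to_target(g, "sb")
    for (r in seq_len(nrow(g$edges))) {
      g2 <- g
      g2$edges <- g$edges[-r, , drop = FALSE]
      d_cut <- distance_to_target(g2, "sb")
      expect_true(all(d_cut >= d_full - 1e-12))
    }
  }
})

test_that("cluster mean distance: mean, N.A., partial connection", {
  sch <- make_schema(c("sitting", "p1", "p2", "q1", "q2"),
                     c("psychology_behaviour", "institutional_home",
                       "institutional_home", "physical_health",
                       "physical_health"),
                     c(list(c("1", "2", "3", "4")),
                       rep(list(c("1", "2")), 4)))
  d <- c(sitting = 0, p1 = 1, p2 = 2, q1 = 2, q2 = Inf)
  cm <- cluster_mean_distance(d, sch,
                              clusters = c("institutional_home",
                                           "physical_health"))
  expect_equal(cm[["institutional_home"]], 1.5)
  expect_equal(cm[["physical_health"]], 2)  # disconnected excluded
  d2 <- c(sitting = 0, p1 = 1, p2 = 2, q1 = Inf, q2 = Inf)
  cm2 <- cluster_mean_distance(d2, sch,
                               clusters = c("physical_health"))
  expect_true(is.na(cm2[["physical_health"]]))  # N.A.
  expect_error(cluster_mean_distance(d, sch, clusters = "bogus"),
               "unknown cluster")
})

test_that("weighted betweenness: star, path, small-graph guard", {
  star <- make_net(c("sitting", "C", "l1", "l2"),
                   c("C", "C", "C"), c("sitting", "l1", "l2"),
                   strength = c(0.8, 0.8, 0.8))
  b <- weighted_betweenness_sb(star)
  expect_gt(b[["C"]], max(b[c("l1", "l2")]))
  expect_equal(unname(b[c("l1", "l2")]), c(0, 0))

  path <- make_net(c("A", "B", "sitting"), c("A", "B"),
                   c("B", "sitting"))
  bp <- weighted_betweenness_sb(path)
  expect_gt(bp[["B"]], bp[["A"]])
  expect_equal(bp[["A"]], 0)

  tiny <- make_net(c("A", "sitting", "off"), "A", "sitting")
  expect_warning(bt <- weighted_betweenness_sb(tiny), "fewer than 3")
  expect_true(all(bt == 0))
})

test_that("betweenness equals the exhaustive shortest-path oracle", {
  for (s in 1:50) {
    g <- random_test_graph(seed = 600 + s)
    b <- weighted_betweenness_sb(g, target = "sb")
    edges <- g$edges
    edges$w <- 1 / edges$strength
    oracle <- oracle_betweenness(g$nodes, edges)
    expect_equal(unname(b[g$nodes]), unname(oracle[g$nodes]),
                 tolerance = 1e-12)
  }
})

test_that("equal strengths reduce to unweighted betweenness ranking", {
  g <- random_test_graph(seed = 314)
  g$edges$strength <- 0.5
  bw <- weighted_betweenness_sb(g, "sb")
  gu <- sosbn:::as_igraph_avg(g)
  bu <- igraph::betweenness(gu, directed = FALSE, weights = NA)
  m <- length(g$nodes)
  bu <- bu / ((m - 1) * (m - 2) / 2)
  expect_equal(order(-bw, names(bw)),
               order(-bu[names(bw)], names(bw)))
})

test_that("top-node ranking: order, ties, degenerate cases", {
  r <- rank_top_nodes(c(A = 0.5, B = 0.2, C = 0.0), k = 2)
  expect_identical(r$node, c("A", "B"))
  expect_identical(r$rank, c(1L, 2L))
  expect_false(any(r$tied))
  # exact tie at rank 2: both reported
  r2 <- rank_top_nodes(c(A = 0.5, B = 0.2, C = 0.2, D = 0.1), k = 2)
  expect_identical(r2$node, c("A", "B", "C"))
  expect_identical(r2$rank, c(1L, 2L, 2L))
  expect_identical(r2$tied, c(FALSE, TRUE, TRUE))
  expect_warning(r3 <- rank_top_nodes(c(A = 0, B = 0)), "zero")
  expect_identical(nrow(r3), 0L)
  # k beyond node count: full ranking
  r4 <- rank_top_nodes(c(A = 0.5, B = 0.2), k = 10)
  expect_identical(r4$node, c("A", "B"))
  # the target is excluded
  r5 <- rank_top_nodes(c(sitting = 9, A = 0.5, B = 0.2), k = 1)
  expect_identical(r5$node, "A")
})

test_that("denseness survives a GraphML round trip", {
  g <- random_test_graph(seed = 808)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path)
  g2 <- read_graphml(path)
  expect_setequal(g2$nodes, g$nodes)
  expect_equal(denseness(g2), denseness(g))
  k1 <- sosbn:::edge_key(g$edges$from, g$edges$to)
  k2 <- sosbn:::edge_key(g2$edges$from, g2$edges$to)
  expect_setequal(k2, k1)
})
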