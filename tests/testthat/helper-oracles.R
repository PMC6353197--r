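# Independent brute-force oracles used to check the graph statistics
# and the quantile-based recodes. All enumeration-based, exact, and
# deliberately naive (only used on tiny inputs).

# all simple paths between two nodes of an undirected weighted graph
enumerate_paths <- function(nodes, edges, from, to) {
  nbr <- function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  }
  cost <- function(a, b) {
    hit <- (edges$from == a & edges$to == b) |
      (edges$from == b & edges$to == a)
    edges$w[hit][1]
  }
  paths <- list()
  walk <- function(path, total) {
    v <- path[length(path)]
    if (v == to) {
      paths[[length(paths) + 1]] <<- list(path = path, cost = total)
      return(invisible())
    }
    for (w in nbr(v)) {
      if (w %in% path) next
      walk(c(path, w), total + cost(v, w))
    }
  }
  walk(from, 0)
  paths
}

# exact weighted betweenness by shortest-path enumeration
oracle_betweenness <- function(nodes, edges, normalize = TRUE) {
  b <- stats::setNames(rep(0, length(nodes)), nodes)
  m <- length(nodes)
  if (m >= 3) {
    pairs <- utils::combn(nodes, 2)
    for (k in seq_len(ncol(pairs))) {
      s <- pairs[1, k]; t <- pairs[2, k]
      ps <- enumerate_paths(nodes, edges, s, t)
      if (!length(ps)) next
      costs <- vapply(ps, `[[`, 0, "cost")
      best <- min(costs)
      sp <- ps[abs(costs - best) < 1e-9]
      sigma <- length(sp)
      for (v in setdiff(nodes, c(s, t))) {
        through <- sum(vapply(sp, function(p) v %in% p$path, TRUE))
        b[v] <- b[v] + through / sigma
      }
    }
    if (normalize) b <- b / ((m - 1) * (m - 2) / 2)
  }
  b
}

# exact hop distance by unweighted shortest-path enumeration
oracle_distances <- function(nodes, edges, target) {
  e1 <- edges
  e1$w <- 1
  vapply(nodes, function(v) {
    if (v == target) return(0)
    ps <- enumerate_paths(nodes, e1, v, target)
    if (!length(ps)) Inf else min(vapply(ps, `[[`, 0, "cost"))
  }, numeric(1))
}

# random connected-ish weighted undirected test graph (<= 7 nodes)
random_test_graph <- function(seed, max_nodes = 7) {
  set.seed(seed)
  m <- sample(3:max_nodes, 1)
  nodes <- c("sb", paste0("v", seq_len(m - 1)))
  pairs <- utils::combn(nodes, 2)
  keep <- runif(ncol(pairs)) < 0.5
  # guarantee at least a spine so the target subgraph is nontrivial
  edges <- data.frame(from = nodes[-m], to = nodes[-1],
                      stringsAsFactors = FALSE)
  if (any(keep))
    edges <- unique(rbind(edges,
                          data.frame(from = pairs[1, keep],
                                     to = pairs[2, keep],
                                     stringsAsFactors = FALSE)))
  a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
  edges <- unique(data.frame(from = a, to = b, stringsAsFactors = FALSE))
  edges$strength <- round(runif(nrow(edges), 0.41, 0.99), 3)
  edges$class <- ifelse(edges$strength >= 0.7, "strong", "weak")
  structure(list(nodes = nodes, edges = edges, threshold = 0.4,
                 strong = 0.7), class = "avg_network")
}

# rank-based tertile oracle: boundaries from sorted order
oracle_tertiles <- function(x) {
  q <- stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  ifelse(x <= q[1], 1L, ifelse(x <= q[2], 2L, 3L))
}
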