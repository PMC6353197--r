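## Network statistics used to rank factors around SB: denseness,
## unweighted distance to the target, per-cluster mean distance, and
## stability-weighted betweenness on the target-linked subgraph.

#' Network denseness
#'
#' Realised edges as a percentage of all possible undirected pairs:
#' `100 * m / (p * (p - 1) / 2)`.
#'
#' @param network an `avg_network`.
#' @return Percentage in `[0, 100]`.
#' @export
denseness <- function(network) {
  p <- length(network$nodes)
  if (p < 2) stop("denseness needs at least 2 nodes")
  100 * nrow(network$edges) / (p * (p - 1) / 2)
}

#' Unweighted distance of every node to a target node
#'
#' Shortest-path edge count to `target` in the averaged network;
#' unreachable nodes are reported as `Inf` (the not-connected marker).
#'
#' @param network an `avg_network`.
#' @param target target node name (the SB node, `"sitting"`).
#' @return Named numeric vector of hop counts (0 for the target).
#' @export
distance_to_target <- function(network, target = "sitting") {
  if (!(target %in% network$nodes))
    stop("target node not in network: ", target)
  g <- as_igraph_avg(network)
  d <- igraph::distances(g, v = target, weights = NA)[1, ]
  d[network$nodes]
}

#' Mean distance to the target per SOS cluster
#'
#' Arithmetic mean of the finite distances of a cluster's nodes;
#' clusters in which no node connects to the target are reported as
#' `NA` (printed as "N.A."). Disconnected nodes of a partly connected
#' cluster are excluded from the mean; the target itself is excluded
#' from its own cluster.
#'
#' @param distances named vector from [distance_to_target()].
#' @param schema the [sos_schema()] carrying cluster labels.
#' @param target the target node name.
#' @param clusters cluster labels to report; defaults to the six
#'   SOS-framework clusters. Unknown labels are rejected.
#' @return Named numeric vector (NA where not applicable).
#' @export
cluster_mean_distance <- function(distances, schema,
                                  target = "sitting",
                                  clusters = sos_clusters()) {
  bad <- setdiff(clusters, unique(schema$cluster))
  if (length(bad)) stop("unknown cluster label(s): ",
                        paste(bad, collapse = ", "))
  vapply(clusters, function(cl) {
    members <- setdiff(schema$name[schema$cluster == cl], target)
    d <- distances[intersect(members, names(distances))]
    d <- d[is.finite(d)]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
}

#' Stability-weighted betweenness centrality on the SB-linked subgraph
#'
#' Betweenness is computed on the subgraph induced by the nodes with a
#' path to `target` (including the target). Edge traversal cost is
#' `1/strength` by default, so more stable edges make shorter paths;
#' the alternative `1 - strength` convention is available. Values are
#' normalised by `(m - 1) * (m - 2) / 2` pairs (subgraph size `m`) so
#' strata of different connectivity are comparable. Subgraphs with
#' fewer than 3 nodes yield all-zero centralities with a warning.
#'
#' @param network an `avg_network`.
#' @param target target node name.
#' @param weighting `"inverse"` (cost `1/strength`) or `"complement"`
#'   (cost `1 - strength`, floored at 1e-6).
#' @param normalize divide by the number of pairs `(m-1)(m-2)/2`.
#' @return Named numeric vector over the subgraph's nodes (target
#'   included, with its own centrality; rankings exclude it).
#' @export
weighted_betweenness_sb <- function(network, target = "sitting",
                                    weighting = c("inverse", "complement"),
                                    normalize = TRUE) {
  weighting <- match.arg(weighting)
  if (!(target %in% network$nodes))
    stop("target node not in network: ", target)
  d <- distance_to_target(network, target)
  sub_nodes <- names(d)[is.finite(d)]
  if (length(sub_nodes) < 3) {
    warning("target-linked subgraph has fewer than 3 nodes; ",
            "betweenness is identically zero")
    return(stats::setNames(rep(0, length(sub_nodes)), sub_nodes))
  }
  g <- as_igraph_avg(network)
  gs <- igraph::induced_subgraph(g, sub_nodes)
  w <- if (weighting == "inverse") 1 / igraph::E(gs)$strength
       else pmax(1 - igraph::E(gs)$strength, 1e-6)
  b <- igraph::betweenness(gs, directed = FALSE, weights = w)
  if (normalize) {
    m <- length(sub_nodes)
    b <- b / ((m - 1) * (m - 2) / 2)
  }
  b[sub_nodes]
}

#' Top nodes by centrality
#'
#' Ranks nodes by decreasing centrality (target excluded), reporting
#' every node tied at a reported rank; ties are ordered lexicographically
#' and flagged. With all-zero centralities an empty ranking is returned
#' with a warning. `k` larger than the node count returns the full
#' ranking.
#'
#' @param centrality named numeric vector (e.g. from
#'   [weighted_betweenness_sb()]).
#' @param k number of ranks to report.
#' @param target node to exclude from the ranking.
#' @return Data frame with columns `rank`, `node`, `value`, `tied`.
#' @export
rank_top_nodes <- function(centrality, k = 2L, target = "sitting") {
  x <- centrality[setdiff(names(centrality), target)]
  if (!length(x) || all(x == 0)) {
    warning("all centralities are zero; empty ranking")
    return(data.frame(rank = integer(0), node = character(0),
                      value = numeric(0), tied = logical(0)))
  }
  ord <- order(-x, names(x))
  x <- x[ord]
  rk <- match(-x, sort(unique(-x)))  # dense rank, ties share a rank
  keep <- rk <= min(k, max(rk))
  data.frame(rank = rk[keep], node = names(x)[keep],
             value = unname(x[keep]),
             tied = duplicated(rk[keep]) | duplicated(rk[keep],
                                                      fromLast = TRUE),
             row.names = NULL)
}

#' Full network statistics report
#'
#' Bundles denseness, per-node distance to the target, per-cluster mean
#' distance, stability-weighted betweenness on the target-linked
#' subgraph, and the top-ranked nodes.
#'
#' @param network an `avg_network`.
#' @param schema the [sos_schema()] for cluster aggregation.
#' @param target target node name.
#' @param k ranks to report.
#' @param weighting betweenness weighting convention.
#' @return A `net_stats` object.
#' @export
network_stats <- function(network, schema, target = "sitting", k = 2L,
                          weighting = "inverse") {
  d <- distance_to_target(network, target)
  clusters <- intersect(sos_clusters(), unique(schema$cluster))
  bw <- weighted_betweenness_sb(network, target, weighting = weighting)
  top <- withCallingHandlers(
    rank_top_nodes(bw, k = k, target = target),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(
    denseness = denseness(network),
    distance = d,
    cluster_distance = cluster_mean_distance(d, schema, target,
                                             clusters = clusters),
    betweenness = bw,
    top_nodes = top,
    target = target,
    n_nodes = length(network$nodes),
    n_edges = nrow(network$edges)), class = "net_stats")
}

#' @export
print.net_stats <- function(x, ...) {
  cat(sprintf("Network statistics (target: %s)\n", x$target))
  cat(sprintf("  denseness: %.1f%% (%d nodes, %d edges)\n",
              x$denseness, x$n_nodes, x$n_edges))
  if (nrow(x$top_nodes)) {
    cat("  top betweenness:",
        paste(sprintf("%s (%.3f)", x$top_nodes$node, x$top_nodes$value),
              collapse = ", "), "\n")
  } else cat("  top betweenness: none (empty or trivial subgraph)\n")
  cd <- x$cluster_distance
  cat("  cluster mean distance to target:\n")
  for (cl in names(cd))
    cat(sprintf("    %-22s %s\n", cl,
                if (is.na(cd[[cl]])) "N.A." else sprintf("%.2f", cd[[cl]])))
  invisible(x)
}
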