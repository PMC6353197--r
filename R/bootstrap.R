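## Bootstrap resampling, repeated structure learning and edge-stability
## model averaging.

#' Bootstrap edge-stability estimation
#'
#' Resamples the dataset with replacement `replicates` times, learns a
#' network per replicate, and reports for every unordered node pair the
#' fraction of replicates in which the pair was connected (in either
#' orientation). Each replicate's resample is drawn from its own seed
#' substream of the master seed, so results do not depend on execution
#' order.
#'
#' @param data a complete, non-empty `cat_data` dataset (or data frame
#'   of factors).
#' @param replicates number of bootstrap replicates (>= 1); the survey
#'   analysis default is 1000.
#' @param seed master integer seed.
#' @param alpha,max_sepset,score,max_iter learner configuration passed
#'   to [learn_structure()].
#' @return An `edge_strength` data frame with columns `from`, `to`,
#'   `strength` (one row per pair seen at least once), plus attributes
#'   `replicates`, `nodes` and the integer occurrence `counts`.
#' @export
bootstrap_networks <- function(data, replicates = 1000L, seed = 1L,
                               alpha = 0.05, max_sepset = 2L,
                               score = "bic", max_iter = 500L) {
  stopifnot(replicates >= 1)
  if (nrow(data) == 0) stop("empty dataset")
  n <- nrow(data)
  counts <- new.env(parent = emptyenv())
  sub_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max, replicates))
  nodes <- NULL
  for (r in seq_len(replicates)) {
    idx <- with_seed(sub_seeds[r], sample.int(n, n, replace = TRUE))
    boot <- data[idx, , drop = FALSE]
    if (inherits(data, "cat_data"))
      boot <- new_cat_data(boot, attr(data, "schema"))
    dag <- learn_structure(boot, alpha = alpha, max_sepset = max_sepset,
                           score = score, max_iter = max_iter)
    if (is.null(nodes)) nodes <- dag$nodes
    und <- to_undirected(dag)
    if (nrow(und)) {
      keys <- edge_key(und[, 1], und[, 2])
      for (k in keys)
        counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- sort(ls(counts))
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  pairs <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(
    from = if (length(keys)) pairs[, 1] else character(0),
    to = if (length(keys)) pairs[, 2] else character(0),
    strength = if (length(keys)) unname(cnt) / replicates else numeric(0),
    stringsAsFactors = FALSE)
  structure(out, replicates = as.integer(replicates), nodes = nodes,
            counts = unname(cnt), seed = as.integer(seed),
            class = c("edge_strength", "data.frame"))
}

#' Threshold an edge-strength table into an averaged network
#'
#' Keeps the pairs whose bootstrap stability is at least `threshold`
#' (40% in the survey analysis) and labels each kept edge `strong`
#' (stability >= `strong`, i.e. found in 70-100% of replicates) or
#' `weak` (40-70%). The result is undirected.
#'
#' @param strengths an `edge_strength` table from
#'   [bootstrap_networks()].
#' @param threshold inclusion threshold in (0, 1].
#' @param strong strong/weak class boundary.
#' @return An `avg_network`: list with `nodes` and an `edges` data frame
#'   (`from`, `to`, `strength`, `class`).
#' @export
average_network <- function(strengths, threshold = 0.40, strong = 0.70) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- strengths$strength >= threshold
  edges <- strengths[keep, c("from", "to", "strength"), drop = FALSE]
  edges$class <- ifelse(edges$strength >= strong, "strong", "weak")
  rownames(edges) <- NULL
  nodes <- attr(strengths, "nodes")
  if (is.null(nodes)) nodes <- sort(unique(c(strengths$from, strengths$to)))
  structure(list(nodes = nodes, edges = edges,
                 threshold = threshold, strong = strong),
            class = "avg_network")
}

#' @export
print.avg_network <- function(x, ...) {
  cat("Averaged network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (", sum(x$edges$class == "strong"), "strong /",
      sum(x$edges$class == "weak"), "weak ), threshold",
      x$threshold, "\n")
  invisible(x)
}

## igraph view of an averaged network (edge attrs strength/class kept)
as_igraph_avg <- function(net, schema = NULL) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges))
    g <- igraph::add_edges(
      g, as.vector(t(as.matrix(net$edges[, c("from", "to")]))),
      strength = net$edges$strength, class = net$edges$class)
  if (!is.null(schema)) {
    i <- match(net$nodes, schema$name)
    igraph::V(g)$cluster <- schema$cluster[i]
  }
  g
}
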