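## Report and graph export: GraphML, DOT, CSV, JSON manifest.

#' Write an averaged network as GraphML
#'
#' Node attribute `cluster` (SOS cluster), edge attributes `strength`
#' and `class`; re-importing with igraph reproduces the node and edge
#' sets.
#'
#' @param network an `avg_network`.
#' @param path output file path.
#' @param schema optional [sos_schema()] for the cluster attribute.
#' @export
write_graphml <- function(network, path, schema = NULL) {
  g <- as_igraph_avg(network, schema)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read an averaged network back from GraphML
#' @param path GraphML file.
#' @return An `avg_network`.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g)
  edges <- data.frame(
    from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]),
    strength = if (igraph::ecount(g)) igraph::E(g)$strength else numeric(0),
    class = if (igraph::ecount(g)) igraph::E(g)$class else character(0),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = igraph::V(g)$name, edges = edges,
                 threshold = NA_real_, strong = NA_real_),
            class = "avg_network")
}

cluster_palette <- function() {
  c(psychology_behaviour = "#e41a1c", institutional_home = "#377eb8",
    physical_health = "#4daf4a", built_natural = "#984ea3",
    social_cultural = "#ff7f00", politics_economics = "#a65628",
    demographic = "#999999")
}

#' Write an averaged network as Graphviz DOT
#'
#' Nodes are coloured by SOS cluster; edge width encodes the stability
#' class (strong edges drawn wider than weak ones).
#'
#' @inheritParams write_graphml
#' @export
write_dot <- function(network, path, schema = NULL) {
  pal <- cluster_palette()
  lines <- c("graph sosbn {",
             "  node [style=filled, fontname=\"Helvetica\"];")
  for (v in network$nodes) {
    col <- "#cccccc"
    if (!is.null(schema) && v %in% schema$name)
      col <- pal[[schema$cluster[match(v, schema$name)]]]
    lines <- c(lines, sprintf("  \"%s\" [fillcolor=\"%s\"];", v, col))
  }
  if (nrow(network$edges))
    for (r in seq_len(nrow(network$edges))) {
      e <- network$edges[r, ]
      lines <- c(lines, sprintf(
        "  \"%s\" -- \"%s\" [penwidth=%s, label=\"%.2f\"];",
        e$from, e$to, if (e$class == "strong") "3" else "1", e$strength))
    }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write an edge-strength table as CSV
#' @param strengths an `edge_strength` or `avg_network` edge table.
#' @param path output path.
#' @export
write_strengths_csv <- function(strengths, path) {
  df <- if (inherits(strengths, "avg_network")) strengths$edges
        else as.data.frame(strengths)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export all reports of an analysis run
#'
#' Per stratum: GraphML and DOT graphs and an edge CSV; plus the
#' Table-1-shaped summary CSV (`table1.csv`, with literal "N.A."
#' entries) and the JSON run manifest. Outputs are byte-identical for
#' identical runs.
#'
#' @param run an `sos_run`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
export_reports <- function(run, dir) {
  stopifnot(inherits(run, "sos_run"))
  if (!length(run$results)) stop("run has no results to export")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0)
    stop("cannot write to output directory: ", dir)
  paths <- character(0)
  for (nm in names(run$results)) {
    r <- run$results[[nm]]
    sch <- run$schema
    p1 <- file.path(dir, paste0("network_", nm, ".graphml"))
    p2 <- file.path(dir, paste0("network_", nm, ".dot"))
    p3 <- file.path(dir, paste0("edges_", nm, ".csv"))
    write_graphml(r$network, p1, sch)
    write_dot(r$network, p2, sch)
    write_strengths_csv(r$network, p3)
    paths <- c(paths, p1, p2, p3)
  }
  p4 <- file.path(dir, "table1.csv")
  utils::write.csv(table1(run), p4, row.names = FALSE)
  p5 <- file.path(dir, "manifest.json")
  jsonlite::write_json(run$manifest, p5, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, p4, p5))
}
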