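## Minimal directed-acyclic-graph container used by the learner.

#' Directed acyclic graph over named variables
#'
#' @param nodes character vector of node names.
#' @param arcs 2-column character matrix (from, to); checked for
#'   self-loops, duplicates and cycles.
#' @return A `bn_dag` object.
#' @export
bn_dag <- function(nodes, arcs = matrix(character(0), 0, 2)) {
  arcs <- as.matrix(arcs)
  if (length(arcs) == 0) arcs <- matrix(character(0), 0, 2)
  colnames(arcs) <- c("from", "to")
  bad <- setdiff(c(arcs), nodes)
  if (length(bad)) stop("arcs reference unknown nodes: ",
                        paste(unique(bad), collapse = ", "))
  if (any(arcs[, 1] == arcs[, 2])) stop("self-loops are not allowed")
  check_acyclic_arcs(nodes, arcs)
  structure(list(nodes = nodes, arcs = arcs), class = "bn_dag")
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("DAG:", length(x$nodes), "nodes,", nrow(x$arcs), "arcs\n")
  if (nrow(x$arcs))
    cat(paste0("  ", x$arcs[, 1], " -> ", x$arcs[, 2], collapse = "\n"),
        "\n")
  invisible(x)
}

## parent list representation used internally by the search
arcs_to_parents <- function(nodes, arcs) {
  out <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) out[[v]] <- unname(arcs[arcs[, 2] == v, 1])
  out
}

parents_to_arcs <- function(parents) {
  from <- unlist(parents, use.names = FALSE)
  to <- rep(names(parents), lengths(parents))
  cbind(from = from, to = to)
}

## is there a directed path from `from` to `to`? (children adjacency)
has_path <- function(children, from, to) {
  if (from == to) return(TRUE)
  stack <- from
  seen <- character(0)
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    kids <- children[[v]]
    if (to %in% kids) return(TRUE)
    stack <- c(stack, kids)
  }
  FALSE
}

#' Drop arc directions
#'
#' @param graph a `bn_dag` (or 2-column arc matrix).
#' @return 2-column character matrix of unordered edges, each pair
#'   sorted and deduplicated.
#' @export
to_undirected <- function(graph) {
  arcs <- if (inherits(graph, "bn_dag")) graph$arcs else as.matrix(graph)
  if (nrow(arcs) == 0)
    return(matrix(character(0), 0, 2,
                  dimnames = list(NULL, c("from", "to"))))
  a <- unname(pmin(arcs[, 1], arcs[, 2]))
  b <- unname(pmax(arcs[, 1], arcs[, 2]))
  key <- paste(a, b)
  keep <- !duplicated(key)
  ord <- order(a[keep], b[keep])
  matrix(c(a[keep][ord], b[keep][ord]), ncol = 2,
         dimnames = list(NULL, c("from", "to")))
}

## undirected edge key helper
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
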