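## Decomposable BIC scoring of discrete networks.

## local BIC of one node given a parent set, on an encoded dataset
local_bic <- function(enc, node, parents) {
  local_bic_cpp(enc$mat, enc$card,
                match(node, enc$vars),
                match(parents, enc$vars))
}

#' BIC score of a directed network
#'
#' Sum over nodes of the multinomial log-likelihood given the node's
#' parents minus `log(n)/2` times the number of free parameters
#' (`(k_v - 1) * prod(k_parents)`, counting the full cross-product of
#' parent levels). The per-node decomposition is attached as attribute
#' `"by_node"`.
#'
#' @param data a complete `cat_data` dataset (or data frame of factors).
#' @param graph a `bn_dag` whose nodes are data variables.
#' @return Numeric score (higher is better) with attribute `by_node`.
#' @export
bic_score <- function(data, graph) {
  stopifnot(inherits(graph, "bn_dag"))
  enc <- encode_data(data)
  miss <- setdiff(graph$nodes, enc$vars)
  if (length(miss)) stop("graph nodes not in data: ",
                         paste(miss, collapse = ", "))
  check_acyclic_arcs(graph$nodes, graph$arcs)
  parents <- arcs_to_parents(graph$nodes, graph$arcs)
  by_node <- vapply(graph$nodes, function(v)
    local_bic(enc, v, parents[[v]]), numeric(1))
  structure(sum(by_node), by_node = by_node)
}
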