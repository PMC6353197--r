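## Hybrid structure learning: PC-stable skeleton (restrict phase) and
## BIC hill climbing within the skeleton (maximize phase).

#' Learn an undirected skeleton by conditional-independence testing
#'
#' PC-stable: starting from the complete graph, for conditioning-set
#' sizes `0..max_sepset` each still-present edge x-y is removed as soon
#' as some subset of the current neighbours of x or of y (neighbour sets
#' frozen per size level, which makes the output independent of the
#' variable ordering) renders x and y independent at level `alpha`.
#' Uninformative tests (zero degrees of freedom) never remove an edge.
#'
#' @param data a complete `cat_data` dataset (or data frame of factors).
#' @param alpha significance level in (0, 1) for the G-squared test.
#' @param max_sepset largest conditioning-set size considered.
#' @return A `bn_skeleton`: list with `nodes` and 2-column `edges`.
#' @export
learn_skeleton <- function(data, alpha = 0.05, max_sepset = 2L) {
  stopifnot(alpha > 0, alpha < 1, max_sepset >= 0)
  if (nrow(data) == 0) stop("empty dataset")
  enc <- encode_data(data)
  vars <- sort(enc$vars)
  p <- length(vars)
  if (p < 2)
    return(structure(list(nodes = vars,
                          edges = matrix(character(0), 0, 2)),
                     class = "bn_skeleton"))
  mat <- enc$mat[, vars, drop = FALSE]
  cards <- enc$card[vars]
  ## adjacency as sorted integer index sets (index into `vars`)
  adj <- lapply(seq_len(p), function(i) setdiff(seq_len(p), i))
  for (l in 0:max_sepset) {
    snapshot <- adj
    if (!any(lengths(snapshot) >= l + 1)) break
    for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
      if (!(j %in% adj[[i]])) next
      nx <- setdiff(snapshot[[i]], j)
      ny <- setdiff(snapshot[[j]], i)
      if (l > 0 && length(nx) < l && length(ny) < l) next
      hit <- g2_sepset_level_cpp(mat, cards, i, j, nx, ny, l, alpha)
      if (hit > 0) {
        adj[[i]] <- setdiff(adj[[i]], j)
        adj[[j]] <- setdiff(adj[[j]], i)
      }
    }
  }
  adj <- stats::setNames(lapply(adj, function(ix) vars[ix]), vars)
  edges <- do.call(rbind, lapply(vars, function(x) {
    nb <- adj[[x]][adj[[x]] > x]
    if (length(nb)) cbind(from = x, to = nb)
  }))
  if (is.null(edges)) edges <- matrix(character(0), 0, 2,
                                      dimnames = list(NULL,
                                                      c("from", "to")))
  structure(list(nodes = vars, edges = edges), class = "bn_skeleton")
}

#' @export
print.bn_skeleton <- function(x, ...) {
  cat("Skeleton:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Greedy hill-climbing search within a skeleton
#'
#' Single-arc additions, deletions and reversals; additions are allowed
#' only between skeleton-adjacent pairs. Candidate moves are scanned in
#' lexicographic (source, target, move-type) order and the first move
#' that strictly increases the score is accepted, so the search is fully
#' deterministic; the trace of accepted scores is strictly increasing by
#' construction. Acyclicity is enforced on every accepted move.
#'
#' @param data a complete `cat_data` dataset (or data frame of factors).
#' @param restrict optional `bn_skeleton`; `NULL` allows all pairs.
#' @param score scoring criterion; currently `"bic"`.
#' @param max_iter maximum number of accepted moves; exhausting it
#'   returns the current graph with a warning.
#' @param seed unused (the search has no random component); kept so
#'   callers can treat all learners uniformly.
#' @return A `bn_dag` with attributes `score` and `score_trace`.
#' @export
hill_climb <- function(data, restrict = NULL, score = "bic",
                       max_iter = 500L, seed = NULL) {
  score <- match.arg(score, "bic")
  enc <- encode_data(data, vars = if (!is.null(restrict)) restrict$nodes)
  vars <- sort(enc$vars)
  p <- length(vars)
  allowed <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  if (is.null(restrict)) {
    allowed[] <- TRUE; diag(allowed) <- FALSE
  } else if (nrow(restrict$edges)) {
    for (r in seq_len(nrow(restrict$edges))) {
      a <- restrict$edges[r, 1]; b <- restrict$edges[r, 2]
      allowed[a, b] <- TRUE; allowed[b, a] <- TRUE
    }
  }
  ## integer-indexed state (index into sorted `vars`); parent-set cache
  ## keys are order-free bitmasks (exact for p <= 53)
  mat <- enc$mat[, vars, drop = FALSE]
  cards <- enc$card[vars]
  parents <- rep(list(integer(0)), p)
  children <- rep(list(integer(0)), p)
  pw <- 2^(seq_len(p) - 1)
  cache <- new.env(parent = emptyenv())
  local_score <- function(v, pars) {
    key <- paste0(v, "_", sum(pw[pars]))
    got <- cache[[key]]
    if (is.null(got)) {
      got <- local_bic_cpp(mat, cards, v, pars)
      cache[[key]] <- got
    }
    got
  }
  ipath <- function(kids, from, to) {
    stack <- from; seen <- logical(p)
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      ch <- kids[[v]]
      if (to %in% ch) return(TRUE)
      stack <- c(stack, ch)
    }
    FALSE
  }
  cur <- vapply(seq_len(p), function(v) local_score(v, integer(0)),
                numeric(1))
  eps <- 1e-8
  trace <- sum(cur)
  iter <- 0L
  pair_idx <- which(allowed, arr.ind = TRUE, useNames = FALSE)
  add_a <- pair_idx[, 1]; add_b <- pair_idx[, 2]
  improved <- FALSE
  repeat {
    ## moves in lexicographic (source, target, type) order (vars are
    ## sorted, so index order is name order; add < delete < reverse);
    ## first strictly improving valid move is accepted
    arc_b <- rep.int(seq_len(p), lengths(parents))
    arc_a <- unlist(parents, use.names = FALSE)
    mv_a <- c(add_a, arc_a, arc_a)
    mv_b <- c(add_b, arc_b, arc_b)
    mv_t <- c(rep.int(0L, length(add_a)),
              rep.int(1L, length(arc_a)), rep.int(2L, length(arc_a)))
    if (!length(mv_a)) break
    ord <- order(mv_a * (3L * (p + 1L)) + mv_b * 3L + mv_t)
    improved <- FALSE
    for (r in ord) {
      a <- mv_a[r]; b <- mv_b[r]; type <- mv_t[r]
      if (type == 0L) {
        if (b %in% children[[a]] || a %in% children[[b]]) next
        delta <- local_score(b, c(parents[[b]], a)) - cur[[b]]
        if (delta <= eps) next
        if (ipath(children, b, a)) next  # would create a cycle
        parents[[b]] <- c(parents[[b]], a)
        children[[a]] <- c(children[[a]], b)
        cur[[b]] <- cur[[b]] + delta
      } else if (type == 1L) {
        delta <- local_score(b, setdiff(parents[[b]], a)) - cur[[b]]
        if (delta <= eps) next
        parents[[b]] <- setdiff(parents[[b]], a)
        children[[a]] <- setdiff(children[[a]], b)
        cur[[b]] <- cur[[b]] + delta
      } else {
        d_b <- local_score(b, setdiff(parents[[b]], a)) - cur[[b]]
        d_a <- local_score(a, c(parents[[a]], b)) - cur[[a]]
        delta <- d_b + d_a
        if (delta <= eps) next
        kids2 <- children
        kids2[[a]] <- setdiff(kids2[[a]], b)
        if (ipath(kids2, a, b)) next  # cycle via another route
        parents[[b]] <- setdiff(parents[[b]], a)
        parents[[a]] <- c(parents[[a]], b)
        children[[a]] <- setdiff(children[[a]], b)
        children[[b]] <- c(children[[b]], a)
        cur[[b]] <- cur[[b]] + d_b
        cur[[a]] <- cur[[a]] + d_a
      }
      improved <- TRUE
      iter <- iter + 1L
      trace <- c(trace, sum(cur))
      break
    }
    if (!improved) break
    if (iter >= max_iter) {
      warning("hill_climb: max_iter (", max_iter,
              ") exhausted before convergence")
      break
    }
  }
  arc_b <- rep.int(seq_len(p), lengths(parents))
  arc_a <- unlist(parents, use.names = FALSE)
  dag <- bn_dag(vars, cbind(from = vars[arc_a], to = vars[arc_b]))
  attr(dag, "score") <- sum(cur)
  attr(dag, "score_trace") <- trace
  attr(dag, "converged") <- !improved || iter < max_iter
  dag
}

#' Hybrid structure learning (restrict then maximize)
#'
#' Learns the skeleton with [learn_skeleton()] and then hill-climbs a
#' DAG within it with [hill_climb()]. With fewer than two variables the
#' empty graph is returned.
#'
#' @inheritParams learn_skeleton
#' @inheritParams hill_climb
#' @return A `bn_dag`.
#' @export
learn_structure <- function(data, alpha = 0.05, max_sepset = 2L,
                            score = "bic", max_iter = 500L) {
  enc_vars <- if (inherits(data, "cat_data"))
    intersect(attr(data, "schema")$name, names(data))
  else names(data)[vapply(data, is.factor, logical(1))]
  if (length(enc_vars) < 2)
    return(bn_dag(sort(enc_vars)))
  skel <- learn_skeleton(data, alpha = alpha, max_sepset = max_sepset)
  hill_climb(data, restrict = skel, score = score, max_iter = max_iter)
}

#' Structural Hamming distance between undirected skeletons
#'
#' Number of edges present in exactly one of the two skeletons
#' (direction-blind).
#'
#' @param g1,g2 `bn_dag`, `bn_skeleton` or 2-column edge matrices.
#' @return Integer count of disagreeing edges.
#' @export
shd_skeleton <- function(g1, g2) {
  as_edges <- function(g) {
    if (inherits(g, "bn_skeleton")) g$edges
    else to_undirected(g)
  }
  e1 <- as_edges(g1); e2 <- as_edges(g2)
  k1 <- if (nrow(e1)) edge_key(e1[, 1], e1[, 2]) else character(0)
  k2 <- if (nrow(e2)) edge_key(e2[, 1], e2[, 2]) else character(0)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}
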