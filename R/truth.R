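## Ground-truth models and ancestral sampling for synthetic survey data.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Build a ground-truth Bayesian network over a schema
#'
#' Constructs a directed acyclic model with one conditional probability
#' table (CPT) per variable, used to simulate categorical survey data
#' with a known dependence structure. Edges are either user-supplied or
#' drawn at random at a given density; CPT rows are sampled from a
#' Dirichlet distribution with concentration `1/effect_strength`, so
#' larger `effect_strength` gives sharper rows and more detectable
#' parent-child dependence.
#'
#' Macro-scope variables (regional) may only have macro-scope parents,
#' because their values are drawn once per region.
#'
#' @param seed integer seed; the model is deterministic given the seed.
#' @param schema an [sos_schema()] (or subset).
#' @param edges optional 2-column character matrix (from, to) of arcs; a
#'   cyclic edge list is rejected with a diagnostic naming a cycle.
#' @param edge_density probability in (0, 1] of including each admissible
#'   arc when `edges` is NULL.
#' @param effect_strength positive dial for dependence detectability;
#'   CPT rows ~ Dirichlet(1/effect_strength).
#' @param n_regions number of simulated macro regions.
#' @return A `ground_truth` object: schema, arcs, CPTs, n_regions.
#' @seealso [default_ground_truth()], [sample_dataset()]
#' @export
build_ground_truth <- function(seed, schema = sos_schema(), edges = NULL,
                               edge_density = 0.08, effect_strength = 2,
                               n_regions = 24L) {
  validate_schema(schema)
  stopifnot(edge_density > 0, edge_density <= 1, effect_strength > 0,
            n_regions >= 1)
  nodes <- schema$name
  macro <- schema$name[schema$scope == "macro"]
  with_seed(seed, {
    if (is.null(edges)) {
      ## macro nodes first in the topological order so micro -> macro
      ## arcs (which would break region constancy) cannot arise
      ord <- c(sample(macro), sample(setdiff(nodes, macro)))
      arcs <- matrix(character(0), 0, 2)
      p <- length(ord)
      demo <- intersect(c("sex", "age_group"), nodes)
      for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
        ## demographics are exogenous roots; macro nodes cannot have
        ## micro parents
        if (ord[j] %in% demo) next
        if (ord[i] %in% macro || !(ord[j] %in% macro)) {
          if (stats::runif(1) < edge_density)
            arcs <- rbind(arcs, c(ord[i], ord[j]))
        }
      }
      ## SB must participate in the system
      if ("sitting" %in% nodes && !any(arcs == "sitting")) {
        other <- sample(setdiff(nodes, c("sitting", macro)), 1L)
        arcs <- rbind(arcs, c(other, "sitting"))
      }
    } else {
      arcs <- as.matrix(edges)
      colnames(arcs) <- NULL
      bad <- setdiff(c(arcs), nodes)
      if (length(bad)) stop("edge list names unknown variables: ",
                            paste(unique(bad), collapse = ", "))
      if (any(arcs[, 1] == arcs[, 2])) stop("self-loops are not allowed")
      mic_to_mac <- arcs[, 2] %in% macro & !(arcs[, 1] %in% macro)
      if (any(mic_to_mac))
        stop("macro variables may only have macro parents: ",
             paste(arcs[mic_to_mac, 2], collapse = ", "))
    }
    check_acyclic_arcs(nodes, arcs)
    card <- schema_cardinalities(schema)
    parents <- lapply(nodes, function(v) arcs[arcs[, 2] == v, 1])
    names(parents) <- nodes
    alpha <- 1 / effect_strength
    cpts <- lapply(nodes, function(v) {
      k <- card[[v]]
      nconf <- prod(card[parents[[v]]])
      g <- matrix(stats::rgamma(nconf * k, shape = alpha), nrow = nconf)
      ## guard against underflow to an all-zero row
      g[rowSums(g) < 1e-300, ] <- 1
      cpt <- g / rowSums(g)
      colnames(cpt) <- schema_levels(schema, v)
      attr(cpt, "parents") <- as.character(parents[[v]])
      cpt
    })
    names(cpts) <- nodes
    ## exogenous demographics get the survey's stratum shares (sex
    ## split and four age bands) instead of random marginals
    demo_marginals <- list(
      sex = c(0.524, 0.476),
      age_group = c(0.099, 0.298, 0.365, 0.238))
    for (v in intersect(names(demo_marginals), nodes)) {
      if (length(attr(cpts[[v]], "parents")) == 0 &&
          ncol(cpts[[v]]) == length(demo_marginals[[v]])) {
        cpts[[v]][1, ] <- demo_marginals[[v]]
      }
    }
    structure(list(schema = schema, arcs = arcs, cpts = cpts,
                   n_regions = as.integer(n_regions),
                   effect_strength = effect_strength, seed = as.integer(seed)),
              class = "ground_truth")
  })
}

## topological sort; errors with an explicit cycle if not a DAG
topo_sort_arcs <- function(nodes, arcs) {
  if (nrow(arcs) == 0) return(nodes)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(factor(arcs[, 2], levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- sort(nodes[indeg == 0])
  work <- arcs
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    out <- c(out, v)
    hit <- work[, 1] == v
    for (w in work[hit, 2]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
    work <- work[!hit, , drop = FALSE]
  }
  if (length(out) < length(nodes)) {
    rem <- setdiff(nodes, out)
    cyc <- find_cycle(rem, arcs)
    stop("edge list is cyclic: ", paste(cyc, collapse = " -> "))
  }
  out
}

find_cycle <- function(nodes, arcs) {
  ## walk forward from any remaining node until a repeat
  v <- nodes[1]; seen <- character(0)
  while (!(v %in% seen)) {
    seen <- c(seen, v)
    nxt <- arcs[arcs[, 1] == v & arcs[, 2] %in% nodes, 2]
    if (!length(nxt)) return(seen)
    v <- nxt[1]
  }
  c(seen[which(seen == v):length(seen)], v)
}

check_acyclic_arcs <- function(nodes, arcs) {
  if (anyDuplicated(paste(arcs[, 1], arcs[, 2])))
    stop("duplicate arcs in edge list")
  invisible(topo_sort_arcs(nodes, arcs))
}

#' Default 10-node test model
#'
#' A hand-specified ground truth with 12 arcs mimicking, qualitatively,
#' the structure reported for the survey data: occupation and regional
#' wealth feed sitting time, region drives GDP and urbanity, urbanity and
#' municipal support drive perceived facilities, and the
#' education/social-class/wealth chain feeds occupation.
#'
#' @param seed integer seed for the CPT draw.
#' @param effect_strength,n_regions passed to [build_ground_truth()].
#' @return A `ground_truth` object with 10 nodes and 12 arcs.
#' @export
default_ground_truth <- function(seed = 1L, effect_strength = 2,
                                 n_regions = 12L) {
  sch <- sos_schema(include = c("region", "gdp", "education", "municipality",
                                "urbanity", "social_class", "occupation",
                                "wealth", "facility", "sitting"))
  edges <- rbind(
    c("region", "gdp"),
    c("region", "urbanity"),
    c("education", "social_class"),
    c("education", "occupation"),
    c("social_class", "occupation"),
    c("social_class", "wealth"),
    c("gdp", "wealth"),
    c("urbanity", "facility"),
    c("municipality", "facility"),
    c("occupation", "sitting"),
    c("gdp", "sitting"),
    c("urbanity", "sitting"))
  build_ground_truth(seed, schema = sch, edges = edges,
                     effect_strength = effect_strength,
                     n_regions = n_regions)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth Bayesian network:", nrow(x$schema), "nodes,",
      nrow(x$arcs), "arcs,", x$n_regions, "regions\n")
  invisible(x)
}

#' Sample a categorical dataset from a ground-truth model
#'
#' Ancestral sampling in topological order. Macro-scope variables are
#' drawn once per region and copied to all members of the region; every
#' row is tagged with its `region_id`.
#'
#' @param model a `ground_truth` object.
#' @param n number of rows (>= 0).
#' @param seed integer seed.
#' @return A `cat_data` object: data frame of factors plus a `region_id`
#'   column, with the schema attached as attribute `schema`.
#' @export
sample_dataset <- function(model, n, seed) {
  stopifnot(inherits(model, "ground_truth"), n >= 0)
  n <- as.integer(n)
  schema <- model$schema
  nodes <- topo_sort_arcs(schema$name, model$arcs)
  card <- schema_cardinalities(schema)
  macro <- schema$name[schema$scope == "macro"]
  with_seed(seed, {
    region_id <- if (n > 0) sample.int(model$n_regions, n, replace = TRUE)
                 else integer(0)
    vals <- vector("list", length(nodes)); names(vals) <- nodes
    reg_vals <- vector("list", length(nodes)); names(reg_vals) <- nodes
    for (v in nodes) {
      cpt <- model$cpts[[v]]
      pars <- attr(cpt, "parents")
      if (v %in% macro) {
        conf <- config_index(reg_vals[pars], card[pars], model$n_regions)
        rv <- draw_categorical(cpt, conf, card[[v]])
        reg_vals[[v]] <- rv
        vals[[v]] <- rv[region_id]
      } else {
        src <- lapply(pars, function(p)
          if (p %in% macro) reg_vals[[p]][region_id] else vals[[p]])
        names(src) <- pars
        conf <- config_index(src, card[pars], n)
        vals[[v]] <- draw_categorical(cpt, conf, card[[v]])
      }
    }
    out <- as.data.frame(lapply(schema$name, function(v)
      factor(schema_levels(schema, v)[vals[[v]]],
             levels = schema_levels(schema, v))),
      col.names = schema$name, stringsAsFactors = FALSE)
    if (n == 0) {
      out <- as.data.frame(stats::setNames(
        lapply(schema$name, function(v)
          factor(character(0), levels = schema_levels(schema, v))),
        schema$name))
    }
    out$region_id <- region_id
    new_cat_data(out, schema)
  })
}

## mixed-radix index of parent configurations, first parent fastest
config_index <- function(value_list, cards, n) {
  if (!length(cards)) return(rep.int(1L, n))
  idx <- rep.int(1L, n)
  stride <- 1L
  for (j in seq_along(cards)) {
    idx <- idx + (value_list[[j]] - 1L) * stride
    stride <- stride * cards[[j]]
  }
  idx
}

## vector of category draws given a CPT (rows = parent configs)
draw_categorical <- function(cpt, conf, k) {
  n <- length(conf)
  if (n == 0) return(integer(0))
  cum <- t(apply(cpt, 1, cumsum))
  u <- stats::runif(n)
  ## count thresholds below u: gives 0..k-1
  out <- integer(n)
  for (j in seq_len(k - 1)) out <- out + (u > cum[conf, j])
  out + 1L
}

new_cat_data <- function(df, schema) {
  attr(df, "schema") <- schema
  class(df) <- c("cat_data", "data.frame")
  df
}

#' @export
print.cat_data <- function(x, ...) {
  sch <- attr(x, "schema")
  cat("Categorical dataset:", nrow(x), "rows,",
      nrow(sch), "schema variables",
      if ("region_id" %in% names(x)) "(+region_id)" else "", "\n")
  invisible(x)
}

#' Inject missing-at-random values
#'
#' Sets analysis cells to `NA` with a per-row probability that is a
#' logistic function of sex and age group only (both always observed and
#' never blanked), so the mechanism is missing-at-random by construction.
#' The overall expected missing-cell fraction equals `rate`. If the table
#' has no `sex`/`age_group` columns the fallback is uniform missingness
#' (MCAR), with a warning.
#'
#' @param table a `cat_data` dataset.
#' @param rate target missing-cell fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return The dataset with `NA`s injected.
#' @export
inject_missing <- function(table, rate, seed) {
  stopifnot(inherits(table, "cat_data"))
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("rate must be in [0, 1)")
  if (rate == 0 || nrow(table) == 0) return(table)
  schema <- attr(table, "schema")
  keep <- intersect(c("sex", "age_group"), names(table))
  target_vars <- setdiff(intersect(schema$name, names(table)), keep)
  with_seed(seed, {
    if (length(keep) == 2) {
      eta <- 0.5 * (as.integer(table$sex) - 1) +
        0.3 * (as.integer(table$age_group) - 1)
      w <- exp(eta) / mean(exp(eta))
      p_row <- pmin(rate * w, 0.95)
    } else {
      warning("no sex/age_group columns; using uniform (MCAR) missingness")
      p_row <- rep.int(rate, nrow(table))
    }
    for (v in target_vars) {
      hit <- stats::runif(nrow(table)) < p_row
      table[[v]][hit] <- NA
    }
    table
  })
}

#' Write / read a ground-truth model as JSON
#'
#' Nodes, arcs, region count and flattened CPT arrays round-trip through
#' a plain JSON document.
#'
#' @param model a `ground_truth` object.
#' @param path file path.
#' @return `read_ground_truth()` returns the reconstructed model.
#' @export
write_ground_truth <- function(model, path) {
  stopifnot(inherits(model, "ground_truth"))
  sch <- model$schema
  doc <- list(
    nodes = lapply(seq_len(nrow(sch)), function(i)
      list(name = sch$name[i], cluster = sch$cluster[i],
           scope = sch$scope[i], levels = sch$levels[[i]])),
    arcs = apply(model$arcs, 1, function(r) list(from = r[1], to = r[2])),
    n_regions = model$n_regions,
    cpts = lapply(model$cpts, function(cpt)
      list(parents = attr(cpt, "parents"),
           probs = as.vector(t(cpt))))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- doc$nodes
  sch <- make_schema(nodes$name, nodes$cluster,
                     if (is.list(nodes$levels)) nodes$levels
                     else as.list(nodes$levels),
                     nodes$scope)
  arcs <- if (length(doc$arcs)) cbind(doc$arcs$from, doc$arcs$to)
          else matrix(character(0), 0, 2)
  card <- schema_cardinalities(sch)
  cpts <- lapply(sch$name, function(v) {
    entry <- doc$cpts[[v]]
    pars <- as.character(unlist(entry$parents))
    k <- card[[v]]
    m <- matrix(entry$probs, ncol = k, byrow = TRUE)
    colnames(m) <- schema_levels(sch, v)
    attr(m, "parents") <- pars
    m
  })
  names(cpts) <- sch$name
  structure(list(schema = sch, arcs = arcs, cpts = cpts,
                 n_regions = as.integer(doc$n_regions),
                 effect_strength = NA_real_, seed = NA_integer_),
            class = "ground_truth")
}
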