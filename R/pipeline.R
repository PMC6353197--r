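## End-to-end orchestration: simulate or ingest, recode, stratify,
## learn, bootstrap, average, score.

#' Analysis run configuration
#'
#' @param seed master seed for the whole run.
#' @param replicates bootstrap replicates per stratum (survey default
#'   1000; tests use 50-100).
#' @param threshold edge-stability inclusion threshold.
#' @param strong strong/weak boundary.
#' @param alpha CI-test significance level.
#' @param max_sepset maximum conditioning-set size.
#' @param score network score.
#' @param max_iter hill-climbing move budget.
#' @param include_pa keep the physical-activity node (sensitivity
#'   analysis); by default PA is excluded from the learned networks.
#' @param exclude further variable names to drop; unknown names are a
#'   configuration error (checked at run time).
#' @param n rows to simulate when the input is a ground-truth model.
#' @param target the SB node name.
#' @param weighting betweenness weighting convention.
#' @param stratify learn per sex/age stratum in addition to the overall
#'   sample.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, replicates = 1000L, threshold = 0.40,
                       strong = 0.70, alpha = 0.05, max_sepset = 2L,
                       score = "bic", max_iter = 500L,
                       include_pa = FALSE, exclude = character(0),
                       n = 24000L, target = "sitting",
                       weighting = "inverse", stratify = TRUE) {
  stopifnot(threshold > 0, threshold <= 1, replicates >= 1)
  structure(list(seed = as.integer(seed),
                 replicates = as.integer(replicates),
                 threshold = threshold, strong = strong, alpha = alpha,
                 max_sepset = as.integer(max_sepset), score = score,
                 max_iter = as.integer(max_iter),
                 include_pa = isTRUE(include_pa), exclude = exclude,
                 n = as.integer(n), target = target,
                 weighting = weighting, stratify = isTRUE(stratify)),
            class = "run_config")
}

#' Analysis variable list with or without PA
#'
#' Drops the physical-activity node unless the sensitivity flag is set,
#' plus any further configured exclusions. Excluding a name that is not
#' a variable is a configuration error.
#'
#' @param vars character vector of variable names (or an `sos_schema`).
#' @param include_pa keep PA (sensitivity analysis).
#' @param exclude further names to drop.
#' @return Character vector of analysis variable names.
#' @export
exclude_pa <- function(vars, include_pa = FALSE,
                       exclude = character(0)) {
  if (inherits(vars, "sos_schema")) vars <- vars$name
  unknown <- setdiff(exclude, vars)
  if (length(unknown))
    stop("configuration error: cannot exclude unknown variable(s): ",
         paste(unknown, collapse = ", "))
  drop <- exclude
  if (!include_pa && "pa" %in% vars) drop <- c(drop, "pa")
  setdiff(vars, drop)
}

stratum_labels <- function() {
  bands <- c("15_25" = "young", "26_44" = "adult", "45_64" = "middle",
             "65plus" = "older")
  out <- character(0)
  for (b in names(bands)) for (s in c("female", "male"))
    out[paste0(bands[[b]], "_", s)] <- paste(b, s, sep = "|")
  out
}

#' Split a dataset into the overall sample and eight sex/age strata
#'
#' Returns the overall dataset (sex and age group retained as network
#' nodes) plus one dataset per sex x age-band stratum with the
#' stratification variables removed from the analysis columns. Empty
#' strata are skipped with a warning.
#'
#' @param data a `cat_data` dataset with `sex` and `age_group` columns.
#' @return Named list of `cat_data` (first element `"all"`).
#' @export
stratify <- function(data) {
  stopifnot(inherits(data, "cat_data"))
  if (!all(c("sex", "age_group") %in% names(data)))
    stop("stratification needs 'sex' and 'age_group' columns")
  schema <- attr(data, "schema")
  out <- list(all = data)
  labs <- stratum_labels()
  sub_schema <- schema[!schema$name %in% c("sex", "age_group"), ,
                       drop = FALSE]
  class(sub_schema) <- c("sos_schema", "data.frame")
  for (nm in names(labs)) {
    parts <- strsplit(labs[[nm]], "|", fixed = TRUE)[[1]]
    rows <- data$age_group == parts[1] & data$sex == parts[2]
    sub <- data[rows, setdiff(names(data), c("sex", "age_group")),
                drop = FALSE]
    if (nrow(sub) == 0) {
      warning("empty stratum skipped: ", nm)
      next
    }
    out[[nm]] <- new_cat_data(sub, sub_schema)
  }
  out
}

#' Run the full analysis
#'
#' Simulates (from a ground-truth model) or ingests (raw survey table
#' or categorical dataset) the data, applies the recodes if needed,
#' removes PA unless configured otherwise, complete-case filters,
#' stratifies, and per stratum runs the bootstrap learner, thresholds
#' the averaged network and computes the network statistics. A failing
#' stratum is logged and skipped; the others proceed.
#'
#' @param input a `ground_truth` model, a raw survey `data.frame`, or a
#'   `cat_data` dataset.
#' @param config a [run_config()].
#' @return An `sos_run` object: per-stratum results (`network`,
#'   `stats`, `strengths`, `n`) plus a manifest.
#' @export
run_full_analysis <- function(input, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- with_seed(config$seed,
    sample.int(.Machine$integer.max, 16L))
  if (inherits(input, "ground_truth")) {
    data <- sample_dataset(input, config$n, seed = seeds[1])
  } else if (inherits(input, "cat_data")) {
    data <- input
  } else if (is.data.frame(input)) {
    data <- apply_recodes(input)
  } else stop("input must be a ground_truth, cat_data or data.frame")
  schema <- attr(data, "schema")
  keep <- exclude_pa(schema, include_pa = config$include_pa,
                     exclude = config$exclude)
  schema2 <- schema_subset(schema, keep)
  data <- new_cat_data(
    data[, intersect(c(keep, "region_id"), names(data)), drop = FALSE],
    schema2)
  data <- suppressMessages(complete_case_filter(data))
  if (nrow(data) == 0) stop("empty stratum: no complete cases")
  strata <- if (config$stratify &&
                all(c("sex", "age_group") %in% names(data)))
    stratify(data) else list(all = data)
  results <- list()
  stratum_seeds <- stats::setNames(
    seeds[1 + seq_along(strata)], names(strata))
  for (nm in names(strata)) {
    d <- strata[[nm]]
    res <- tryCatch({
      st <- bootstrap_networks(
        d, replicates = config$replicates, seed = stratum_seeds[[nm]],
        alpha = config$alpha, max_sepset = config$max_sepset,
        score = config$score, max_iter = config$max_iter)
      net <- average_network(st, threshold = config$threshold,
                             strong = config$strong)
      stats_ <- withCallingHandlers(
        network_stats(net, attr(d, "schema"), target = config$target,
                      weighting = config$weighting),
        warning = function(w) invokeRestart("muffleWarning"))
      list(network = net, stats = stats_, strengths = st, n = nrow(d))
    }, error = function(e) {
      warning("stratum '", nm, "' failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) results[[nm]] <- res
  }
  manifest <- list(
    package = "sosbn",
    version = as.character(utils::packageVersion("sosbn")),
    seed = config$seed,
    stratum_seeds = as.list(stratum_seeds),
    config = unclass(config),
    n_total = nrow(data),
    stratum_n = lapply(results, `[[`, "n"),
    variables = keep)
  structure(list(results = results, manifest = manifest,
                 schema = schema2), class = "sos_run")
}

#' @export
print.sos_run <- function(x, ...) {
  cat("sosbn analysis run:", length(x$results), "strata\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %-14s n = %6d, edges = %3d, denseness = %5.1f%%\n",
                nm, r$n, nrow(r$network$edges), r$stats$denseness))
  }
  invisible(x)
}

#' Summary table of per-stratum network statistics
#'
#' One column per stratum: sample size, denseness, the top-2 nodes by
#' weighted betweenness, and the per-cluster mean distance to SB with
#' the literal "N.A." where no node of a cluster connects.
#'
#' @param run an `sos_run`.
#' @return A character data frame (statistics x strata).
#' @export
table1 <- function(run) {
  stopifnot(inherits(run, "sos_run"))
  fmt_top <- function(top, rank) {
    nodes <- top$node[top$rank == rank]
    if (!length(nodes)) "" else paste(nodes, collapse = " & ")
  }
  cols <- lapply(run$results, function(r) {
    cd <- r$stats$cluster_distance
    c(`Sample size` = as.character(r$n),
      `Highest weighted betweenness centrality` =
        fmt_top(r$stats$top_nodes, 1L),
      `2nd highest weighted betweenness centrality` =
        fmt_top(r$stats$top_nodes, 2L),
      `Network denseness` = sprintf("%.1f%%", r$stats$denseness),
      vapply(names(cd), function(cl)
        if (is.na(cd[[cl]])) "N.A." else sprintf("%.2f", cd[[cl]]),
        character(1)))
  })
  out <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  names(out) <- names(run$results)
  cbind(statistic = rownames(out), out, stringsAsFactors = FALSE,
        row.names = NULL)
}
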