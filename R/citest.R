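## Conditional-independence testing on categorical data.

## integer-encode the analysis columns of a cat_data (or plain factor
## data frame); returns matrix, cardinalities and names
encode_data <- function(data, vars = NULL) {
  if (inherits(data, "cat_data")) {
    schema <- attr(data, "schema")
    cols <- intersect(schema$name, names(data))
  } else {
    cols <- names(data)[vapply(data, is.factor, logical(1))]
  }
  if (!is.null(vars)) cols <- intersect(cols, vars)
  if (anyNA(data[cols]))
    stop("missing values present; apply complete_case_filter() first")
  mat <- vapply(cols, function(v) as.integer(data[[v]]),
                integer(nrow(data)))
  if (nrow(data) == 1L) mat <- matrix(mat, nrow = 1,
                                      dimnames = list(NULL, cols))
  card <- vapply(cols, function(v) nlevels(data[[v]]), integer(1))
  list(mat = mat, card = card, vars = cols, n = nrow(data))
}

z_config <- function(enc, z) {
  if (!length(z)) return(list(idx = rep.int(1L, enc$n), k = 1L))
  m <- enc$mat[, z, drop = FALSE]
  k <- as.integer(prod(enc$card[z]))
  list(idx = config_index_cpp(m, enc$card[z]), k = k)
}

#' Contingency counts for (x, y) within configurations of z
#'
#' @param data a complete `cat_data` dataset (or data frame of factors).
#' @param x,y variable names (distinct).
#' @param z character vector of conditioning variables (may be empty),
#'   excluding `x` and `y`.
#' @return Integer array of dimension `levels(x) x levels(y) x
#'   z-configurations`.
#' @export
contingency_counts <- function(data, x, y, z = character(0)) {
  if (x == y || x %in% z || y %in% z)
    stop("x, y and z must name distinct variables")
  enc <- encode_data(data)
  miss <- setdiff(c(x, y, z), enc$vars)
  if (length(miss)) stop("variable(s) not in data: ",
                         paste(miss, collapse = ", "))
  zc <- z_config(enc, z)
  counts <- joint_counts_cpp(enc$mat[, x], enc$card[[x]],
                             enc$mat[, y], enc$card[[y]],
                             zc$idx, zc$k)
  dim(counts) <- c(enc$card[[x]], enc$card[[y]], zc$k)
  dimnames(counts) <- list(levels(data[[x]]), levels(data[[y]]), NULL)
  counts
}

#' G-squared conditional-independence test
#'
#' Computes `G2 = 2 * sum O log(O/E)` within each configuration of the
#' conditioning set, with `E` the independence-expected counts, and
#' compares it against a chi-square reference. Degrees of freedom use
#' the standard sparse-table adjustment: per populated configuration,
#' `(observed x levels - 1)(observed y levels - 1)`; configurations
#' without data contribute nothing. A test with zero degrees of freedom
#' (e.g. a single observed level) is reported as uninformative
#' (`p = 1`).
#'
#' @inheritParams contingency_counts
#' @return A `ci_test` object: list with `statistic`, `df`, `p.value`,
#'   `n`, and the tested triple.
#' @export
g2_test <- function(data, x, y, z = character(0)) {
  if (x == y || x %in% z || y %in% z)
    stop("x, y and z must name distinct variables")
  enc <- encode_data(data)
  miss <- setdiff(c(x, y, z), enc$vars)
  if (length(miss)) stop("variable(s) not in data: ",
                         paste(miss, collapse = ", "))
  zc <- z_config(enc, z)
  res <- g2_stat_cpp(enc$mat[, x], enc$card[[x]],
                     enc$mat[, y], enc$card[[y]],
                     zc$idx, zc$k)
  g2_result(res[1], res[2], enc$n, x, y, z)
}

g2_result <- function(stat, df, n, x, y, z) {
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else 1
  structure(list(statistic = stat, df = df, p.value = p, n = n,
                 x = x, y = y, z = z,
                 informative = df > 0),
            class = "ci_test")
}

#' @export
print.ci_test <- function(x, ...) {
  cat(sprintf("G2 test: %s _||_ %s %s\n", x$x, x$y,
              if (length(x$z)) paste("|", paste(x$z, collapse = ", "))
              else ""))
  cat(sprintf("  G2 = %.4f, df = %d, p = %.4g%s\n", x$statistic,
              as.integer(x$df), x$p.value,
              if (!x$informative) " (uninformative)" else ""))
  invisible(x)
}
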