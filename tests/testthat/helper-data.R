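# Test-data builders: tiny categorical datasets and hand-specified
# ground-truth models assembled in code.

# wrap a data frame of factors as a cat_data with a generic schema
as_test_cat <- function(df, clusters = "psychology_behaviour",
                        scopes = "micro") {
  df[] <- lapply(df, function(x) if (is.factor(x)) x else factor(x))
  sch <- make_schema(names(df), clusters,
                     lapply(df, levels), scopes)
  sosbn:::new_cat_data(df, sch)
}

# dataset realising exact 2x2 counts [[a,b],[c,d]] for variables x, y
counts2x2_data <- function(a, b, c, d) {
  df <- data.frame(
    x = factor(c(rep("x1", a + b), rep("x2", c + d)),
               levels = c("x1", "x2")),
    y = factor(c(rep("y1", a), rep("y2", b), rep("y1", c), rep("y2", d)),
               levels = c("y1", "y2")))
  as_test_cat(df)
}

# 3-node chain model a -> b -> c with hand-set CPTs (all 2-level)
chain_model <- function() {
  sch <- make_schema(c("a", "b", "c"), "psychology_behaviour",
                     list(c("l1", "l2"), c("l1", "l2"), c("l1", "l2")))
  m <- build_ground_truth(1, schema = sch,
                          edges = rbind(c("a", "b"), c("b", "c")),
                          n_regions = 1)
  m$cpts$a[1, ] <- c(0.3, 0.7)
  m$cpts$b[, 1] <- c(0.8, 0.2); m$cpts$b[, 2] <- c(0.2, 0.8)
  m$cpts$c[, 1] <- c(0.9, 0.25); m$cpts$c[, 2] <- c(0.1, 0.75)
  m
}

# collider model a -> c <- b, a and b marginally independent
collider_model <- function() {
  sch <- make_schema(c("a", "b", "c"), "psychology_behaviour",
                     list(c("l1", "l2"), c("l1", "l2"), c("l1", "l2")))
  m <- build_ground_truth(1, schema = sch,
                          edges = rbind(c("a", "c"), c("b", "c")),
                          n_regions = 1)
  m$cpts$a[1, ] <- c(0.5, 0.5)
  m$cpts$b[1, ] <- c(0.5, 0.5)
  # c depends on both parents with clear marginal dependence on each
  # (faithful: no XOR-like cancellation)
  m$cpts$c[, 1] <- c(0.95, 0.5, 0.5, 0.05)
  m$cpts$c[, 2] <- 1 - m$cpts$c[, 1]
  m
}

# simulate x <- z -> y with independent noise; x _||_ y | z holds
simulate_common_cause <- function(n, seed, kz = 3) {
  set.seed(seed)
  z <- sample.int(kz, n, replace = TRUE)
  px <- c(0.2, 0.5, 0.8)[z]
  py <- c(0.7, 0.4, 0.1)[z]
  df <- data.frame(
    x = factor(ifelse(runif(n) < px, "x1", "x2")),
    y = factor(ifelse(runif(n) < py, "y1", "y2")),
    z = factor(paste0("z", z)))
  as_test_cat(df)
}
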