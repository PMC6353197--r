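test_that("ground-truth construction: determinism, CPTs, acyclicity", {
  m1 <- build_ground_truth(seed = 42)
  m2 <- build_ground_truth(seed = 42)
  expect_identical(m1$arcs, m2$arcs)
  expect_identical(m1$cpts, m2$cpts)
  m3 <- build_ground_truth(seed = 43)
  expect_false(identical(m1$cpts, m3$cpts))

  # every CPT row sums to 1 and covers the full parent cross-product
  card <- sosbn:::schema_cardinalities(m1$schema)
  for (v in m1$schema$name) {
    cpt <- m1$cpts[[v]]
    pars <- attr(cpt, "parents")
    expect_identical(nrow(cpt), as.integer(prod(card[pars])))
    expect_true(all(abs(rowSums(cpt) - 1) < 1e-12))
  }
  # SB participates in the system
  expect_true(any(m1$arcs == "sitting"))
})

test_that("default 10-node truth has exactly 12 arcs and is acyclic", {
  m <- default_ground_truth(seed = 1)
  expect_identical(nrow(m$arcs), 12L)
  expect_identical(nrow(m$schema), 10L)
  # topological sort succeeds (would error on a cycle)
  expect_silent(sosbn:::topo_sort_arcs(m$schema$name, m$arcs))
})

test_that("cyclic and invalid edge lists are rejected with diagnostics", {
  sch <- make_schema(c("a", "b", "c"), "psychology_behaviour",
                     list(c("1", "2"), c("1", "2"), c("1", "2")))
  cyc <- rbind(c("a", "b"), c("b", "c"), c("c", "a"))
  expect_error(build_ground_truth(1, sch, edges = cyc), "cyclic")
  # the diagnostic names a cycle
  expect_error(build_ground_truth(1, sch, edges = cyc), "a.*->")
  expect_error(build_ground_truth(1, sch,
                                  edges = rbind(c("a", "a"))),
               "self-loop")
  sch2 <- make_schema(c("mi", "ma"), "built_natural",
                      list(c("1", "2"), c("1", "2")),
                      scopes = c("micro", "macro"))
  expect_error(build_ground_truth(1, sch2,
                                  edges = rbind(c("mi", "ma"))),
               "macro")
})

test_that("ancestral sampling: empty case, marginals, determinism", {
  m <- chain_model()
  d0 <- sample_dataset(m, 0, seed = 1)
  expect_identical(nrow(d0), 0L)
  expect_setequal(names(d0), c("a", "b", "c", "region_id"))

  # root marginal within 3 binomial standard errors of its CPT
  n <- 50000
  d <- sample_dataset(m, n, seed = 7)
  p_hat <- mean(d$a == "l1")
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(p_hat - 0.3), 3 * se)

  expect_identical(sample_dataset(m, 100, seed = 3),
                   sample_dataset(m, 100, seed = 3))
})

test_that("joint sampling matches the chain CPTs (goodness of fit)", {
  m <- chain_model()
  d <- sample_dataset(m, 50000, seed = 11)
  # P(c | b) must match the c-CPT within Monte-Carlo error
  for (bl in c("l1", "l2")) {
    obs <- table(d$c[d$b == bl])
    expected_p <- m$cpts$c[match(bl, c("l1", "l2")), ]
    gof <- suppressWarnings(stats::chisq.test(obs, p = expected_p))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("macro variables are constant within regions", {
  m <- build_ground_truth(seed = 5, n_regions = 8)
  d <- sample_dataset(m, 2000, seed = 6)
  macro <- m$schema$name[m$schema$scope == "macro"]
  for (v in macro) {
    per_region <- tapply(as.integer(d[[v]]), d$region_id,
                         function(x) length(unique(x)))
    expect_true(all(per_region == 1L), label = v)
  }
})

test_that("inject_missing: identity, rate, MAR mechanism", {
  m <- build_ground_truth(seed = 5, n_regions = 6)
  d <- sample_dataset(m, 10000, seed = 6)
  expect_identical(inject_missing(d, 0, seed = 1), d)
  expect_error(inject_missing(d, 1.2, seed = 1), "rate")
  expect_error(inject_missing(d, -0.1, seed = 1), "rate")

  dm <- inject_missing(d, 0.05, seed = 2)
  # sex/age (the MAR drivers) are never blanked
  expect_false(anyNA(dm$sex)); expect_false(anyNA(dm$age_group))
  vars <- setdiff(attr(d, "schema")$name, c("sex", "age_group"))
  frac <- mean(is.na(as.matrix(dm[vars])))
  ncell <- nrow(d) * length(vars)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / ncell))
  # determinism
  expect_identical(inject_missing(d, 0.05, seed = 2), dm)
})

test_that("missingness is independent of an unobserved latent", {
  m <- build_ground_truth(seed = 5, n_regions = 6)
  rejections <- 0L
  for (s in 1:20) {
    d <- sample_dataset(m, 2000, seed = 100 + s)
    dm <- inject_missing(d, 0.1, seed = 200 + s)
    set.seed(300 + s)
    latent <- factor(sample(c("u1", "u2"), nrow(d), replace = TRUE))
    probe <- as_test_cat(data.frame(
      miss = factor(ifelse(is.na(dm$sitting), "yes", "no"),
                    levels = c("no", "yes")),
      latent = latent))
    res <- g2_test(probe, "miss", "latent")
    if (res$p.value < 0.01) rejections <- rejections + 1L
  }
  # Binomial(20, 0.01): observing 3+ rejections has probability ~0.1%
  expect_lte(rejections, 2L)
})

test_that("ground-truth JSON round trip", {
  m <- default_ground_truth(seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(m, path)
  m2 <- read_ground_truth(path)
  expect_identical(m2$schema$name, m$schema$name)
  expect_identical(m2$arcs, unname(m$arcs))
  for (v in m$schema$name) {
    expect_equal(unname(m2$cpts[[v]]), unname(m$cpts[[v]]),
                 tolerance = 1e-12)
    expect_identical(attr(m2$cpts[[v]], "parents"),
                     attr(m$cpts[[v]], "parents"))
  }
  d1 <- sample_dataset(m, 50, seed = 1)
  d2 <- sample_dataset(m2, 50, seed = 1)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
})
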