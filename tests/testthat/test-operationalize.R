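test_that("sitting time collapses to the four IPAQ bands", {
  # '1h or less' -> band 1; '4h31-5h30' -> band 3; top codes -> band 4
  expect_identical(derive_sitting(1), 1L)
  expect_identical(derive_sitting(6), 3L)
  expect_identical(derive_sitting(c(9, 10)), c(4L, 4L))
  expect_identical(derive_sitting(1:10),
                   c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L))
  expect_error(derive_sitting(11), "out of range")
  expect_error(derive_sitting(0), "out of range")
  expect_true(is.na(derive_sitting(NA)))
})

test_that("physical activity classes follow the printed rules", {
  expect_identical(derive_pa(0, 0), 0L)      # inactive
  expect_identical(derive_pa(100, 50), 1L)   # low active
  expect_identical(derive_pa(160, 0), 2L)    # sufficiently (MPA rule)
  expect_identical(derive_pa(0, 80), 2L)     # sufficiently (VPA rule)
  expect_identical(derive_pa(180, 90), 3L)   # highly active
  expect_error(derive_pa(-1, 0), "negative")

  # the four classes partition the whole (MPA, VPA) grid
  grid <- expand.grid(m = c(0, 1, 74, 75, 149, 150, 600),
                      v = c(0, 1, 74, 75, 149, 150, 300))
  cls <- derive_pa(grid$m, grid$v)
  expect_true(all(cls %in% 0:3))
  # rule consistency at every grid point
  expect_identical(cls == 3L, grid$m >= 150 & grid$v >= 75)
  expect_identical(cls == 0L, grid$m == 0 & grid$v == 0)
  expect_identical(cls == 2L,
                   (grid$m >= 150 | grid$v >= 75) &
                     !(grid$m >= 150 & grid$v >= 75))
})

test_that("netuse takes the maximum location frequency", {
  expect_identical(derive_netuse(0, 2, 0), 2L)
  expect_identical(derive_netuse(0, 0, 0), 0L)
  expect_identical(derive_netuse(1, 1, 1), 1L)
  expect_error(derive_netuse(3, 0, 0), "\\{0,1,2\\}")
})

test_that("education bands and still-studying handling", {
  expect_identical(derive_education(c(14, 15, 16, 17, 19, 20, 22)),
                   c(1L, 1L, 2L, 2L, 2L, 3L, 3L))
  # still studying: band from current age, else missing
  expect_identical(derive_education(0, current_age = 22), 3L)
  expect_identical(derive_education(0, current_age = 17), 2L)
  expect_true(is.na(derive_education(0)))
  expect_error(derive_education(-3), ">= 0")
})

test_that("climate bands use the printed cut points", {
  expect_identical(categorize_climate(16, 1)$temperature, 3L)   # hot
  expect_identical(categorize_climate(12, 1)$temperature, 2L)
  expect_identical(categorize_climate(9.9, 1)$temperature, 1L)  # cold
  # closed middle intervals
  expect_identical(categorize_climate(15, 1)$temperature, 2L)
  expect_identical(categorize_climate(10, 1)$temperature, 2L)
  expect_identical(categorize_climate(12, 0.1)$precipitation, 1L)
  expect_identical(categorize_climate(12, 3.0)$precipitation, 3L)
  expect_identical(categorize_climate(12, 0.2)$precipitation, 2L)
  expect_identical(categorize_climate(12, 2.0)$precipitation, 2L)
  expect_error(categorize_climate(Inf, 1), "non-finite")
})

test_that("household size sums the three counts, capped at 3+", {
  expect_identical(derive_household_size(0, 0, 0), 0L)
  expect_identical(derive_household_size(1, 0, 1), 2L)
  expect_identical(derive_household_size(2, 1, 2), 3L)
  expect_identical(derive_household_size(0, 0, 7), 3L)
})

test_that("EU migration is the nationality/residence mismatch", {
  expect_identical(derive_migration("FR", "DE"), 1L)
  expect_identical(derive_migration("FR", "FR"), 0L)
  expect_identical(derive_migration("PL", "IE"), 1L)
  expect_error(derive_migration("XX", "FR"), "unknown ISO")
  # lookup of WHO regions is total over the 28 member states
  expect_true(all(derive_who_region(eu_countries()) %in% 1:4))
})

test_that("tertile_split: exact thirds, ties, degenerate input", {
  expect_identical(tertile_split(1:9),
                   c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L))
  expect_error(tertile_split(rep(5, 10)), "distinct")
  expect_error(tertile_split(c(1, 2)), "distinct")
  # ties at a boundary go to the lower tertile; sizes off by <= ties
  for (s in 1:25) {
    set.seed(s)
    x <- sample(1:6, 30, replace = TRUE)  # many ties
    lv <- tertile_split(x)
    expect_identical(lv, oracle_tertiles(x))
    q1 <- stats::quantile(x, 1 / 3, names = FALSE)
    ties_at_q1 <- sum(x == max(x[x <= q1]))
    expect_lte(sum(lv == 1) - ceiling(length(x) / 3), ties_at_q1)
  }
})

test_that("above-average flag: strict inequality, ties below", {
  expect_identical(above_average_flag(5, 4), 1L)
  expect_identical(above_average_flag(4, 4), 0L)
  expect_identical(above_average_flag(c(1, 2, 3), 2), c(0L, 0L, 1L))
  expect_error(above_average_flag(1, Inf), "finite")
})

test_that("recode maps are total over every declared raw domain", {
  dom <- recode_domains()
  n <- 3 * max(lengths(dom))
  raw <- as.data.frame(lapply(dom, function(v)
    rep_len(v, n)), stringsAsFactors = FALSE)
  # migration needs valid pairs but any pair of EU codes is valid;
  # regional tertiles need >= 3 distinct regions
  raw$region_id <- rep_len(1:6, n)
  raw$healthcare_pers_per100k <- rep_len(c(120, 250, 310, 180, 205,
                                           390), n)
  raw$gdp_pc <- rep_len(c(11000, 21000, 33000, 15000, 25000, 38000), n)
  raw$social_media_pct <- rep_len(c(30, 55), n)
  raw$eu_social_media_avg <- 40
  raw$chronic_prev_pct <- rep_len(c(20, 35), n)
  raw$eu_chronic_avg <- 30
  out <- apply_recodes(raw)
  sch <- attr(out, "schema")
  expect_setequal(sch$name, sos_schema()$name)
  for (v in sch$name) {
    expect_false(anyNA(out[[v]]), label = paste("no NA in", v))
    expect_true(all(out[[v]] %in% sosbn:::schema_levels(sch, v)),
                label = v)
  }
})

test_that("out-of-domain raw values are rejected naming field and row", {
  dom <- recode_domains()
  raw <- as.data.frame(lapply(dom, function(v) rep_len(v, 4)))
  raw$region_id <- 1:4
  raw$social_media_pct <- 30; raw$eu_social_media_avg <- 40
  raw$chronic_prev_pct <- 20; raw$eu_chronic_avg <- 30
  raw$healthcare_pers_per100k <- c(100, 200, 300, 150)
  raw$gdp_pc <- c(1, 2, 3, 4) * 1e4
  raw$occupation_18cat[3] <- 99
  expect_error(apply_recodes(raw), "occupation_18cat.*row 3")
})

test_that("recoding an already-categorical dataset is a domain error", {
  d <- sample_dataset(default_ground_truth(1), 10, seed = 1)
  expect_error(apply_recodes(d), "already")
})

test_that("raw expansion round-trips through the recodes", {
  m <- build_ground_truth(seed = 31, n_regions = 24)
  d <- sample_dataset(m, 2000, seed = 32)
  raw <- as_raw_survey(d, seed = 33)
  back <- apply_recodes(raw)
  exact_vars <- setdiff(attr(d, "schema")$name,
                        c("gdp", "healthcare_provision"))
  for (v in exact_vars)
    expect_identical(as.character(back[[v]]), as.character(d[[v]]),
                     label = v)
  # the empirical regional tertiles remain valid categories and agree
  # with the simulated levels on a clear majority of rows
  for (v in c("gdp", "healthcare_provision")) {
    expect_false(anyNA(back[[v]]))
    expect_gt(mean(as.character(back[[v]]) == as.character(d[[v]])),
              0.5)
  }
})

test_that("complete-case filter counts and degenerate cases", {
  df <- data.frame(
    x = factor(c("a", "a", NA, "b", "a", "b", NA, "a", "b", "a")),
    y = factor(c("u", "u", "u", NA, "u", "v", "v", "u", "v", "v")))
  d <- as_test_cat(df)
  expect_message(out <- complete_case_filter(d), "retained 7 of 10")
  expect_identical(nrow(out), 7L)
  # no missing: unchanged
  expect_identical(nrow(suppressMessages(complete_case_filter(out))), 7L)
  # all rows missing somewhere: empty result, downstream refuses
  d_all_na <- as_test_cat(data.frame(
    x = factor(c("a", NA), levels = c("a", "b")),
    y = factor(c(NA, "u"), levels = c("u", "v"))))
  empty <- suppressMessages(complete_case_filter(d_all_na))
  expect_identical(nrow(empty), 0L)
  expect_error(bootstrap_networks(empty, replicates = 2, seed = 1),
               "empty")
})
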