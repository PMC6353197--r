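## Expansion of a categorical dataset into a raw Eurobarometer-shaped
## survey table. Together with sample_dataset() this yields synthetic
## raw data whose recoded form reproduces the simulated categories, so
## the operationalisation layer can be exercised end to end.

#' Expand a categorical dataset into raw survey fields
#'
#' Inverse of the recoding layer: for every analysis variable present,
#' raw field values are drawn uniformly within the band implied by the
#' simulated category (e.g. a sitting band expands to one of its IPAQ
#' response codes, an education band to a stop age inside it, a WHO
#' region to a member country, macro categories to numeric regional
#' values inside their cut intervals). `apply_recodes()` on the result
#' reproduces the input categories exactly for all variables except the
#' two regional tertile factors (GDP, healthcare provision), whose
#' empirical cutpoints depend on the realised region mix.
#'
#' @param data a `cat_data` dataset from [sample_dataset()] containing a
#'   `region_id` column.
#' @param seed integer seed for the within-band draws.
#' @return A raw survey `data.frame`.
#' @export
as_raw_survey <- function(data, seed) {
  stopifnot(inherits(data, "cat_data"), "region_id" %in% names(data))
  schema <- attr(data, "schema")
  n <- nrow(data)
  region_id <- data$region_id
  has <- function(v) v %in% names(data) && v %in% schema$name
  code <- function(v) as.integer(data[[v]])
  runi <- function(lo, hi) if (n) stats::runif(n, lo, hi) else numeric(0)
  pick <- function(idx, choices) {
    ## choices: list of candidate raw codes per category index
    out <- rep(NA_integer_, length(idx))
    for (k in seq_along(choices)) {
      i <- which(!is.na(idx) & idx == k)
      if (length(i))
        out[i] <- choices[[k]][1L + (sample.int(length(choices[[k]]) ,
                                                length(i), replace = TRUE) - 1L)]
    }
    out
  }
  ## per-region draw helper: one value per region, mapped to rows
  per_region <- function(reg_codes, f) {
    u <- !duplicated(region_id)
    regs <- region_id[u]
    vals <- f(reg_codes[u])
    names(vals) <- as.character(regs)
    vals[as.character(region_id)]
  }
  with_seed(seed, {
    raw <- data.frame(region_id = region_id)
    if (has("sitting"))
      raw$sitting_10cat <- pick(code("sitting"),
                                list(1:3, 4:5, 6:8, 9:10))
    if (has("pa")) {
      lev <- code("pa")  # 1 inactive, 2 low, 3 sufficient, 4 high
      m <- integer(n); v <- integer(n)
      i <- lev == 1L; m[i] <- 0L; v[i] <- 0L
      i <- which(lev == 2L)
      if (length(i)) {
        m[i] <- sample(0:149, length(i), replace = TRUE)
        v[i] <- sample(0:74, length(i), replace = TRUE)
        both0 <- i[m[i] == 0L & v[i] == 0L]
        m[both0] <- 30L
      }
      i <- which(lev == 3L)
      if (length(i)) {
        branch <- stats::runif(length(i)) < 0.5
        m[i] <- ifelse(branch, sample(150:600, length(i), replace = TRUE),
                       sample(0:149, length(i), replace = TRUE))
        v[i] <- ifelse(branch, sample(0:74, length(i), replace = TRUE),
                       sample(75:300, length(i), replace = TRUE))
      }
      i <- which(lev == 4L)
      if (length(i)) {
        m[i] <- sample(150:600, length(i), replace = TRUE)
        v[i] <- sample(75:300, length(i), replace = TRUE)
      }
      raw$mpa_minutes <- m; raw$vpa_minutes <- v
    }
    if (has("life_satisfaction"))
      raw$lifesat_4cat <- pick(code("life_satisfaction"), list(3:4, 1:2))
    if (has("netuse")) {
      lev <- code("netuse") - 1L  # 0..2
      loc <- matrix(0L, n, 3)
      for (j in 1:3) loc[, j] <- ifelse(lev > 0,
        sample.int(3L, n, replace = TRUE) %% (lev + 1L), 0L)
      which_max <- sample.int(3L, n, replace = TRUE)
      loc[cbind(seq_len(n), which_max)] <- lev
      raw$net_home <- loc[, 1]; raw$net_work <- loc[, 2]
      raw$net_elsewhere <- loc[, 3]
    }
    if (has("occupation"))
      raw$occupation_18cat <- pick(code("occupation"),
        list(5:9, 10:11, 12:14, 15:18, 1L, 3L, 4L, 2L))
    if (has("education"))
      raw$edu_stop_age <- pick(code("education"),
                               list(10:15, 16:19, 20:30))
    if (has("social_class"))
      raw$social_class_3cat <- pick(code("social_class"), list(1L, 2:3))
    if (has("financial_burden"))
      raw$finburden_3cat <- pick(code("financial_burden"), list(3L, 1:2))
    if (has("wealth")) {
      lev <- code("wealth")  # 1 none, 2 paying, 3 paid
      raw$own_home_paid <- as.integer(lev == 3L)
      raw$own_home_paying <- as.integer(lev == 2L)
    }
    if (has("computer")) raw$own_computer <- code("computer") - 1L
    if (has("internet")) raw$own_internet <- code("internet") - 1L
    if (has("social_media")) {
      raw$eu_social_media_avg <- rep(40, n)
      raw$social_media_pct <- per_region(code("social_media"), function(l)
        ifelse(l == 2L, 40 + stats::runif(length(l), 1, 15),
               40 - stats::runif(length(l), 1, 15)))
    }
    if (has("healthcare_quality"))
      raw$hcquality_4cat <- pick(code("healthcare_quality"),
                                 list(3:4, 1:2))
    if (has("healthcare_provision"))
      raw$healthcare_pers_per100k <-
        per_region(code("healthcare_provision"), function(l)
          100 * l + stats::runif(length(l), 0, 99))
    if (has("chronic_disease")) {
      raw$eu_chronic_avg <- rep(30, n)
      raw$chronic_prev_pct <- per_region(code("chronic_disease"), function(l)
        ifelse(l == 2L, 30 + stats::runif(length(l), 1, 10),
               30 - stats::runif(length(l), 1, 10)))
    }
    if (has("urbanity")) raw$urbanity_3cat <- code("urbanity")
    if (has("facility")) {
      lev <- code("facility")  # 1 low, 2 high
      a <- pick(lev, list(3:4, 1:4))
      b <- pick(lev, list(3:4, 1:4))
      fix <- lev == 2L & a > 2L & b > 2L
      a[fix] <- pick(rep(1L, sum(fix)), list(1:2))
      raw$fac_area_4cat <- a; raw$fac_clubs_4cat <- b
    }
    if (has("municipality"))
      raw$municipality_4cat <- pick(code("municipality"), list(1:2, 3:4))
    if (has("region")) {
      by_region <- split(eu_countries(), who_region_table())
      raw$country_iso <- per_region(code("region"), function(l)
        vapply(l, function(k) sample(by_region[[k]], 1L), ""))
    } else if (has("migration")) {
      raw$country_iso <- per_region(rep(1L, n), function(l)
        sample(eu_countries(), length(l), replace = TRUE))
    }
    if (has("temperature") || has("precipitation")) {
      tlev <- if (has("temperature")) code("temperature")
              else rep(2L, n)
      plev <- if (has("precipitation")) code("precipitation")
              else rep(2L, n)
      raw$temp_max_avg <- per_region(tlev, function(l) {
        lo <- c(-5, 10, 15.1)[l]; hi <- c(9.9, 15, 25)[l]
        lo + stats::runif(length(l)) * (hi - lo)
      })
      raw$precip_daily_avg <- per_region(plev, function(l) {
        lo <- c(0, 0.2, 2.1)[l]; hi <- c(0.19, 2, 5)[l]
        lo + stats::runif(length(l)) * (hi - lo)
      })
    }
    if (has("household_size")) {
      tot <- pick(code("household_size"), list(0L, 1L, 2L, 3:6))
      counts <- t(vapply(tot, function(t)
        if (is.na(t)) rep(NA_integer_, 3)
        else as.integer(stats::rmultinom(1, t, c(0.25, 0.25, 0.5))),
        integer(3)))
      raw$n_child_lt10 <- counts[, 1]; raw$n_child_10_14 <- counts[, 2]
      raw$n_ge15 <- counts[, 3]
    }
    if (has("partner") || has("children")) {
      p <- if (has("partner")) code("partner") else rep(1L, n)
      ch <- if (has("children")) code("children") else rep(1L, n)
      comb <- (p - 1L) * 2L + ch  # 1 no/no, 2 no/yes, 3 yes/no, 4 yes/yes
      raw$relationship_14cat <- pick(comb,
        list(c(10L, 12L, 14L), c(11L, 13L), c(1L, 4L, 7L),
             c(2L, 3L, 5L, 6L, 8L, 9L)))
    }
    if (has("club_member")) {
      lev <- code("club_member")
      flags <- matrix(0L, n, 4)
      yes <- which(lev == 2L)
      if (length(yes)) {
        flags[yes, ] <- matrix(stats::rbinom(length(yes) * 4, 1, 0.4),
                               ncol = 4)
        none <- yes[rowSums(flags[yes, , drop = FALSE]) == 0]
        flags[cbind(none, sample.int(4L, length(none), replace = TRUE))] <- 1L
      }
      raw$club_fitness <- flags[, 1]; raw$club_sport <- flags[, 2]
      raw$club_social <- flags[, 3]; raw$club_other <- flags[, 4]
    }
    if (has("migration")) {
      lev <- code("migration")
      nat <- raw$country_iso
      mig <- which(lev == 2L)
      if (length(mig))
        nat[mig] <- vapply(raw$country_iso[mig], function(cc)
          sample(setdiff(eu_countries(), cc), 1L), "")
      nat[is.na(lev)] <- NA_character_
      raw$nationality_iso <- nat
    }
    if (has("car")) raw$own_car <- code("car") - 1L
    if (has("sb_guideline"))
      raw$sb_guideline_flag <- per_region(code("sb_guideline") - 1L,
                                          identity)
    if (has("pa_guideline"))
      raw$pa_guideline_flag <- per_region(code("pa_guideline") - 1L,
                                          identity)
    if (has("transport_policy"))
      raw$transport_policy_flag <- per_region(code("transport_policy") - 1L,
                                              identity)
    if (has("gdp"))
      raw$gdp_pc <- per_region(code("gdp"), function(l)
        10000 * l + stats::runif(length(l), 0, 9999))
    if (has("sex")) raw$sex_raw <- code("sex")
    if (has("age_group"))
      raw$age <- pick(code("age_group"),
                      list(15:25, 26:44, 45:64, 65:85))
    ## NA categories blank their raw sources
    for (v in schema$name) if (has(v)) {
      na_rows <- is.na(data[[v]])
      if (any(na_rows)) {
        srcs <- raw_sources(v)
        for (s in intersect(srcs, names(raw))) raw[[s]][na_rows] <- NA
      }
    }
    raw
  })
}

raw_sources <- function(var) {
  switch(var,
    sitting = "sitting_10cat",
    pa = c("mpa_minutes", "vpa_minutes"),
    life_satisfaction = "lifesat_4cat",
    netuse = c("net_home", "net_work", "net_elsewhere"),
    occupation = "occupation_18cat",
    education = "edu_stop_age",
    social_class = "social_class_3cat",
    financial_burden = "finburden_3cat",
    wealth = c("own_home_paid", "own_home_paying"),
    computer = "own_computer",
    internet = "own_internet",
    social_media = "social_media_pct",
    healthcare_quality = "hcquality_4cat",
    healthcare_provision = "healthcare_pers_per100k",
    chronic_disease = "chronic_prev_pct",
    urbanity = "urbanity_3cat",
    facility = c("fac_area_4cat", "fac_clubs_4cat"),
    municipality = "municipality_4cat",
    region = character(0),       # country also feeds migration
    temperature = "temp_max_avg",
    precipitation = "precip_daily_avg",
    household_size = c("n_child_lt10", "n_child_10_14", "n_ge15"),
    partner = "relationship_14cat",
    children = "relationship_14cat",
    club_member = c("club_fitness", "club_sport", "club_social",
                    "club_other"),
    migration = "nationality_iso",
    car = "own_car",
    sb_guideline = "sb_guideline_flag",
    pa_guideline = "pa_guideline_flag",
    transport_policy = "transport_policy_flag",
    gdp = "gdp_pc",
    sex = "sex_raw",
    age_group = "age",
    character(0))
}

#' Write a dataset as CSV (missing encoded as empty field)
#' @param data a data frame.
#' @param path output path.
#' @export
write_survey_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}
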