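## Variable derivation and categorisation rules: raw survey fields ->
## analysis categories. All derive_*() operations are vectorised, total
## over their declared raw domains, and propagate NA.

#' Collapse 10-category IPAQ sitting time to 4 bands
#'
#' The ten IPAQ response categories are collapsed into four: '1h or less
#' up to 2h30' (1), '2h31 up to 4h30' (2), '4h31 up to 7h30' (3) and
#' '7h31 up to 8h30 or more' (4).
#'
#' @param sitting_10cat integer codes 1..10 (1 = '1h or less', 10 =
#'   'more than 8h30'); NA allowed.
#' @return integer band 1..4.
#' @export
derive_sitting <- function(sitting_10cat) {
  x <- as.integer(sitting_10cat)
  bad <- !is.na(x) & (x < 1L | x > 10L)
  if (any(bad))
    stop("sitting_10cat out of range 1..10 at row ", which(bad)[1])
  ## raw cats 1-3: <= 2h30; 4-5: 2h31-4h30; 6-8: 4h31-7h30; 9-10: >= 7h31
  c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L)[x]
}

#' Categorise physical activity from MPA/VPA minutes per week
#'
#' Four classes evaluated in precedence order highly -> sufficiently ->
#' low -> inactive: 'highly active' (3) if MPA >= 150 and VPA >= 75;
#' 'sufficiently active' (2) if MPA >= 150 or VPA >= 75; 'inactive' (0)
#' if both are exactly 0; otherwise 'low active' (1). The precedence
#' makes the four printed rules a partition.
#'
#' @param mpa_minutes,vpa_minutes nonnegative minutes per week.
#' @return integer class 0..3.
#' @export
derive_pa <- function(mpa_minutes, vpa_minutes) {
  m <- as.numeric(mpa_minutes); v <- as.numeric(vpa_minutes)
  if (any(m < 0 | v < 0, na.rm = TRUE)) stop("negative minutes rejected")
  out <- ifelse(m >= 150 & v >= 75, 3L,
         ifelse(m >= 150 | v >= 75, 2L,
         ifelse(m == 0 & v == 0, 0L, 1L)))
  out[is.na(m) | is.na(v)] <- NA_integer_
  out
}

#' Internet use: maximum frequency over three locations
#'
#' @param home,work,elsewhere collapsed frequency codes 0 (never/no
#'   access), 1 (monthly or less), 2 (everyday).
#' @return integer 0..2.
#' @export
derive_netuse <- function(home, work, elsewhere) {
  for (x in list(home, work, elsewhere)) {
    bad <- !is.na(x) & !(x %in% 0:2)
    if (any(bad)) stop("netuse frequency code outside {0,1,2} at row ",
                       which(bad)[1])
  }
  as.integer(pmax(home, work, elsewhere))
}

#' Educational level from age at which full-time education stopped
#'
#' Bands: '15 years old or younger' (1), '16 to 19' (2), '20 or older'
#' (3). Code 0 denotes a respondent still in full-time education; their
#' band is taken from the current age when available (the eventual stop
#' age is at least the current age), otherwise the value is missing.
#'
#' @param stop_age years (0 = still studying); NA allowed.
#' @param current_age optional current age in years, used for
#'   still-studying respondents.
#' @return integer level 1..3.
#' @export
derive_education <- function(stop_age, current_age = NULL) {
  x <- as.numeric(stop_age)
  if (any(x < 0, na.rm = TRUE)) stop("stop_age must be >= 0")
  band <- function(a) ifelse(a <= 15, 1L, ifelse(a <= 19, 2L, 3L))
  out <- ifelse(is.na(x), NA_integer_, band(x))
  still <- !is.na(x) & x == 0
  if (any(still)) {
    if (is.null(current_age)) {
      out[still] <- NA_integer_
    } else {
      a <- as.numeric(current_age)[still]
      out[still] <- ifelse(is.na(a), NA_integer_, band(a))
    }
  }
  out
}

#' Categorise regional climate
#'
#' Temperature (maximum annual average): 'hot' (> 15 C), 'moderate'
#' (10-15 C, closed), 'cold' (< 10 C). Precipitation (average per day):
#' 'dry' (< 0.2 mm/day), 'moderate' (0.2-2 mm/day, closed), 'wet'
#' (> 2 mm/day).
#'
#' @param temp_max_avg degrees Celsius.
#' @param precip_daily_avg mm per day.
#' @return data frame with integer columns `temperature` and
#'   `precipitation` coded 1 = cold/dry, 2 = moderate, 3 = hot/wet.
#' @export
categorize_climate <- function(temp_max_avg, precip_daily_avg) {
  t <- as.numeric(temp_max_avg); p <- as.numeric(precip_daily_avg)
  if (any(!is.finite(t) & !is.na(t)) || any(!is.finite(p) & !is.na(p)))
    stop("non-finite climate values rejected")
  temp <- ifelse(t > 15, 3L, ifelse(t >= 10, 2L, 1L))
  prec <- ifelse(p > 2, 3L, ifelse(p >= 0.2, 2L, 1L))
  temp[is.na(t)] <- NA_integer_; prec[is.na(p)] <- NA_integer_
  data.frame(temperature = temp, precipitation = prec)
}

#' Household size from the three reported member counts
#'
#' Sum of children younger than 10, children aged 10-14, and persons 15
#' or older, capped at '3 or more'.
#'
#' @param n_under10,n_10to14,n_15plus nonnegative counts.
#' @return integer 0, 1, 2 or 3 (3 = '3 or more').
#' @export
derive_household_size <- function(n_under10, n_10to14, n_15plus) {
  s <- as.numeric(n_under10) + as.numeric(n_10to14) + as.numeric(n_15plus)
  if (any(s < 0, na.rm = TRUE)) stop("counts must be >= 0")
  out <- pmin(as.integer(s), 3L)
  out
}

#' EU-migration status from nationality vs residence country mismatch
#'
#' @param nationality_iso,residence_iso ISO country codes from the set of
#'   `valid` codes; unknown codes are rejected.
#' @param valid character vector of admissible codes.
#' @return integer 1 iff the codes differ, 0 otherwise.
#' @export
derive_migration <- function(nationality_iso, residence_iso,
                             valid = eu_countries()) {
  nat <- toupper(as.character(nationality_iso))
  res <- toupper(as.character(residence_iso))
  bad <- (!is.na(nat) & !(nat %in% valid)) | (!is.na(res) & !(res %in% valid))
  if (any(bad)) stop("unknown ISO country code at row ", which(bad)[1])
  out <- as.integer(nat != res)
  out[is.na(nat) | is.na(res)] <- NA_integer_
  out
}

#' EU member-state ISO codes (Eurostat convention: EL, UK)
#' @return character vector of 28 codes.
#' @export
eu_countries <- function() {
  c("AT", "BE", "BG", "CY", "CZ", "DE", "DK", "EE", "EL", "ES", "FI",
    "FR", "HR", "HU", "IE", "IT", "LT", "LU", "LV", "MT", "NL", "PL",
    "PT", "RO", "SE", "SI", "SK", "UK")
}

#' WHO-style geographical region from ISO country code
#'
#' Lookup of the four European regions ('west_central', 'southern',
#' 'northern', 'eastern') used as the macro `region` factor.
#'
#' @param country_iso ISO codes (see [eu_countries()]).
#' @return integer 1..4 in the order west_central, southern, northern,
#'   eastern.
#' @export
derive_who_region <- function(country_iso) {
  x <- toupper(as.character(country_iso))
  tab <- who_region_table()
  bad <- !is.na(x) & !(x %in% names(tab))
  if (any(bad)) stop("unknown ISO country code at row ", which(bad)[1])
  unname(tab[x])
}

who_region_table <- function() {
  tab <- c(AT = 1L, BE = 1L, CZ = 1L, DE = 1L, FR = 1L, HR = 1L, HU = 1L,
           IE = 1L, LU = 1L, NL = 1L, PL = 1L, SI = 1L, SK = 1L, UK = 1L,
           CY = 2L, EL = 2L, ES = 2L, IT = 2L, MT = 2L, PT = 2L,
           DK = 3L, EE = 3L, FI = 3L, LT = 3L, LV = 3L, SE = 3L,
           BG = 4L, RO = 4L)
  tab[eu_countries()]
}

#' Occupation: 18 survey categories condensed to 8
#'
#' Eight classes: self-employed (1), employed professional or management
#' (2), employed desk/travelling position (3), employed service or
#' manual worker (4), responsible for the household (5), unemployed (6),
#' retired or unable to work (7), student (8).
#'
#' @param occupation_18cat integer raw codes 1..18.
#' @return integer class 1..8.
#' @export
derive_occupation <- function(occupation_18cat) {
  x <- as.integer(occupation_18cat)
  bad <- !is.na(x) & (x < 1L | x > 18L)
  if (any(bad)) stop("occupation_18cat out of range 1..18 at row ",
                     which(bad)[1])
  ## 1 house person; 2 student; 3 unemployed; 4 retired/unable;
  ## 5-9 self-employed; 10-11 professional/management; 12-14 desk or
  ## travelling; 15-18 service/supervisor/manual
  map <- c(5L, 8L, 6L, 7L, 1L, 1L, 1L, 1L, 1L,
           2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 4L)
  map[x]
}

#' Partner / children status from the 14-category relationship item
#'
#' @param relationship_14cat integer raw codes 1..14.
#' @return data frame with integer columns `partner` and `children`
#'   (0/1).
#' @export
derive_partner_children <- function(relationship_14cat) {
  x <- as.integer(relationship_14cat)
  bad <- !is.na(x) & (x < 1L | x > 14L)
  if (any(bad)) stop("relationship_14cat out of range 1..14 at row ",
                     which(bad)[1])
  ## 1-9: married/remarried/with partner (codes 2,3,5,6,8,9 with
  ## children); 10-11 single (11 with children); 12-13 divorced or
  ## separated (13 with children); 14 widowed/other without children
  partner <- as.integer(x <= 9)
  children <- as.integer(x %in% c(2L, 3L, 5L, 6L, 8L, 9L, 11L, 13L))
  partner[is.na(x)] <- NA_integer_; children[is.na(x)] <- NA_integer_
  data.frame(partner = partner, children = children)
}

#' Perceived availability of recreational facilities
#'
#' 'High' (1) if the respondent agreed (totally or tend to) with at
#' least one of the two facility statements, 'low' (0) if they disagreed
#' with both.
#'
#' @param item_area,item_clubs Likert codes 1 (totally agree) .. 4
#'   (totally disagree).
#' @return integer 0/1.
#' @export
derive_facility <- function(item_area, item_clubs) {
  for (x in list(item_area, item_clubs)) {
    bad <- !is.na(x) & !(x %in% 1:4)
    if (any(bad)) stop("Likert code outside 1..4 at row ", which(bad)[1])
  }
  out <- as.integer(item_area <= 2 | item_clubs <= 2)
  out[is.na(item_area) | is.na(item_clubs)] <- NA_integer_
  out
}

## agreement with the negative statement "the local authority does not
## do enough" means LOW perceived municipal support
derive_municipality <- function(item_municipality) {
  bad <- !is.na(item_municipality) & !(item_municipality %in% 1:4)
  if (any(bad)) stop("Likert code outside 1..4 at row ", which(bad)[1])
  as.integer(item_municipality >= 3)
}

## generic positive-Likert dichotomizer: 1..2 -> 1, 3..4 -> 0
dichotomize_likert4 <- function(x, field = "likert") {
  bad <- !is.na(x) & !(x %in% 1:4)
  if (any(bad)) stop(field, " code outside 1..4 at row ", which(bad)[1])
  as.integer(x <= 2)
}

#' Split a numeric vector into empirical tertiles
#'
#' Entries are assigned to the lower/middle/upper tertile by the 1/3 and
#' 2/3 empirical quantiles; boundary ties go to the lower tertile.
#'
#' @param values numeric vector with at least 3 distinct finite values.
#' @return integer tertile 1..3 per entry (NA preserved).
#' @export
tertile_split <- function(values) {
  x <- as.numeric(values)
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 3)
    stop("tertile_split needs at least 3 distinct values")
  q <- stats::quantile(obs, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  out <- ifelse(x <= q[1], 1L, ifelse(x <= q[2], 2L, 3L))
  as.integer(out)
}

#' Flag values above a reference average
#'
#' @param values numeric vector.
#' @param reference finite reference mean (e.g. the EU average).
#' @return integer 1 iff value > reference, 0 for ties or below.
#' @export
above_average_flag <- function(values, reference) {
  if (!is.finite(reference)) stop("reference must be finite")
  x <- as.numeric(values)
  if (any(!is.finite(x) & !is.na(x))) stop("non-finite value rejected")
  out <- as.integer(x > reference)
  out
}

## map 0/1 (or NA) with domain check
check_binary <- function(x, field) {
  bad <- !is.na(x) & !(x %in% 0:1)
  if (any(bad)) stop(field, " must be 0/1; offending row ", which(bad)[1])
  as.integer(x)
}

#' Age in years to the four analysis age bands
#'
#' @param age years (>= 15).
#' @return integer band: 1 = 15-25, 2 = 26-44, 3 = 45-64, 4 = 65+.
#' @export
age_to_band <- function(age) {
  a <- as.numeric(age)
  if (any(a < 15, na.rm = TRUE)) stop("age below 15 not in sampling frame")
  out <- ifelse(a <= 25, 1L, ifelse(a <= 44, 2L, ifelse(a <= 64, 3L, 4L)))
  as.integer(out)
}

#' Declared raw domains of every recode input
#'
#' Used to verify totality of the recode maps by exhaustive enumeration.
#' Numeric fields are represented by a finite probe set covering their
#' bands and boundaries.
#'
#' @return named list of admissible raw values per raw field.
#' @export
recode_domains <- function() {
  list(
    sitting_10cat = 1:10,
    mpa_minutes = c(0, 1, 74, 75, 149, 150, 600),
    vpa_minutes = c(0, 1, 74, 75, 149, 150, 300),
    lifesat_4cat = 1:4,
    net_home = 0:2, net_work = 0:2, net_elsewhere = 0:2,
    occupation_18cat = 1:18,
    edu_stop_age = c(0, 10, 14, 15, 16, 19, 20, 30),
    social_class_3cat = 1:3,
    finburden_3cat = 1:3,
    own_home_paid = 0:1, own_home_paying = 0:1,
    own_computer = 0:1, own_internet = 0:1, own_car = 0:1,
    hcquality_4cat = 1:4,
    urbanity_3cat = 1:3,
    fac_area_4cat = 1:4, fac_clubs_4cat = 1:4,
    municipality_4cat = 1:4,
    relationship_14cat = 1:14,
    n_child_lt10 = 0:3, n_child_10_14 = 0:3, n_ge15 = 0:5,
    club_fitness = 0:1, club_sport = 0:1, club_social = 0:1,
    club_other = 0:1,
    nationality_iso = eu_countries(),
    country_iso = eu_countries(),
    sex_raw = 1:2,
    age = c(15, 25, 26, 44, 45, 64, 65, 85),
    temp_max_avg = c(-5, 9.9, 10, 12, 15, 15.1, 25),
    precip_daily_avg = c(0, 0.1, 0.2, 1, 2, 2.1, 5),
    sb_guideline_flag = 0:1, pa_guideline_flag = 0:1,
    transport_policy_flag = 0:1
  )
}

#' Apply all recode maps to a raw survey table
#'
#' Derives one categorical column per schema variable from the raw
#' Eurobarometer-shaped fields. Missing inputs propagate as missing;
#' source values outside their declared domain are rejected naming the
#' field and row. Regional tertile variables (GDP, healthcare provision)
#' are cut over the distinct regional values; 'above average' variables
#' are compared against the EU reference columns carried by the table.
#'
#' Applying the recodes to an already-categorical dataset is a domain
#' error (the operation is not idempotent by design).
#'
#' @param table a raw survey data frame (see [as_raw_survey()]).
#' @param schema target [sos_schema()]; only variables present in the
#'   schema are derived.
#' @return A `cat_data` data frame of factors (missing values allowed)
#'   plus `region_id`.
#' @export
apply_recodes <- function(table, schema = sos_schema()) {
  if (inherits(table, "cat_data"))
    stop("domain error: input is already a categorical analysis dataset")
  stopifnot(is.data.frame(table))
  n <- nrow(table)
  need <- function(...) {
    f <- c(...)
    miss <- setdiff(f, names(table))
    if (length(miss)) stop("raw field(s) missing: ",
                           paste(miss, collapse = ", "))
    invisible(TRUE)
  }
  out <- list()
  has <- function(v) v %in% schema$name
  if (has("sitting")) { need("sitting_10cat")
    out$sitting <- derive_sitting(table$sitting_10cat) }
  if (has("pa")) { need("mpa_minutes", "vpa_minutes")
    out$pa <- derive_pa(table$mpa_minutes, table$vpa_minutes) + 1L }
  if (has("life_satisfaction")) { need("lifesat_4cat")
    out$life_satisfaction <-
      dichotomize_likert4(table$lifesat_4cat, "lifesat_4cat") + 1L }
  if (has("netuse")) { need("net_home", "net_work", "net_elsewhere")
    out$netuse <- derive_netuse(table$net_home, table$net_work,
                                table$net_elsewhere) + 1L }
  if (has("occupation")) { need("occupation_18cat")
    out$occupation <- derive_occupation(table$occupation_18cat) }
  if (has("education")) { need("edu_stop_age")
    out$education <- derive_education(
      table$edu_stop_age,
      current_age = if ("age" %in% names(table)) table$age else NULL) }
  if (has("social_class")) { need("social_class_3cat")
    x <- table$social_class_3cat
    bad <- !is.na(x) & !(x %in% 1:3)
    if (any(bad)) stop("social_class_3cat outside 1..3 at row ",
                       which(bad)[1])
    out$social_class <- as.integer(x >= 2) + 1L }
  if (has("financial_burden")) { need("finburden_3cat")
    x <- table$finburden_3cat
    bad <- !is.na(x) & !(x %in% 1:3)
    if (any(bad)) stop("finburden_3cat outside 1..3 at row ", which(bad)[1])
    out$financial_burden <- as.integer(x <= 2) + 1L }
  if (has("wealth")) { need("own_home_paid", "own_home_paying")
    paid <- check_binary(table$own_home_paid, "own_home_paid")
    paying <- check_binary(table$own_home_paying, "own_home_paying")
    out$wealth <- ifelse(paid == 1L, 3L, ifelse(paying == 1L, 2L, 1L)) }
  if (has("computer")) { need("own_computer")
    out$computer <- check_binary(table$own_computer, "own_computer") + 1L }
  if (has("internet")) { need("own_internet")
    out$internet <- check_binary(table$own_internet, "own_internet") + 1L }
  if (has("social_media")) { need("social_media_pct", "eu_social_media_avg")
    out$social_media <- above_average_flag(
      table$social_media_pct, table$eu_social_media_avg[1]) + 1L }
  if (has("healthcare_quality")) { need("hcquality_4cat")
    out$healthcare_quality <-
      dichotomize_likert4(table$hcquality_4cat, "hcquality_4cat") + 1L }
  if (has("healthcare_provision")) { need("healthcare_pers_per100k",
                                          "region_id")
    out$healthcare_provision <-
      regional_tertile(table$healthcare_pers_per100k, table$region_id) }
  if (has("chronic_disease")) { need("chronic_prev_pct", "eu_chronic_avg")
    out$chronic_disease <- above_average_flag(
      table$chronic_prev_pct, table$eu_chronic_avg[1]) + 1L }
  if (has("urbanity")) { need("urbanity_3cat")
    x <- table$urbanity_3cat
    bad <- !is.na(x) & !(x %in% 1:3)
    if (any(bad)) stop("urbanity_3cat outside 1..3 at row ", which(bad)[1])
    out$urbanity <- as.integer(x) }
  if (has("facility")) { need("fac_area_4cat", "fac_clubs_4cat")
    out$facility <- derive_facility(table$fac_area_4cat,
                                    table$fac_clubs_4cat) + 1L }
  if (has("municipality")) { need("municipality_4cat")
    out$municipality <- derive_municipality(table$municipality_4cat) + 1L }
  if (has("region")) { need("country_iso")
    out$region <- derive_who_region(table$country_iso) }
  if (has("temperature") || has("precipitation")) {
    need("temp_max_avg", "precip_daily_avg")
    cl <- categorize_climate(table$temp_max_avg, table$precip_daily_avg)
    if (has("temperature")) out$temperature <- cl$temperature
    if (has("precipitation")) out$precipitation <- cl$precipitation }
  if (has("household_size")) { need("n_child_lt10", "n_child_10_14", "n_ge15")
    out$household_size <- derive_household_size(
      table$n_child_lt10, table$n_child_10_14, table$n_ge15) + 1L }
  if (has("partner") || has("children")) { need("relationship_14cat")
    pc <- derive_partner_children(table$relationship_14cat)
    if (has("partner")) out$partner <- pc$partner + 1L
    if (has("children")) out$children <- pc$children + 1L }
  if (has("club_member")) { need("club_fitness", "club_sport",
                                 "club_social", "club_other")
    flags <- cbind(check_binary(table$club_fitness, "club_fitness"),
                   check_binary(table$club_sport, "club_sport"),
                   check_binary(table$club_social, "club_social"),
                   check_binary(table$club_other, "club_other"))
    any_na <- apply(is.na(flags), 1, any)
    out$club_member <- as.integer(rowSums(flags, na.rm = TRUE) > 0) + 1L
    out$club_member[any_na & rowSums(flags, na.rm = TRUE) == 0] <-
      NA_integer_ }
  if (has("migration")) { need("nationality_iso", "country_iso")
    out$migration <- derive_migration(table$nationality_iso,
                                      table$country_iso) + 1L }
  if (has("car")) { need("own_car")
    out$car <- check_binary(table$own_car, "own_car") + 1L }
  if (has("sb_guideline")) { need("sb_guideline_flag")
    out$sb_guideline <- check_binary(table$sb_guideline_flag,
                                     "sb_guideline_flag") + 1L }
  if (has("pa_guideline")) { need("pa_guideline_flag")
    out$pa_guideline <- check_binary(table$pa_guideline_flag,
                                     "pa_guideline_flag") + 1L }
  if (has("transport_policy")) { need("transport_policy_flag")
    out$transport_policy <- check_binary(table$transport_policy_flag,
                                         "transport_policy_flag") + 1L }
  if (has("gdp")) { need("gdp_pc", "region_id")
    out$gdp <- regional_tertile(table$gdp_pc, table$region_id) }
  if (has("sex")) { need("sex_raw")
    x <- table$sex_raw
    bad <- !is.na(x) & !(x %in% 1:2)
    if (any(bad)) stop("sex_raw outside 1..2 at row ", which(bad)[1])
    out$sex <- as.integer(x) }
  if (has("age_group")) { need("age")
    out$age_group <- age_to_band(table$age) }

  vars <- schema$name[schema$name %in% names(out)]
  df <- as.data.frame(lapply(vars, function(v)
    factor(schema_levels(schema, v)[out[[v]]],
           levels = schema_levels(schema, v))),
    col.names = vars, stringsAsFactors = FALSE)
  if (n == 0)
    df <- as.data.frame(stats::setNames(lapply(vars, function(v)
      factor(character(0), levels = schema_levels(schema, v))), vars))
  if ("region_id" %in% names(table)) df$region_id <- table$region_id
  new_cat_data(df, schema_subset(schema, vars))
}

## tertile over the distinct regional values, mapped back to rows
regional_tertile <- function(values, region_id) {
  u <- !duplicated(region_id) & !is.na(values)
  if (!any(u)) return(rep(NA_integer_, length(region_id)))
  lev <- tertile_split(values[u])
  names(lev) <- as.character(region_id[u])
  out <- lev[as.character(region_id)]
  unname(out)
}

#' Complete-case filter
#'
#' Removes every row with a missing value in any schema variable; the
#' retained count is reported via `message()`.
#'
#' @param data a `cat_data` dataset (missing values allowed).
#' @return The filtered `cat_data` dataset.
#' @export
complete_case_filter <- function(data) {
  stopifnot(inherits(data, "cat_data"))
  schema <- attr(data, "schema")
  vars <- intersect(schema$name, names(data))
  keep <- !Reduce(`|`, lapply(data[vars], is.na), accumulate = FALSE)
  if (length(keep) == 0) keep <- logical(0)
  out <- data[keep, , drop = FALSE]
  message("complete-case filter: retained ", nrow(out), " of ",
          nrow(data), " rows")
  new_cat_data(out, schema)
}
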