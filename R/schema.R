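#' Variable schema for the SOS-framework analysis
#'
#' A schema describes the categorical variables entering the network
#' analysis: their names, SOS-framework cluster, ordered category levels
#' and scope. Micro-scope variables vary per respondent; macro-scope
#' variables are regional (constant within a simulated region).
#'
#' The default schema holds 33 variables: 31 SOS factors (including
#' sitting time, the SB node, and physical activity) plus `sex` and
#' `age_group`. This matches the survey-based roster in which the overall
#' network has 32 nodes (all factors except PA, plus sex and age) and the
#' sex/age-stratified networks have 30 nodes.
#'
#' @param include optional character vector of variable names to keep.
#' @param exclude optional character vector of variable names to drop.
#' @return An object of class `sos_schema`: a data frame with columns
#'   `name`, `cluster`, `scope` and a list-column `levels`.
#' @examples
#' sch <- sos_schema()
#' nrow(sch)                       # 33
#' sch$levels[[which(sch$name == "sitting")]]
#' @export
sos_schema <- function(include = NULL, exclude = NULL) {
  v <- function(name, cluster, levels, scope = "micro") {
    list(name = name, cluster = cluster, levels = levels, scope = scope)
  }
  vars <- list(
    ## psychology and behaviour
    v("sitting", "psychology_behaviour",
      c("le2h30", "2h31_4h30", "4h31_7h30", "ge7h31")),
    v("pa", "psychology_behaviour",
      c("inactive", "low", "sufficient", "high")),
    v("life_satisfaction", "psychology_behaviour", c("not_satisfied", "satisfied")),
    v("netuse", "psychology_behaviour", c("never", "monthly_or_less", "everyday")),
    ## institutional and home settings
    v("occupation", "institutional_home",
      c("self_employed", "professional_management", "desk_travel",
        "manual_service", "housekeeping", "unemployed", "retired", "student")),
    v("education", "institutional_home", c("le15", "16_19", "ge20")),
    v("social_class", "institutional_home", c("working", "middle_higher")),
    v("financial_burden", "institutional_home", c("no", "yes")),
    v("wealth", "institutional_home", c("none", "paying", "paid")),
    v("computer", "institutional_home", c("no", "yes")),
    v("internet", "institutional_home", c("no", "yes")),
    v("social_media", "institutional_home", c("below_avg", "above_avg"), "macro"),
    ## physical health and wellbeing
    v("healthcare_quality", "physical_health", c("bad", "good")),
    v("healthcare_provision", "physical_health", c("low", "mid", "high"), "macro"),
    v("chronic_disease", "physical_health", c("below_avg", "above_avg"), "macro"),
    ## built and natural environment
    v("urbanity", "built_natural", c("rural", "town", "city")),
    v("facility", "built_natural", c("low", "high")),
    v("municipality", "built_natural", c("low", "high")),
    v("region", "built_natural",
      c("west_central", "southern", "northern", "eastern"), "macro"),
    v("temperature", "built_natural", c("cold", "moderate", "hot"), "macro"),
    v("precipitation", "built_natural", c("dry", "moderate", "wet"), "macro"),
    ## social and cultural context
    v("household_size", "social_cultural", c("0", "1", "2", "3plus")),
    v("partner", "social_cultural", c("no", "yes")),
    v("children", "social_cultural", c("no", "yes")),
    v("club_member", "social_cultural", c("no", "yes")),
    v("migration", "social_cultural", c("no", "yes")),
    ## politics and economics
    v("car", "politics_economics", c("no", "yes")),
    v("sb_guideline", "politics_economics", c("no", "yes"), "macro"),
    v("pa_guideline", "politics_economics", c("no", "yes"), "macro"),
    v("transport_policy", "politics_economics", c("no", "yes"), "macro"),
    v("gdp", "politics_economics", c("low", "mid", "high"), "macro"),
    ## demographics (stratification variables)
    v("sex", "demographic", c("female", "male")),
    v("age_group", "demographic", c("15_25", "26_44", "45_64", "65plus"))
  )
  sch <- data.frame(
    name = vapply(vars, `[[`, "", "name"),
    cluster = vapply(vars, `[[`, "", "cluster"),
    scope = vapply(vars, `[[`, "", "scope"),
    stringsAsFactors = FALSE
  )
  sch$levels <- lapply(vars, `[[`, "levels")
  class(sch) <- c("sos_schema", "data.frame")
  if (!is.null(include)) sch <- schema_subset(sch, include)
  if (!is.null(exclude)) {
    missing <- setdiff(exclude, sch$name)
    if (length(missing))
      stop("unknown variable(s) in 'exclude': ", paste(missing, collapse = ", "))
    sch <- sch[!sch$name %in% exclude, , drop = FALSE]
    rownames(sch) <- NULL
    class(sch) <- c("sos_schema", "data.frame")
  }
  validate_schema(sch)
  sch
}

#' Build a custom schema
#'
#' @param names,clusters,scopes character vectors of equal length.
#' @param levels list of character vectors of category labels (length >= 2).
#' @return An `sos_schema` object.
#' @export
make_schema <- function(names, clusters, levels, scopes = "micro") {
  scopes <- rep_len(scopes, length(names))
  clusters <- rep_len(clusters, length(names))
  sch <- data.frame(name = names, cluster = clusters, scope = scopes,
                    stringsAsFactors = FALSE)
  sch$levels <- levels
  class(sch) <- c("sos_schema", "data.frame")
  validate_schema(sch)
  sch
}

schema_subset <- function(schema, vars) {
  missing <- setdiff(vars, schema$name)
  if (length(missing))
    stop("unknown variable(s): ", paste(missing, collapse = ", "))
  out <- schema[match(vars, schema$name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sos_schema", "data.frame")
  out
}

validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema),
            all(c("name", "cluster", "scope", "levels") %in% names(schema)))
  if (anyDuplicated(schema$name))
    stop("duplicate variable names in schema")
  if (!all(schema$scope %in% c("micro", "macro")))
    stop("scope must be 'micro' or 'macro'")
  ok_card <- vapply(schema$levels, function(l) {
    length(l) >= 2 && !anyDuplicated(l)
  }, logical(1))
  if (!all(ok_card))
    stop("every variable needs >= 2 unique level labels: ",
         paste(schema$name[!ok_card], collapse = ", "))
  if ("sitting" %in% schema$name &&
      length(schema$levels[[match("sitting", schema$name)]]) != 4L)
    stop("'sitting' must have exactly 4 levels")
  invisible(schema)
}

schema_levels <- function(schema, var) {
  i <- match(var, schema$name)
  if (is.na(i)) stop("variable not in schema: ", var)
  schema$levels[[i]]
}

schema_cardinalities <- function(schema) {
  k <- vapply(schema$levels, length, integer(1))
  names(k) <- schema$name
  k
}

#' @export
print.sos_schema <- function(x, ...) {
  cat("SOS variable schema:", nrow(x), "variables\n")
  k <- vapply(x$levels, length, integer(1))
  for (cl in unique(x$cluster)) {
    i <- x$cluster == cl
    cat(sprintf("  %-22s %s\n", cl,
                paste0(x$name[i], "(", k[i],
                       ifelse(x$scope[i] == "macro", ",M", ""), ")",
                       collapse = " ")))
  }
  invisible(x)
}

## SOS-framework cluster labels used throughout
sos_clusters <- function() {
  c("psychology_behaviour", "institutional_home", "physical_health",
    "built_natural", "social_cultural", "politics_economics")
}
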