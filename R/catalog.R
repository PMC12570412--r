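#' Social-factor catalogs
#'
#' A factor catalog is the data dictionary of the analysis: one entry per
#' social factor, declaring the social-determinant domain it belongs to, its
#' ordered category levels, its reference level (scored 0 points), and an
#' orientation flag controlling how the reference is chosen when the score
#' card is built.
#'
#' @param entries A list of factor specifications, each a list with elements
#'   `name`, `domain`, `levels`, `reference` and optionally `orientation`
#'   (one of `"adverse_reference"`, `"as_declared"`; default
#'   `"adverse_reference"`).
#' @return An object of class `factor_catalog`.
#' @examples
#' cat29 <- default_catalog()
#' length(catalog_names(cat29))
#' @export
factor_catalog <- function(entries) {
  if (!is.list(entries) || length(entries) == 0L)
    stop("catalog must contain at least one factor entry", call. = FALSE)
  entries <- lapply(entries, validate_factor_spec)
  nms <- vapply(entries, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate factor names in catalog: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(entries) <- nms
  structure(list(entries = entries), class = "factor_catalog")
}

sdoh_domains <- c("economic_stability", "neighborhood_environment", "education",
                  "community_social_context", "healthcare_system")

validate_factor_spec <- function(spec) {
  for (f in c("name", "domain", "levels", "reference")) {
    if (is.null(spec[[f]]))
      stop("factor entry ", if (!is.null(spec$name)) sQuote(spec$name) else "",
           " is missing field ", sQuote(f), call. = FALSE)
  }
  spec$levels <- as.character(spec$levels)
  if (!spec$domain %in% sdoh_domains)
    stop("factor ", sQuote(spec$name), ": unknown domain ", sQuote(spec$domain),
         "; must be one of ", paste(sdoh_domains, collapse = ", "), call. = FALSE)
  if (length(spec$levels) < 2L || anyDuplicated(spec$levels))
    stop("factor ", sQuote(spec$name), ": needs >= 2 distinct levels", call. = FALSE)
  if (!spec$reference %in% spec$levels)
    stop("factor ", sQuote(spec$name), ": reference level ",
         sQuote(spec$reference), " is not among its levels", call. = FALSE)
  spec$orientation <- match.arg(spec$orientation %||% "adverse_reference",
                                c("adverse_reference", "as_declared"))
  spec[c("name", "domain", "levels", "reference", "orientation")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.factor_catalog <- function(x, ...) {
  doms <- vapply(x$entries, `[[`, "", "domain")
  cat("Factor catalog:", length(x$entries), "factors in",
      length(unique(doms)), "domains\n")
  for (d in unique(doms)) {
    cat("  ", d, ": ", paste(names(x$entries)[doms == d], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @rdname factor_catalog
#' @param catalog A `factor_catalog`.
#' @export
catalog_names <- function(catalog) {
  stopifnot(inherits(catalog, "factor_catalog"))
  names(catalog$entries)
}

#' @rdname factor_catalog
#' @param name Factor name to look up.
#' @export
catalog_spec <- function(catalog, name) {
  stopifnot(inherits(catalog, "factor_catalog"))
  spec <- catalog$entries[[name]]
  if (is.null(spec)) stop("unknown factor ", sQuote(name), call. = FALSE)
  spec
}

#' Read or write a factor catalog as a YAML data dictionary
#'
#' The on-disk format is a YAML list under a top-level `factors` key, each
#' element carrying `name`, `domain`, `levels`, `reference` and optional
#' `orientation`.
#'
#' @param path Path to a YAML file.
#' @return `read_catalog` returns a validated `factor_catalog`;
#'   `write_catalog` returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  entries <- doc$factors %||% doc
  if (!is.list(entries) || length(entries) == 0L)
    stop("catalog file has no factor entries", call. = FALSE)
  factor_catalog(entries)
}

#' @rdname read_catalog
#' @param catalog A `factor_catalog` to serialise.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "factor_catalog"))
  yaml::write_yaml(list(factors = unname(catalog$entries)), path)
  invisible(path)
}

#' Re-orient a catalog so each reference level is the highest-risk level
#'
#' The point rule scores non-reference levels as `round(|beta| * 10)`; it is
#' only coherent when every non-reference coefficient is protective (negative).
#' This helper re-levels each factor with `orientation = "adverse_reference"`
#' so that its reference becomes the level with the highest weighted outcome
#' prevalence in `data`, making protective coefficients negative by
#' construction. Factors declared `as_declared` are left untouched.
#'
#' @param catalog A `factor_catalog`.
#' @param data A cohort data frame with `outcome` and `weight` columns.
#' @return A `factor_catalog` with updated reference levels.
#' @export
orient_catalog <- function(catalog, data) {
  stopifnot(inherits(catalog, "factor_catalog"))
  entries <- lapply(catalog$entries, function(spec) {
    if (spec$orientation != "adverse_reference" || !spec$name %in% names(data))
      return(spec)
    x <- as.character(data[[spec$name]])
    keep <- !is.na(x) & !is.na(data$outcome)
    if (!any(keep)) return(spec)
    risk <- vapply(spec$levels, function(lv) {
      sel <- keep & x == lv
      if (!any(sel)) return(NA_real_)
      wmean(data$outcome[sel], data$weight[sel])
    }, 0)
    if (all(is.na(risk))) return(spec)
    spec$reference <- spec$levels[which.max(risk)]
    spec
  })
  factor_catalog(entries)
}

#' Built-in 29-factor social-determinant catalog
#'
#' A ready-made data dictionary covering the five social-determinant domains
#' (economic stability; neighborhood and physical environment; education;
#' community and social context; healthcare system) with 29 factors typical of
#' ageing surveys: household wealth quintile, housing quality items, education,
#' community type, marital status, social-network and social-engagement items,
#' religious participation, information-technology access, and health
#' insurance. Used as the default dictionary by the synthetic cohort generator.
#'
#' @return A `factor_catalog` with 29 entries.
#' @export
default_catalog <- function() {
  yn <- c("no", "yes")
  e <- list(
    list(name = "wealth_index", domain = "economic_stability",
         levels = paste0("quintile_", 1:5), reference = "quintile_1"),
    list(name = "living_region", domain = "neighborhood_environment",
         levels = c("rural", "urban"), reference = "rural"),
    list(name = "housing_type", domain = "neighborhood_environment",
         levels = c("other", "single_house"), reference = "other"),
    list(name = "roof_material", domain = "neighborhood_environment",
         levels = c("light_or_mixed", "strong"), reference = "light_or_mixed"),
    list(name = "wall_material", domain = "neighborhood_environment",
         levels = c("light_or_mixed", "strong"), reference = "light_or_mixed"),
    list(name = "floor_material", domain = "neighborhood_environment",
         levels = c("other", "cement", "ceramic_tiles"), reference = "other"),
    list(name = "housing_tenure", domain = "neighborhood_environment",
         levels = c("rent", "own"), reference = "rent"),
    list(name = "electricity", domain = "neighborhood_environment",
         levels = yn, reference = "no"),
    list(name = "education", domain = "education",
         levels = c("below_elementary", "high_school", "college_plus"),
         reference = "below_elementary"),
    list(name = "community_type", domain = "community_social_context",
         levels = c("rural", "poblacion", "city"), reference = "rural"),
    list(name = "marital_status", domain = "community_social_context",
         levels = c("unmarried_separated", "widowed", "married"),
         reference = "unmarried_separated"),
    list(name = "living_arrangement", domain = "community_social_context",
         levels = c("alone", "with_others"), reference = "alone"),
    list(name = "num_friends_contact", domain = "community_social_context",
         levels = c("none", "1_2", "3_5", "6_plus"), reference = "none"),
    list(name = "num_friends_close", domain = "community_social_context",
         levels = c("none", "1_2", "3_5", "6_plus"), reference = "none"),
    list(name = "freq_social_activities", domain = "community_social_context",
         levels = c("never", "a_few_times_a_year", "monthly", "weekly"),
         reference = "never"),
    list(name = "freq_seeing_friends", domain = "community_social_context",
         levels = c("never", "yearly", "monthly", "weekly"), reference = "never"),
    list(name = "freq_hanging_out", domain = "community_social_context",
         levels = c("never", "sometimes", "often"), reference = "never"),
    list(name = "freq_gambling", domain = "community_social_context",
         levels = c("never", "sometimes", "often"), reference = "never"),
    list(name = "religious_services_outside", domain = "community_social_context",
         levels = yn, reference = "no"),
    list(name = "religious_activities_outside", domain = "community_social_context",
         levels = yn, reference = "no"),
    list(name = "religious_media", domain = "community_social_context",
         levels = yn, reference = "no"),
    list(name = "private_religious_activities", domain = "community_social_context",
         levels = yn, reference = "no"),
    list(name = "has_cellphone", domain = "community_social_context",
         levels = yn, reference = "no"),
    list(name = "has_internet", domain = "community_social_context",
         levels = yn, reference = "no"),
    list(name = "has_tablet_laptop", domain = "community_social_context",
         levels = yn, reference = "no"),
    list(name = "it_access", domain = "community_social_context",
         levels = yn, reference = "no"),
    list(name = "children_support", domain = "community_social_context",
         levels = yn, reference = "no"),
    list(name = "friends_support", domain = "community_social_context",
         levels = yn, reference = "no"),
    list(name = "health_insurance", domain = "healthcare_system",
         levels = yn, reference = "no")
  )
  factor_catalog(e)
}
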