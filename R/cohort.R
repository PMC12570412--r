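#' Cohort input and output
#'
#' A cohort is a plain data frame with one row per participant: reserved
#' columns `id`, `gender` (`men`/`women`), `age_group` (`60-69`, `70-79`,
#' `80+`), `weight` (positive sampling weight), `outcome` (0/1 disability
#' indicator, possibly missing), the lifestyle covariates `smoking`,
#' `drinking`, `sleep_trouble`, and one column per catalog factor holding a
#' level label or `NA`.
#'
#' `read_cohort` parses a UTF-8 CSV (empty string and `"Not sure"` are read as
#' missing), validates the reserved columns, and coerces every factor column
#' against the catalog: cells that are not a declared level become missing and
#' their count is reported via `message`. `write_cohort` writes the same
#' dialect back (missing as the empty string), so a read/write cycle preserves
#' values and missingness.
#'
#' @param path CSV file path.
#' @param catalog A `factor_catalog` describing the factor columns.
#' @return `read_cohort`: a validated cohort data frame.
#' @export
read_cohort <- function(path, catalog) {
  stopifnot(inherits(catalog, "factor_catalog"))
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = c("", "NA", "Not sure"))
  validate_cohort(raw, catalog)
}

reserved_cols <- c("id", "gender", "age_group", "weight", "outcome",
                   "smoking", "drinking", "sleep_trouble")

covariate_levels <- list(
  smoking = c("never", "former", "current"),
  drinking = c("none", "lt_monthly", "monthly_weekly", "frequent"),
  sleep_trouble = c("never", "rarely", "sometimes", "most_of_the_time")
)

gender_levels <- c("men", "women")
age_levels <- c("60-69", "70-79", "80+")

#' Validate and type a raw cohort table against a catalog
#'
#' @param raw A data frame (character or already-typed columns).
#' @inheritParams read_cohort
#' @return A typed cohort data frame.
#' @export
validate_cohort <- function(raw, catalog) {
  missing_cols <- setdiff(reserved_cols, names(raw))
  if (length(missing_cols))
    stop("cohort is missing reserved column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- raw
  out$id <- as.character(raw$id)
  if (anyDuplicated(out$id))
    stop("duplicate participant ids", call. = FALSE)
  out$weight <- as.numeric(raw$weight)
  if (anyNA(out$weight) || any(out$weight <= 0)) {
    bad <- which(is.na(out$weight) | out$weight <= 0)
    stop("non-positive or missing sampling weight in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out$gender <- factor(as.character(raw$gender), levels = gender_levels)
  if (anyNA(out$gender)) stop("gender must be 'men' or 'women'", call. = FALSE)
  out$age_group <- factor(as.character(raw$age_group), levels = age_levels)
  if (anyNA(out$age_group))
    stop("age_group must be one of ", paste(age_levels, collapse = ", "),
         call. = FALSE)
  oc <- suppressWarnings(as.numeric(as.character(raw$outcome)))
  if (any(!is.na(oc) & !oc %in% c(0, 1)))
    stop("outcome must be 0, 1 or missing", call. = FALSE)
  out$outcome <- as.integer(oc)
  n_bad <- 0L
  for (cv in names(covariate_levels)) {
    x <- factor(as.character(raw[[cv]]), levels = covariate_levels[[cv]])
    n_bad <- n_bad + sum(!is.na(raw[[cv]]) & is.na(x))
    out[[cv]] <- x
  }
  for (nm in catalog_names(catalog)) {
    if (!nm %in% names(raw)) {
      out[[nm]] <- factor(rep(NA_character_, nrow(raw)),
                          levels = catalog_spec(catalog, nm)$levels)
      next
    }
    spec <- catalog_spec(catalog, nm)
    x <- factor(as.character(raw[[nm]]), levels = spec$levels)
    n_bad <- n_bad + sum(!is.na(raw[[nm]]) & is.na(x))
    out[[nm]] <- x
  }
  if (n_bad > 0L)
    message(n_bad, " cell(s) did not match declared levels and were set to missing")
  out[, c(reserved_cols, catalog_names(catalog)), drop = FALSE]
}

#' @rdname read_cohort
#' @param data A cohort data frame.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Derive the disability outcome from the seven daily-living items
#'
#' Participants reporting difficulty on any of the seven activities of daily
#' living (bathing, dressing, eating, transferring, walking around the house,
#' going outside, toileting) are classified as having ADL disability (1); those
#' answering no to all seven are classified 0. If no item is positive but at
#' least one is missing, the outcome is missing: difficulty on the unanswered
#' item cannot be ruled out.
#'
#' @param items A length-7 vector, or an n x 7 matrix / data frame (one column
#'   per item). Accepted codings: `"yes"`/`"no"`, 1/0, `TRUE`/`FALSE`, `NA`.
#' @return Integer 0/1/`NA`, vectorised over rows for matrix input.
#' @examples
#' derive_outcome(c("no", "no", "no", "no", "no", "no", "yes"))
#' @export
derive_outcome <- function(items) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (!is.matrix(items)) items <- matrix(items, nrow = 1L)
  if (ncol(items) != 7L)
    stop("exactly 7 daily-living items are required, got ", ncol(items),
         call. = FALSE)
  norm <- function(v) {
    v <- tolower(as.character(v))
    ifelse(is.na(v) | v %in% c("", "not sure"), NA,
           v %in% c("yes", "1", "true", "y"))
  }
  m <- apply(items, 2L, norm)
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  any_yes <- apply(m, 1L, function(r) any(r %in% TRUE))
  any_na <- apply(m, 1L, anyNA)
  as.integer(ifelse(any_yes, 1L, ifelse(any_na, NA, 0L)))
}

#' Restrict a cohort to complete cases on selected columns
#'
#' @param data Cohort data frame.
#' @param columns Character vector of column names that must be non-missing;
#'   an empty vector returns the cohort unchanged.
#' @return A list with elements `data` (the filtered cohort) and `n_dropped`.
#' @export
complete_case_filter <- function(data, columns) {
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (length(columns) == 0L)
    return(list(data = data, n_dropped = 0L))
  keep <- stats::complete.cases(data[, columns, drop = FALSE])
  list(data = data[keep, , drop = FALSE], n_dropped = sum(!keep))
}

#' Weighted descriptive table with gender comparisons
#'
#' Produces the weighted descriptive summary of a cohort: for categorical
#' variables, weighted percentages overall and by gender with a design-adjusted
#' chi-squared test (weighted Pearson statistic computed on a table rescaled to
#' the Kish effective sample size — a first-order Rao-Scott style correction);
#' for numeric variables, weighted means and SDs with a design-based two-sample
#' t test (linearised variance of the weighted means).
#'
#' @param data Cohort data frame with `gender` and `weight` columns.
#' @param variables Character vector of column names to summarise.
#' @return A data frame of class `weighted_summary`: one row per variable
#'   level (or one per numeric variable) with weighted percentages/means for
#'   the total sample and each gender, the p-value and the test used.
#' @export
weighted_table_one <- function(data, variables) {
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols))
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    keep <- !is.na(x)
    if (!any(keep)) stop("variable ", sQuote(v), " is entirely missing",
                         call. = FALSE)
    x <- x[keep]
    w <- data$weight[keep]
    g <- data$gender[keep]
    if (is.numeric(x)) {
      summarise_numeric(v, x, w, g)
    } else {
      summarise_categorical(v, factor(x), w, g)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("weighted_summary", class(out))
  out
}

summarise_numeric <- function(v, x, w, g) {
  grp_stats <- lapply(split(seq_along(x), g), function(i) {
    m <- wmean(x[i], w[i])
    # variance of the weighted mean (linearisation)
    vm <- sum((w[i] * (x[i] - m))^2) / sum(w[i])^2
    c(mean = m, sd = sqrt(wvar(x[i], w[i])), vmean = vm)
  })
  z <- (grp_stats$men["mean"] - grp_stats$women["mean"]) /
    sqrt(grp_stats$men["vmean"] + grp_stats$women["vmean"])
  data.frame(
    variable = v, level = "(mean)",
    total = wmean(x, w), men = unname(grp_stats$men["mean"]),
    women = unname(grp_stats$women["mean"]),
    p_value = unname(2 * stats::pnorm(-abs(z))), test_used = "t",
    stringsAsFactors = FALSE
  )
}

summarise_categorical <- function(v, x, w, g) {
  x <- droplevels(x)
  pct <- function(sel) {
    if (!any(sel)) return(rep(0, nlevels(x)))
    100 * vapply(levels(x),
                 function(lv) sum(w[sel & x == lv]) / sum(w[sel]), 0)
  }
  # weighted Pearson chi-square rescaled to the Kish effective sample size
  tab <- vapply(gender_levels, function(gl) {
    vapply(levels(x), function(lv) sum(w[g == gl & x == lv]), 0)
  }, numeric(nlevels(x)))
  tab <- matrix(tab, nrow = nlevels(x))
  tab_eff <- tab / sum(tab) * kish_neff(w)
  p <- if (nlevels(x) < 2L) NA_real_ else {
    suppressWarnings(stats::chisq.test(tab_eff, correct = FALSE)$p.value)
  }
  data.frame(
    variable = v, level = levels(x),
    total = pct(rep(TRUE, length(x))), men = pct(g == "men"),
    women = pct(g == "women"),
    p_value = c(p, rep(NA_real_, nlevels(x) - 1L)), test_used = "chi2",
    stringsAsFactors = FALSE
  )
}

#' @export
print.weighted_summary <- function(x, digits = 1, ...) {
  y <- x
  for (cc in c("total", "men", "women")) y[[cc]] <- round(y[[cc]], digits)
  y$p_value <- signif(y$p_value, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
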