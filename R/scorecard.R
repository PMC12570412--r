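#' Survey-weighted logistic regression on selected factors
#'
#' Fits the outcome on the selected social factors by maximum likelihood with
#' sampling weights (via a quasibinomial `glm`, whose point estimates are the
#' weighted-ML solution). With unit weights the fit equals an ordinary
#' logistic regression. Standard errors are robust (HC0 sandwich) whenever
#' non-constant weights are used, and model-based otherwise.
#'
#' @param data Complete-case cohort data frame on `outcome` and `factors`.
#' @param factors Character vector of factor column names to include.
#' @param catalog Optional `factor_catalog`; when given, each factor is
#'   re-levelled so the catalog reference level is the baseline.
#' @param use_weights Use the `weight` column as sampling weights
#'   (default TRUE).
#' @return An object of class `logistic_fit`: list with `terms` (data frame:
#'   `factor`, `level`, `beta`, `se`, `ci_lo`, `ci_hi`; reference levels are
#'   absent and implicitly 0), `intercept`, `factors`, `weighted`, `n`, and
#'   `sparse_cells` (factor levels unobserved in one outcome class).
#' @export
fit_weighted_logistic <- function(data, factors, catalog = NULL,
                                  use_weights = TRUE) {
  cc <- stats::complete.cases(data[, c("outcome", factors), drop = FALSE])
  if (!all(cc))
    stop("complete cases required on outcome and factors; ", sum(!cc),
         " row(s) missing", call. = FALSE)
  check_binary_outcome(data$outcome)
  df <- data
  for (f in factors) {
    x <- droplevels(factor(df[[f]]))
    if (!is.null(catalog) && f %in% catalog_names(catalog)) {
      ref <- catalog_spec(catalog, f)$reference
      if (ref %in% levels(x)) x <- stats::relevel(x, ref = ref)
    }
    df[[f]] <- x
  }
  sparse <- character()
  for (f in factors) {
    tab <- table(df[[f]], df$outcome)
    zero <- rownames(tab)[apply(tab == 0, 1, any)]
    if (length(zero)) sparse <- c(sparse, paste0(f, "=", zero))
  }
  if (length(sparse))
    warning("level(s) unobserved in one outcome class: ",
            paste(sparse, collapse = ", "))
  w <- if (use_weights) df$weight else rep(1, nrow(df))
  fml <- stats::reformulate(factors, response = "outcome")
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::quasibinomial(), data = df, weights = w))
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("rank-deficient design; aliased term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(abs(cf[-1]) > 15)) {
    bad <- names(cf[-1])[abs(cf[-1]) > 15]
    stop("(quasi-)separation detected for term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  weighted <- use_weights && stats::var(w) > 0
  V <- if (weighted) sandwich::vcovHC(fit, type = "HC0") else stats::vcov(fit)
  se <- sqrt(diag(V))
  terms <- do.call(rbind, lapply(factors, function(f) {
    lv <- levels(df[[f]])[-1]
    if (length(lv) == 0L) return(NULL)
    nm <- paste0(f, lv)
    data.frame(factor = f, level = lv, beta = unname(cf[nm]),
               se = unname(se[nm]),
               ci_lo = unname(cf[nm] - 1.96 * se[nm]),
               ci_hi = unname(cf[nm] + 1.96 * se[nm]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(terms))
    terms <- data.frame(factor = character(), level = character(),
                        beta = numeric(), se = numeric(), ci_lo = numeric(),
                        ci_hi = numeric(), stringsAsFactors = FALSE)
  structure(list(terms = terms, intercept = unname(cf[1]),
                 factors = factors, weighted = weighted, n = nrow(df),
                 sparse_cells = sparse),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Weighted logistic fit:", x$n, "participants,",
      length(x$factors), "factors",
      if (x$weighted) "(sampling-weighted, sandwich SEs)" else "(unweighted)",
      "\n")
  y <- x$terms
  y$or <- exp(y$beta)
  for (cc in c("beta", "se", "ci_lo", "ci_hi", "or")) y[[cc]] <- round(y[[cc]], 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Integer points from a logistic coefficient
#'
#' The point rule of the score card: the absolute regression coefficient times
#' ten, rounded half away from zero to the nearest integer. A coefficient of
#' -0.61 yields 6 points; -0.26 yields 3; reference levels carry 0.
#'
#' @param beta Numeric vector of finite log-odds coefficients.
#' @return Integer vector of nonnegative points.
#' @examples
#' points_from_beta(c(-0.61, -0.26, 0))
#' @export
points_from_beta <- function(beta) {
  if (any(!is.finite(beta))) stop("coefficients must be finite", call. = FALSE)
  as.integer(floor(abs(beta) * 10 + 0.5))
}

#' Build the point score card from a logistic fit
#'
#' One entry per factor level: non-reference levels score
#' `points_from_beta(beta)`, reference levels score 0. Because the rule uses
#' the absolute coefficient, a risk-increasing (positive) coefficient would
#' still add points; any such level triggers an orientation warning — use
#' [orient_catalog()] beforehand to re-level factors so the reference is the
#' highest-risk level and all coefficients are protective.
#'
#' @param fit A `logistic_fit`.
#' @param catalog A `factor_catalog` the fit's terms must map onto.
#' @return An object of class `scorecard`: data frame with `factor`, `level`,
#'   `beta`, `points`, `is_reference`.
#' @export
build_scorecard <- function(fit, catalog) {
  stopifnot(inherits(fit, "logistic_fit"), inherits(catalog, "factor_catalog"))
  unknown_f <- setdiff(fit$terms$factor, catalog_names(catalog))
  if (length(unknown_f))
    stop("fit term(s) for unknown factor(s): ",
         paste(unknown_f, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(fit$terms))) {
    spec <- catalog_spec(catalog, fit$terms$factor[i])
    if (!fit$terms$level[i] %in% spec$levels)
      stop("fit term for unknown level ", sQuote(fit$terms$level[i]),
           " of factor ", sQuote(fit$terms$factor[i]), call. = FALSE)
  }
  if (nrow(fit$terms) == 0L)
    warning("fit has no non-reference terms; all card points are 0")
  rows <- do.call(rbind, lapply(fit$factors, function(f) {
    spec <- catalog_spec(catalog, f)
    tf <- fit$terms[fit$terms$factor == f, , drop = FALSE]
    beta <- stats::setNames(rep(0, length(spec$levels)), spec$levels)
    beta[tf$level] <- tf$beta
    is_ref <- !spec$levels %in% tf$level
    data.frame(factor = f, level = spec$levels, beta = unname(beta),
               points = ifelse(is_ref, 0L, points_from_beta(unname(beta))),
               is_reference = is_ref, stringsAsFactors = FALSE)
  }))
  pos <- rows[!rows$is_reference & rows$beta > 0, , drop = FALSE]
  if (nrow(pos) > 0L)
    warning("risk-increasing level(s) add points under the |beta| rule: ",
            paste0(pos$factor, "=", pos$level, collapse = ", "),
            "; consider orient_catalog()")
  class(rows) <- c("scorecard", class(rows))
  rows
}

#' @export
print.scorecard <- function(x, ...) {
  cat("Polysocial score card:", length(unique(x$factor)), "factors, max score",
      sum(tapply(x$points, x$factor, max)), "\n")
  y <- x; y$beta <- round(y$beta, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Compute per-participant polysocial scores
#'
#' Sums the card points of each participant's factor levels. Participants
#' missing any card factor get an `NA` score and are counted in a message.
#'
#' @param data Cohort data frame.
#' @param card A `scorecard`.
#' @return Data frame with `id` and integer `score` (`NA` where skipped).
#' @export
score_participants <- function(data, card) {
  stopifnot(inherits(card, "scorecard"))
  factors <- unique(card$factor)
  missing_cols <- setdiff(factors, names(data))
  if (length(missing_cols))
    stop("cohort lacks card factor(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  score <- rep(0L, nrow(data))
  for (f in factors) {
    pts <- stats::setNames(card$points[card$factor == f],
                           card$level[card$factor == f])
    score <- score + as.integer(pts[as.character(data[[f]])])
  }
  if (anyNA(score))
    message(sum(is.na(score)),
            " participant(s) skipped: missing value on a card factor")
  data.frame(id = data$id, score = score, stringsAsFactors = FALSE)
}

#' Categorise polysocial scores into low / intermediate / high
#'
#' The quintile scheme labels the bottom quintile `low`, quintiles 2-4
#' `intermediate`, and the top quintile `high`, using unweighted type-7
#' quantile cutpoints at 0.2 and 0.8; intervals are left-closed on the upper
#' side (a score equal to a cutpoint moves up), so tied scores always share a
#' category. The fixed scheme takes two inclusive upper bounds
#' `cutoffs = c(low_max, mid_max)`, e.g. `c(37, 63)` for the bands 0-37,
#' 38-63, 64+.
#'
#' @param scores Integer/numeric score vector (`NA` allowed, propagated).
#' @param scheme `"quintile"` (default) or `"fixed"`.
#' @param cutoffs For `scheme = "fixed"`: numeric `c(low_max, mid_max)`.
#' @return A list with `category` (factor `low`/`intermediate`/`high` aligned
#'   to `scores`) and `cutoffs` (the two boundaries used, as
#'   `c(low_max, mid_max)` on the observed scale).
#' @export
categorize_scores <- function(scores, scheme = c("quintile", "fixed"),
                              cutoffs = NULL) {
  scheme <- match.arg(scheme)
  s_obs <- scores[!is.na(scores)]
  if (scheme == "quintile") {
    if (length(unique(s_obs)) < 5L)
      stop("quintile categories need at least 5 distinct scores", call. = FALSE)
    q <- stats::quantile(s_obs, c(0.2, 0.8), type = 7, names = FALSE)
    category <- ifelse(scores < q[1], "low",
                       ifelse(scores < q[2], "intermediate", "high"))
    cuts <- q
  } else {
    if (is.null(cutoffs) || length(cutoffs) != 2L || cutoffs[1] >= cutoffs[2])
      stop("fixed scheme needs cutoffs = c(low_max, mid_max) with low_max < mid_max",
           call. = FALSE)
    category <- ifelse(scores <= cutoffs[1], "low",
                       ifelse(scores <= cutoffs[2], "intermediate", "high"))
    cuts <- cutoffs
  }
  list(category = factor(category, levels = c("low", "intermediate", "high")),
       cutoffs = unname(cuts), scheme = scheme)
}
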