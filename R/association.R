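#' Smoothed score-risk curve
#'
#' Locally weighted scatterplot smoothing of the binary outcome on the
#' polysocial score: tricube-weighted local linear fits with robustness
#' iterations, used to inspect the shape of the score-risk relation before
#' committing to a parametric model. Fitted values are clipped to [0, 1].
#'
#' @param scores Numeric scores (at least 20 non-missing values, not all
#'   equal).
#' @param outcomes 0/1 outcomes aligned to `scores`.
#' @param span Smoothing span: the fraction of points in each local
#'   neighbourhood (default 2/3).
#' @param iterations Robustness iterations (default 3).
#' @return Data frame with `score` (sorted) and `prob` (smoothed risk).
#' @export
lowess_curve <- function(scores, outcomes, span = 2/3, iterations = 3L) {
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]; outcomes <- outcomes[keep]
  if (length(scores) < 20L)
    stop("at least 20 observations required", call. = FALSE)
  if (length(unique(scores)) < 2L)
    stop("scores are constant; no curve can be fitted", call. = FALSE)
  sm <- stats::lowess(scores, outcomes, f = span, iter = iterations)
  data.frame(score = sm$x, prob = pmin(pmax(sm$y, 0), 1))
}

default_adjustment <- c("age_group", "smoking", "drinking", "sleep_trouble")

#' Odds ratios for the polysocial score
#'
#' Survey-weighted logistic regression of the outcome on the polysocial
#' score, either per one-point increment (`exposure = "continuous"`, using
#' the `score` column) or across risk categories (`exposure = "category"`,
#' using the `category` column with the lowest category as reference).
#' Adjusted models add the demographic/lifestyle covariates. Odds ratios are
#' `exp(beta)` with Wald 95% CIs on the log-odds scale; SEs are HC0 sandwich
#' under non-constant weights.
#'
#' @param data Cohort data frame carrying `outcome`, `weight`, and a `score`
#'   and/or `category` column (see [score_participants()],
#'   [categorize_scores()]).
#' @param exposure `"continuous"` or `"category"`.
#' @param adjusted Add the adjustment covariates (default FALSE).
#' @param covariates Adjustment set (default age group, smoking, drinking,
#'   sleep trouble).
#' @param use_weights Use sampling weights (default TRUE).
#' @return A data frame of class `association_result`: one row per contrast
#'   (`exposure`, `contrast`, `or`, `ci_lo`, `ci_hi`, `adjusted`, `n`); the
#'   reference category appears with OR 1.
#' @export
estimate_ors <- function(data, exposure = c("continuous", "category"),
                         adjusted = FALSE, covariates = default_adjustment,
                         use_weights = TRUE) {
  exposure <- match.arg(exposure)
  var <- if (exposure == "continuous") "score" else "category"
  if (!var %in% names(data))
    stop("cohort lacks the ", sQuote(var), " column", call. = FALSE)
  keep_cols <- c("outcome", var, if (adjusted) covariates)
  cc <- stats::complete.cases(data[, keep_cols, drop = FALSE])
  df <- data[cc, , drop = FALSE]
  check_binary_outcome(df$outcome)
  if (exposure == "continuous") {
    if (stats::var(df$score) == 0)
      stop("score is constant; no contrast to estimate", call. = FALSE)
  } else {
    df$category <- factor(df$category)
    if (nlevels(df$category) < 2L || any(table(df$category) == 0))
      stop("empty or single score category", call. = FALSE)
  }
  w <- if (use_weights) df$weight else rep(1, nrow(df))
  fml <- stats::reformulate(c(var, if (adjusted) covariates),
                            response = "outcome")
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::quasibinomial(), data = df, weights = w))
  V <- if (use_weights && stats::var(w) > 0) sandwich::vcovHC(fit, type = "HC0")
       else stats::vcov(fit)
  cf <- stats::coef(fit); se <- sqrt(diag(V))
  rows <- if (exposure == "continuous") {
    data.frame(exposure = "continuous", contrast = "per 1-point increment",
               or = exp(cf[["score"]]),
               ci_lo = exp(cf[["score"]] - 1.96 * se[["score"]]),
               ci_hi = exp(cf[["score"]] + 1.96 * se[["score"]]),
               stringsAsFactors = FALSE)
  } else {
    lv <- levels(df$category)
    nm <- paste0("category", lv[-1])
    rbind(
      data.frame(exposure = "category", contrast = paste0(lv[1], " (ref)"),
                 or = 1, ci_lo = NA_real_, ci_hi = NA_real_,
                 stringsAsFactors = FALSE),
      data.frame(exposure = "category", contrast = lv[-1],
                 or = exp(unname(cf[nm])),
                 ci_lo = exp(unname(cf[nm] - 1.96 * se[nm])),
                 ci_hi = exp(unname(cf[nm] + 1.96 * se[nm])),
                 stringsAsFactors = FALSE))
  }
  rows$adjusted <- adjusted
  rows$n <- nrow(df)
  class(rows) <- c("association_result", class(rows))
  rows
}

#' @export
print.association_result <- function(x, ...) {
  y <- x
  for (cc in c("or", "ci_lo", "ci_hi")) y[[cc]] <- round(y[[cc]], 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
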