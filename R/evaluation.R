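#' Cross-validated out-of-fold predicted probabilities
#'
#' Splits the cohort into `k` folds stratified on the outcome, fits the given
#' logistic model on each training set (with sampling weights), and predicts
#' each participant exactly once, by the model not trained on them. `k = n`
#' gives leave-one-out.
#'
#' @param data Cohort data frame (complete cases on the model variables).
#' @param formula Model formula with `outcome` on the left-hand side.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param use_weights Use sampling weights when fitting (default TRUE).
#' @return Numeric vector of out-of-fold predicted probabilities aligned to
#'   the rows of `data`.
#' @export
crossval_predictions <- function(data, formula, k = 10L, seed = 1L,
                                 use_weights = TRUE) {
  vars <- all.vars(formula)
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  if (!all(cc))
    stop("complete cases required on model variables; ", sum(!cc),
         " row(s) missing", call. = FALSE)
  check_binary_outcome(data$outcome)
  folds <- if (k >= nrow(data)) seq_len(nrow(data)) # leave-one-out
           else stratified_folds(data$outcome, k, substream_seed(seed, "cvfolds"))
  w_all <- if (use_weights) data$weight else rep(1, nrow(data))
  # one design matrix for the whole cohort so factor levels unseen in a
  # training fold alias to zero columns instead of breaking prediction
  X <- stats::model.matrix(formula, data)
  y <- data$outcome
  pred <- numeric(nrow(data))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L)
      stop("training fold with a single outcome class; reduce k", call. = FALSE)
    fit <- suppressWarnings(
      stats::glm.fit(X[tr, , drop = FALSE], y[tr], weights = w_all[tr],
                     family = stats::quasibinomial()))
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    pred[!tr] <- stats::plogis(drop(X[!tr, , drop = FALSE] %*% cf))
  }
  pred
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups participants into `n_groups` bins of predicted risk (decile
#' cutpoints; tied predictions always share a bin), and compares observed and
#' expected event counts: the statistic is the sum over bins of
#' `(O - E)^2 / (n p (1 - p))` with `p` the mean predicted risk in the bin,
#' referred to a chi-squared distribution with `groups - 2` degrees of
#' freedom. Bins with expected counts of 0 (or expected non-events of 0) are
#' merged into their neighbour with a message.
#'
#' @param predicted Predicted probabilities.
#' @param observed 0/1 outcomes.
#' @param n_groups Number of risk groups (default 10).
#' @return A list with `statistic`, `df`, `p`, `n_groups` (after any
#'   merging), and `bins` (per-bin n, observed, expected and mean predicted
#'   risk — the calibration-plot table).
#' @export
hosmer_lemeshow <- function(predicted, observed, n_groups = 10L) {
  stopifnot(length(predicted) == length(observed))
  check_binary_outcome(observed)
  if (any(predicted < 0 | predicted > 1))
    stop("predicted probabilities must lie in [0, 1]", call. = FALSE)
  br <- unique(stats::quantile(predicted, probs = seq(0, 1, length.out = n_groups + 1),
                               type = 7, names = FALSE))
  if (length(br) < 3L)
    stop("too few distinct predictions to form risk groups", call. = FALSE)
  g <- cut(predicted, breaks = br, include.lowest = TRUE)
  bins <- data.frame(
    n = as.numeric(tapply(observed, g, length)),
    observed = as.numeric(tapply(observed, g, sum)),
    expected = as.numeric(tapply(predicted, g, sum)),
    mean_pred = as.numeric(tapply(predicted, g, mean))
  )
  bins <- bins[!is.na(bins$n), , drop = FALSE]
  # merge degenerate bins (expected events or non-events ~ 0) into a neighbour
  i <- 1L
  while (i <= nrow(bins) && nrow(bins) > 1L) {
    if (bins$expected[i] < 1e-10 || (bins$n[i] - bins$expected[i]) < 1e-10) {
      j <- if (i == nrow(bins)) i - 1L else i + 1L
      bins$n[j] <- bins$n[j] + bins$n[i]
      bins$observed[j] <- bins$observed[j] + bins$observed[i]
      bins$expected[j] <- bins$expected[j] + bins$expected[i]
      bins$mean_pred[j] <- bins$expected[j] / bins$n[j]
      bins <- bins[-i, , drop = FALSE]
      message("merged a degenerate risk group with its neighbour")
    } else i <- i + 1L
  }
  pbar <- bins$expected / bins$n
  stat <- sum((bins$observed - bins$expected)^2 / (bins$n * pbar * (1 - pbar)))
  df <- max(nrow(bins) - 2L, 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       n_groups = nrow(bins), bins = bins)
}

#' C-statistic of two models with paired DeLong comparison
#'
#' The C-statistic of each prediction vector (the probability a random event
#' out-scores a random non-event) and the paired DeLong test of their
#' difference; intended for pooled out-of-fold predictions from
#' [crossval_predictions()].
#'
#' @param pred_ref,pred_new Predicted probabilities from the reference and
#'   the richer model, aligned to `outcome`.
#' @param outcome 0/1 outcomes.
#' @param weights Optional sampling weights.
#' @return A list with `c_ref`, `c_new`, `delta` (`c_new - c_ref`), `z`, `p`,
#'   and the 95% CIs of both C-statistics.
#' @export
c_statistic_delta <- function(pred_ref, pred_new, outcome, weights = NULL) {
  ac <- auc_with_covariance(pred_new, pred_ref, outcome, weights)
  dl <- suppressWarnings(delong_test(pred_new, pred_ref, outcome, weights))
  ci <- function(a, v) c(a - 1.96 * sqrt(max(v, 0)), a + 1.96 * sqrt(max(v, 0)))
  list(c_ref = ac$auc_b, c_new = ac$auc_a, delta = dl$delta_auc,
       z = dl$z, p = dl$p,
       ci_ref = ci(ac$auc_b, ac$var_b), ci_new = ci(ac$auc_a, ac$var_a))
}

#' Net reclassification improvement
#'
#' Category-free (continuous) NRI by default: an upward move is any increase
#' in predicted risk from the reference to the new model. The event component
#' is `P(up | event) - P(down | event)`, the non-event component
#' `P(down | non-event) - P(up | non-event)`, and the overall NRI their sum.
#' Categorical NRI classifies both prediction vectors with `cuts` and counts
#' category moves instead. Percentile bootstrap CIs resample participants
#' (keeping the prediction pairing).
#'
#' @param pred_ref,pred_new Aligned predicted probabilities.
#' @param outcome 0/1 outcomes with both classes present.
#' @param mode `"continuous"` (default) or `"categorical"`.
#' @param cuts Risk-category boundaries for `mode = "categorical"`.
#' @param n_boot Bootstrap replicates for the CIs (default 1000; 0 disables).
#' @param seed Bootstrap seed.
#' @return A list with `overall`, `event`, `non_event`, and `ci` (3 x 2
#'   matrix of percentile 95% CIs when `n_boot > 0`).
#' @export
nri <- function(pred_ref, pred_new, outcome, mode = c("continuous", "categorical"),
                cuts = NULL, n_boot = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(pred_ref) == length(outcome),
            length(pred_new) == length(outcome))
  check_binary_outcome(outcome)
  if (mode == "categorical") {
    if (is.null(cuts)) stop("categorical mode needs cuts", call. = FALSE)
    pred_ref <- as.integer(cut(pred_ref, c(-Inf, cuts, Inf)))
    pred_new <- as.integer(cut(pred_new, c(-Inf, cuts, Inf)))
  }
  comp <- function(idx) {
    up <- pred_new[idx] > pred_ref[idx]
    down <- pred_new[idx] < pred_ref[idx]
    ev <- outcome[idx] == 1
    event <- mean(up[ev]) - mean(down[ev])
    non_event <- mean(down[!ev]) - mean(up[!ev])
    c(overall = event + non_event, event = event, non_event = non_event)
  }
  est <- comp(seq_along(outcome))
  ci <- NULL
  if (n_boot > 0L) {
    boot <- with_seed(substream_seed(seed, "nri_boot"), {
      vapply(seq_len(n_boot), function(b) {
        repeat {
          idx <- sample.int(length(outcome), replace = TRUE)
          if (length(unique(outcome[idx])) == 2L) break
        }
        comp(idx)
      }, numeric(3))
    })
    ci <- t(apply(boot, 1L, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE))
    dimnames(ci) <- list(c("overall", "event", "non_event"),
                         c("lo", "hi"))
  }
  list(overall = unname(est["overall"]), event = unname(est["event"]),
       non_event = unname(est["non_event"]), ci = ci, mode = mode)
}
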