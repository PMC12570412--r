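#' Default boosting hyperparameters for factor ranking
#'
#' Fixed, documented settings for the gradient-boosted ranking stage: DART
#' booster (additive regression trees with tree dropout), 100 boosting
#' rounds, learning rate 0.1, depth-4 trees, dropout rate 0.1, histogram
#' split finding, single thread (for reproducibility).
#'
#' @return A named list understood by [rank_factors()] and
#'   [sequential_select()].
#' @export
default_boost_params <- function() {
  list(nrounds = 100L, eta = 0.1, max_depth = 4L, rate_drop = 0.1,
       skip_drop = 0.25, min_child_weight = 1)
}

# integer level codes, one column per factor; trees split on the codes so
# information gain aggregates per factor without one-hot expansion
factor_matrix <- function(data, factors) {
  m <- vapply(factors, function(nm) as.numeric(data[[nm]]) - 1, numeric(nrow(data)))
  m <- matrix(m, nrow = nrow(data), dimnames = list(NULL, factors))
  m
}

train_boost <- function(X, y, w, hyper, seed) {
  dm <- xgboost::xgb.DMatrix(X, label = y, weight = w, nthread = 1)
  params <- list(booster = "dart", objective = "binary:logistic",
                 eta = hyper$eta, max_depth = hyper$max_depth,
                 rate_drop = hyper$rate_drop, skip_drop = hyper$skip_drop,
                 min_child_weight = hyper$min_child_weight,
                 tree_method = "hist", nthread = 1)
  with_seed(seed,
            xgboost::xgb.train(params, dm, nrounds = hyper$nrounds, verbose = 0))
}

#' Rank social factors by boosted-tree information gain
#'
#' Fits a dropout-regularised gradient-boosted tree ensemble (DART) to the
#' binary outcome on the full cohort and ranks every catalog factor by its
#' total information gain — the cumulative loss reduction attributed to splits
#' on that factor. Factors the ensemble never splits on (e.g. constant
#' columns) receive gain 0. Sampling weights are passed as instance weights
#' unless `use_weights = FALSE`.
#'
#' @param data Complete-case cohort data frame (no missing values in
#'   `outcome` or the ranked factors).
#' @param catalog A `factor_catalog`.
#' @param factors Factors to rank (default: all catalog factors).
#' @param hyperparams Boosting settings, see [default_boost_params()].
#' @param use_weights Pass sampling weights as instance weights (default TRUE).
#' @param seed RNG seed controlling the dropout draws; fixed seed gives an
#'   identical ranking on rerun.
#' @return A data frame of class `importance_ranking` with columns `factor`,
#'   `gain`, `rank`, sorted by decreasing gain.
#' @export
rank_factors <- function(data, catalog, factors = catalog_names(catalog),
                         hyperparams = default_boost_params(),
                         use_weights = TRUE, seed = 1L) {
  stopifnot(inherits(catalog, "factor_catalog"))
  cc <- stats::complete.cases(data[, c("outcome", factors), drop = FALSE])
  if (!all(cc))
    stop("rank_factors requires complete cases on outcome and factors; ",
         sum(!cc), " row(s) have missing values", call. = FALSE)
  check_binary_outcome(data$outcome)
  hyper <- utils::modifyList(default_boost_params(), hyperparams)
  X <- factor_matrix(data, factors)
  w <- if (use_weights) data$weight else rep(1, nrow(data))
  bst <- train_boost(X, data$outcome, w, hyper, substream_seed(seed, "rank"))
  imp <- xgboost::xgb.importance(model = bst)
  gain <- stats::setNames(rep(0, length(factors)), factors)
  gain[imp$Feature] <- imp$Gain
  ord <- order(-gain)
  out <- data.frame(factor = factors[ord], gain = unname(gain[ord]),
                    rank = seq_along(factors), stringsAsFactors = FALSE)
  class(out) <- c("importance_ranking", class(out))
  out
}

#' AUC of two correlated score vectors with DeLong covariance
#'
#' Computes the (optionally weighted) Mann-Whitney AUC of each score vector
#' against the same binary outcome, together with the variances and the
#' covariance of the two AUC estimates from DeLong's structural components
#' (placement values): the placement of an event is the proportion of
#' non-events it out-scores (ties count one half), and variances combine the
#' event-side and non-event-side empirical covariances of the placements.
#' With sampling weights, placements and their covariances are
#' weight-averaged and scaled by Kish effective sample sizes; at equal
#' weights this reduces exactly to DeLong's estimator.
#'
#' @param scores_a,scores_b Numeric score vectors aligned to `outcome`.
#' @param outcome 0/1 vector containing both classes.
#' @param weights Optional positive sampling weights.
#' @return A list with `auc_a`, `auc_b`, `var_a`, `var_b`, `cov_ab`.
#' @export
auc_with_covariance <- function(scores_a, scores_b, outcome, weights = NULL) {
  check_binary_outcome(outcome)
  stopifnot(length(scores_a) == length(outcome),
            length(scores_b) == length(outcome))
  if (is.null(weights)) weights <- rep(1, length(outcome))
  stopifnot(all(weights > 0))
  ev <- outcome == 1
  m <- sum(ev); n <- sum(!ev)
  wa <- weights[ev]; wb <- weights[!ev]

  # weighted placements via sorted unique values: for each point, the
  # weight of opposite-class points it out-scores plus half the tied weight
  place_against <- function(x, y, wy) {
    ord <- order(y)
    ys <- y[ord]; ws <- wy[ord]
    new_val <- !duplicated(ys)
    yu <- ys[new_val]
    wu <- as.numeric(rowsum(ws, cumsum(new_val)))
    cumw <- cumsum(wu)
    idx <- findInterval(x, yu)
    w_le <- ifelse(idx == 0, 0, cumw[pmax(idx, 1)])
    tie <- ifelse(idx > 0 & yu[pmax(idx, 1)] == x, wu[pmax(idx, 1)], 0)
    (w_le - tie + 0.5 * tie) / sum(wy)
  }
  placements <- function(s) {
    x <- s[ev]; y <- s[!ev]
    v10 <- place_against(x, y, wb)
    v01 <- 1 - place_against(y, x, wa)
    auc <- sum(wa * v10) / sum(wa)
    list(v10 = v10, v01 = v01, auc = auc)
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)

  wcov <- function(u, v, w) {
    neff <- kish_neff(w)
    mu_u <- sum(w * u) / sum(w); mu_v <- sum(w * v) / sum(w)
    sum(w * (u - mu_u) * (v - mu_v)) / sum(w) * neff / (neff - 1)
  }
  neff_m <- kish_neff(wa); neff_n <- kish_neff(wb)
  s10 <- function(u, v) wcov(u, v, wa) / neff_m
  s01 <- function(u, v) wcov(u, v, wb) / neff_n
  list(auc_a = pa$auc, auc_b = pb$auc,
       var_a = s10(pa$v10, pa$v10) + s01(pa$v01, pa$v01),
       var_b = s10(pb$v10, pb$v10) + s01(pb$v01, pb$v01),
       cov_ab = s10(pa$v10, pb$v10) + s01(pa$v01, pb$v01))
}

#' Paired DeLong test for the difference of two correlated AUCs
#'
#' @inheritParams auc_with_covariance
#' @return A list with `auc_a`, `auc_b`, `delta_auc`, `z` and the two-sided
#'   normal-approximation `p`. When the variance of the difference is zero
#'   (e.g. identical score vectors) `p = 1` with a warning.
#' @export
delong_test <- function(scores_a, scores_b, outcome, weights = NULL) {
  ac <- auc_with_covariance(scores_a, scores_b, outcome, weights)
  delta <- ac$auc_a - ac$auc_b
  v <- ac$var_a + ac$var_b - 2 * ac$cov_ab
  if (v <= .Machine$double.eps^0.5) {
    if (abs(delta) > .Machine$double.eps^0.5)
      warning("zero variance with nonzero AUC difference")
    else warning("zero variance of the AUC difference; p set to 1")
    return(list(auc_a = ac$auc_a, auc_b = ac$auc_b, delta_auc = delta,
                z = 0, p = 1))
  }
  z <- delta / sqrt(v)
  list(auc_a = ac$auc_a, auc_b = ac$auc_b, delta_auc = delta, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

# out-of-fold DART predictions for a fixed fold assignment
boost_oof <- function(X, y, w, folds, hyper, seed) {
  pred <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    bst <- train_boost(X[tr, , drop = FALSE], y[tr], w[tr], hyper,
                       substream_seed(seed, paste0("fold", f)))
    pred[!tr] <- stats::predict(
      bst, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], nthread = 1))
  }
  pred
}

#' Forward model-size selection gated by sequential DeLong tests
#'
#' Starting from the gain ranking, models with the top-k factors
#' (k = 1, 2, ...) are evaluated by stratified cross-validated out-of-fold
#' prediction (same folds for every k). Each added factor is tested against
#' the previous model with a paired DeLong test on the out-of-fold scores;
#' scanning stops once two consecutive added factors each fail the test at
#' `alpha` (no incremental gain), and the selected size `stop_k` is the k
#' with the highest AUC among the scanned models.
#'
#' With fewer than 3 ranked factors no stopping rule can operate: all factors
#' are evaluated and the trace is flagged `no_stopping_possible`.
#'
#' @param data Complete-case cohort data frame.
#' @param ranking An `importance_ranking` (or data frame with a `factor`
#'   column in rank order).
#' @param alpha Two-sided significance level of the DeLong gate (default
#'   0.05). An added factor counts as a non-improvement when `p >= alpha`, so
#'   `alpha = 0` stops after the first two comparisons and `alpha = 1` scans
#'   the whole ranking.
#' @param k_folds Number of cross-validation folds (default 5, stratified on
#'   the outcome).
#' @param hyperparams,use_weights,seed As in [rank_factors()].
#' @return An object of class `selection_trace`: list with `steps` (data
#'   frame: `k`, `factor_added`, `auc`, `se`, `delong_p`), `stop_k`,
#'   `selected` (first `stop_k` factor names), `alpha`,
#'   `no_stopping_possible`.
#' @export
sequential_select <- function(data, ranking, alpha = 0.05, k_folds = 5L,
                              hyperparams = default_boost_params(),
                              use_weights = TRUE, seed = 1L) {
  factors <- as.character(ranking$factor)
  if (length(factors) == 0L) stop("ranking is empty", call. = FALSE)
  check_binary_outcome(data$outcome)
  hyper <- utils::modifyList(default_boost_params(), hyperparams)
  w <- if (use_weights) data$weight else rep(1, nrow(data))
  folds <- stratified_folds(data$outcome, k_folds, substream_seed(seed, "folds"))
  no_stop <- length(factors) < 3L

  steps <- data.frame(k = integer(), factor_added = character(),
                      auc = numeric(), se = numeric(), delong_p = numeric(),
                      stringsAsFactors = FALSE)
  oof_prev <- NULL
  nonsig <- 0L
  for (k in seq_along(factors)) {
    X <- factor_matrix(data, factors[seq_len(k)])
    oof <- boost_oof(X, data$outcome, w, folds, hyper,
                     substream_seed(seed, paste0("select_k", k)))
    ac <- auc_with_covariance(oof, oof, data$outcome, w)
    p <- NA_real_
    if (!is.null(oof_prev)) {
      p <- suppressWarnings(delong_test(oof, oof_prev, data$outcome, w)$p)
      nonsig <- if (p >= alpha) nonsig + 1L else 0L
    }
    steps <- rbind(steps, data.frame(
      k = k, factor_added = factors[k], auc = ac$auc_a,
      se = sqrt(max(ac$var_a, 0)), delong_p = p, stringsAsFactors = FALSE))
    oof_prev <- oof
    if (!no_stop && nonsig >= 2L) break
  }
  stop_k <- steps$k[which.max(steps$auc)]
  structure(list(steps = steps, stop_k = stop_k,
                 selected = factors[seq_len(stop_k)], alpha = alpha,
                 no_stopping_possible = no_stop),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Sequential factor selection (alpha =", x$alpha, ")\n")
  s <- x$steps
  s$auc <- round(s$auc, 4); s$se <- round(s$se, 4)
  s$delong_p <- signif(s$delong_p, 3)
  print.data.frame(s, row.names = FALSE)
  cat("Selected", x$stop_k, "factor(s)",
      if (x$no_stopping_possible) "(too few factors for the stopping rule)",
      "\n")
  invisible(x)
}
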