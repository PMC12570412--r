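#' Chained-equations multiple imputation of categorical factor columns
#'
#' Column-by-column conditional imputation: each target column is modelled by
#' multinomial logistic regression on gender, age group, the outcome and the
#' other factor columns (entered as integer level codes for tractability),
#' fitted on the originally observed rows with the current completed values
#' of the predictors, and missing cells are replaced by draws from the fitted
#' category probabilities. The cycle over columns is repeated `iterations`
#' times, and `m` independent completed datasets are produced from separate
#' RNG substreams. Observed cells are never modified.
#'
#' @param data Cohort data frame.
#' @param columns Factor columns to impute (default: every factor column with
#'   missing values among those in `catalog`-style factor columns present).
#' @param m Number of completed datasets (default 10).
#' @param iterations Chained cycles per dataset (default 10).
#' @param seed Master seed.
#' @return An object of class `imputation_result`: list with `m`, `datasets`
#'   (list of completed cohorts), `iterations`, and `method` (per-column,
#'   always `"categorical-draw"`).
#' @export
mice_impute <- function(data, columns = NULL, m = 10L, iterations = 10L,
                        seed = 1L) {
  if (is.null(columns)) {
    cand <- setdiff(names(data), reserved_cols)
    columns <- cand[vapply(cand, function(cl) anyNA(data[[cl]]), TRUE)]
  }
  for (cl in columns) {
    if (!cl %in% names(data)) stop("unknown column ", sQuote(cl), call. = FALSE)
    if (all(is.na(data[[cl]])))
      stop("column ", sQuote(cl), " is entirely missing; cannot impute",
           call. = FALSE)
    if (!is.factor(data[[cl]]))
      stop("column ", sQuote(cl), " must be a factor", call. = FALSE)
  }
  if (length(columns) == 0L || !anyNA(data[, columns, drop = FALSE])) {
    return(structure(list(m = m, datasets = rep(list(data), m),
                          iterations = 0L,
                          method = stats::setNames(rep("categorical-draw",
                                                       length(columns)), columns)),
                     class = "imputation_result"))
  }
  predictors_for <- function(target) {
    others <- setdiff(columns, target)
    base <- c("gender", "age_group", if (!anyNA(data$outcome)) "outcome")
    c(base, others)
  }
  code <- function(x) if (is.factor(x)) as.numeric(x) else as.numeric(x)

  impute_once <- function(sub_seed) {
    with_seed(sub_seed, {
      comp <- data
      for (cl in columns) { # initial fill: draws from the observed marginal
        miss <- is.na(comp[[cl]])
        obs <- comp[[cl]][!miss]
        comp[[cl]][miss] <- sample(obs, sum(miss), replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (cl in columns) {
          miss <- is.na(data[[cl]])
          if (!any(miss)) next
          pr <- predictors_for(cl)
          X <- as.data.frame(lapply(comp[pr], code))
          y_obs <- droplevels(data[[cl]][!miss])
          if (nlevels(y_obs) < 2L) { # observed part is constant: draw it
            comp[[cl]][miss] <- levels(y_obs)[1]
            next
          }
          df_fit <- X[!miss, , drop = FALSE]
          df_fit$.y <- y_obs
          fit <- nnet::multinom(.y ~ ., data = df_fit,
                                trace = FALSE, maxit = 200)
          pp <- stats::predict(fit, newdata = X[miss, , drop = FALSE],
                               type = "probs")
          if (is.null(dim(pp))) pp <- cbind(1 - pp, pp) # binary target
          draws <- apply(pp, 1L, function(p)
            sample(levels(y_obs), 1L, prob = pmax(p, 0)))
          comp[[cl]][miss] <- factor(draws, levels = levels(data[[cl]]))
        }
      }
      comp
    })
  }
  datasets <- lapply(seq_len(m), function(i)
    impute_once(substream_seed(seed, paste0("imputation", i))))
  structure(list(m = m, datasets = datasets, iterations = iterations,
                 method = stats::setNames(rep("categorical-draw",
                                              length(columns)), columns)),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("Multiple imputation:", x$m, "completed dataset(s),",
      x$iterations, "chained cycle(s),", length(x$method), "column(s)\n")
  invisible(x)
}

#' Factor-selection agreement between two analysis runs
#'
#' Compares the factor sets selected by two runs (e.g. complete-case vs
#' pooled-imputation) by intersection count and Jaccard index.
#'
#' @param trace_a,trace_b `selection_trace` objects or character vectors of
#'   selected factor names.
#' @return An object of class `overlap_report`: list with `selected_a`,
#'   `selected_b`, `overlap` (the common factors), `overlap_count`,
#'   `jaccard`.
#' @export
selection_overlap <- function(trace_a, trace_b) {
  sel <- function(x) {
    if (inherits(x, "selection_trace")) unique(x$selected)
    else unique(as.character(x))
  }
  a <- sel(trace_a); b <- sel(trace_b)
  ov <- intersect(a, b)
  un <- union(a, b)
  structure(list(selected_a = a, selected_b = b, overlap = ov,
                 overlap_count = length(ov),
                 jaccard = if (length(un)) length(ov) / length(un) else 1),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Selection overlap:", length(x$selected_a), "vs", length(x$selected_b),
      "factors;", x$overlap_count, "shared (Jaccard",
      round(x$jaccard, 3), ")\n")
  invisible(x)
}

#' Pooled factor selection across imputed datasets
#'
#' Runs the ranking and sequential-selection stages on every completed
#' dataset and keeps the factors chosen in more than half of them — the
#' majority-vote pooling rule for the variable-selection step.
#'
#' @param imputed An `imputation_result`.
#' @param catalog A `factor_catalog`.
#' @param alpha,k_folds,hyperparams,use_weights,seed Passed to
#'   [rank_factors()] / [sequential_select()].
#' @return Character vector of factors selected under imputation.
#' @export
pooled_selection <- function(imputed, catalog, alpha = 0.05, k_folds = 5L,
                             hyperparams = default_boost_params(),
                             use_weights = TRUE, seed = 1L) {
  stopifnot(inherits(imputed, "imputation_result"))
  votes <- table(unlist(lapply(seq_along(imputed$datasets), function(i) {
    d <- imputed$datasets[[i]]
    d <- complete_case_filter(d, c("outcome", catalog_names(catalog)))$data
    rk <- rank_factors(d, catalog, hyperparams = hyperparams,
                       use_weights = use_weights,
                       seed = substream_seed(seed, paste0("rank_imp", i)))
    tr <- sequential_select(d, rk, alpha = alpha, k_folds = k_folds,
                            hyperparams = hyperparams,
                            use_weights = use_weights,
                            seed = substream_seed(seed, paste0("sel_imp", i)))
    tr$selected
  })))
  names(votes)[votes > imputed$m / 2]
}
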