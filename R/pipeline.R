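#' Configure and run the full gender-stratified analysis
#'
#' `pipeline_config` validates the run configuration before any compute;
#' `run_pipeline` executes the whole pipeline per gender stratum: complete
#' case filtering, reference re-orientation, gain ranking, DeLong-gated
#' forward selection, weighted logistic fit, score card, participant scores,
#' quintile categories, crude and adjusted odds ratios (continuous and
#' categorical), and ten-fold cross-validated performance of the reference
#' covariate model against reference + continuous and reference + categorical
#' score models (C-statistic with paired DeLong comparison, Hosmer-Lemeshow
#' calibration, continuous NRI). Stage outputs are written as TSV with a
#' metadata header; the run manifest records the seed, a configuration hash,
#' stage timings and content checksums so that identical configuration and
#' seed reproduce identical checksums.
#'
#' @param cohort A cohort data frame, or `cohort_path` to a CSV.
#' @param catalog A `factor_catalog`, or `catalog_path` to a YAML dictionary.
#' @param cohort_path,catalog_path File alternatives to in-memory objects.
#' @param alpha Significance level of the selection gate (default 0.05).
#' @param k_folds Folds for the selection stage (default 5).
#' @param cv_folds Folds for the evaluation stage (default 10).
#' @param n_boot Bootstrap replicates for the NRI CIs (default 200).
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed); `NULL` uses a
#'   temporary directory.
#' @return `pipeline_config`: a validated config list.
#' @export
pipeline_config <- function(cohort = NULL, catalog = NULL,
                            cohort_path = NULL, catalog_path = NULL,
                            alpha = 0.05, k_folds = 5L, cv_folds = 10L,
                            n_boot = 200L, seed = 1L, out_dir = NULL) {
  if (is.null(catalog) && is.null(catalog_path))
    stop("config error: a catalog (or catalog_path) is required", call. = FALSE)
  if (is.null(cohort) && is.null(cohort_path))
    stop("config error: a cohort (or cohort_path) is required", call. = FALSE)
  if (!is.null(catalog_path) && !file.exists(catalog_path))
    stop("config error: catalog_path does not exist: ", catalog_path,
         call. = FALSE)
  if (!is.null(cohort_path) && !file.exists(cohort_path))
    stop("config error: cohort_path does not exist: ", cohort_path,
         call. = FALSE)
  stopifnot(alpha >= 0, alpha <= 1, k_folds >= 2, cv_folds >= 2)
  structure(list(cohort = cohort, catalog = catalog,
                 cohort_path = cohort_path, catalog_path = catalog_path,
                 alpha = alpha, k_folds = as.integer(k_folds),
                 cv_folds = as.integer(cv_folds), n_boot = as.integer(n_boot),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

md5_of <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  # stable text rendering, independent of session state
  writeLines(utils::capture.output(utils::str(obj, vec.len = 1e6,
                                              digits.d = 15)), tf)
  unname(tools::md5sum(tf))
}

# checksum of a written TSV ignoring its '#' metadata header
checksum_tsv <- function(path) {
  lines <- readLines(path)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(lines[!startsWith(lines, "#")], tf)
  unname(tools::md5sum(tf))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  catalog <- config$catalog %||% read_catalog(config$catalog_path)
  cohort <- config$cohort %||% read_cohort(config$cohort_path, catalog)
  out_dir <- config$out_dir %||% tempfile("polysocial_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  timings <- c()
  checksums <- c()
  results <- list()

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }
  emit <- function(name, df, meta = list()) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv_meta(df, path, c(list(seed = seed), meta))
    checksums[[paste0(name, ".tsv")]] <<- checksum_tsv(path)
    path
  }

  for (g in gender_levels) {
    dat_g <- cohort[cohort$gender == g, , drop = FALSE]
    gseed <- substream_seed(seed, paste0("stratum:", g))

    fl <- stage(paste0(g, ":complete_cases"),
                complete_case_filter(dat_g, c("outcome",
                                              catalog_names(catalog))))
    dg <- fl$data
    cat_g <- stage(paste0(g, ":orient"), orient_catalog(catalog, dg))

    ranking <- stage(paste0(g, ":rank"),
                     rank_factors(dg, cat_g, seed = gseed))
    emit(paste0("ranking_", g), ranking, list(gender = g))

    trace <- stage(paste0(g, ":select"),
                   sequential_select(dg, ranking, alpha = config$alpha,
                                     k_folds = config$k_folds, seed = gseed))
    emit(paste0("trace_", g), trace$steps,
         list(gender = g, stop_k = trace$stop_k))

    fit <- stage(paste0(g, ":fit"),
                 fit_weighted_logistic(dg, trace$selected, catalog = cat_g))
    card <- stage(paste0(g, ":scorecard"),
                  suppressWarnings(build_scorecard(fit, cat_g)))
    emit(paste0("card_", g), as.data.frame(card), list(gender = g))

    sc <- stage(paste0(g, ":score"), score_participants(dg, card))
    cats <- stage(paste0(g, ":categorize"),
                  categorize_scores(sc$score, scheme = "quintile"))
    dg$score <- sc$score
    dg$category <- cats$category
    emit(paste0("scores_", g),
         data.frame(id = sc$id, score = sc$score,
                    category = as.character(cats$category)),
         list(gender = g,
              cutoffs = paste(round(cats$cutoffs, 3), collapse = ",")))

    curve <- stage(paste0(g, ":lowess"), lowess_curve(dg$score, dg$outcome))
    emit(paste0("curve_", g), curve, list(gender = g))

    assoc <- stage(paste0(g, ":association"), rbind(
      estimate_ors(dg, "continuous", adjusted = FALSE),
      estimate_ors(dg, "continuous", adjusted = TRUE),
      estimate_ors(dg, "category", adjusted = FALSE),
      estimate_ors(dg, "category", adjusted = TRUE)))
    emit(paste0("assoc_", g), as.data.frame(assoc), list(gender = g))

    perf <- stage(paste0(g, ":evaluate"),
                  evaluate_models(dg, cv_folds = config$cv_folds,
                                  n_boot = config$n_boot, seed = gseed))
    emit(paste0("perf_", g), perf, list(gender = g))

    results[[g]] <- list(n = nrow(dg), n_dropped = fl$n_dropped,
                         ranking = ranking, trace = trace, fit = fit,
                         card = card, scores = dg[, c("id", "score", "category")],
                         cutoffs = cats$cutoffs, curve = curve,
                         association = assoc, performance = perf)
  }

  manifest <- list(seed = seed,
                   config_hash = md5_of(config[setdiff(names(config),
                                                       c("cohort", "catalog"))]),
                   cohort_hash = md5_of(cohort),
                   version = as.character(utils::packageVersion("polysocial")),
                   timings = timings, checksums = checksums,
                   out_dir = out_dir)
  yaml::write_yaml(manifest[c("seed", "config_hash", "cohort_hash",
                              "version", "checksums")],
                   file.path(out_dir, "manifest.yaml"))
  structure(list(manifest = manifest, results = results),
            class = "pipeline_result")
}

#' Table-3-style model performance for a scored stratum
#'
#' Compares the reference covariate-only model (age group, smoking, drinking,
#' sleep trouble) with reference + continuous score and reference +
#' categorical score, all by `cv_folds`-fold cross-validated out-of-fold
#' prediction: C-statistic with 95% CI, paired DeLong delta against the
#' reference, Hosmer-Lemeshow statistic, and continuous NRI with bootstrap
#' CIs.
#'
#' @param data Stratum data frame with `outcome`, `weight`, covariates,
#'   `score`, `category`.
#' @param cv_folds Cross-validation folds (default 10).
#' @param n_boot NRI bootstrap replicates.
#' @param seed Seed for folds and bootstrap.
#' @return Data frame, one row per model, with discrimination, calibration
#'   and reclassification columns.
#' @export
evaluate_models <- function(data, cv_folds = 10L, n_boot = 200L, seed = 1L) {
  keep <- stats::complete.cases(data[, c("outcome", default_adjustment,
                                         "score", "category")])
  df <- data[keep, , drop = FALSE]
  forms <- list(
    reference = stats::reformulate(default_adjustment, "outcome"),
    reference_continuous = stats::reformulate(c(default_adjustment, "score"),
                                              "outcome"),
    reference_categorical = stats::reformulate(c(default_adjustment, "category"),
                                               "outcome"))
  preds <- lapply(seq_along(forms), function(i)
    crossval_predictions(df, forms[[i]], k = cv_folds,
                         seed = substream_seed(seed, names(forms)[i])))
  names(preds) <- names(forms)
  rows <- lapply(names(forms), function(mn) {
    p <- preds[[mn]]
    hl <- hosmer_lemeshow(p, df$outcome)
    if (mn == "reference") {
      cs <- c_statistic_delta(p, p, df$outcome)
      data.frame(model = mn, c_statistic = cs$c_new,
                 c_lo = cs$ci_new[1], c_hi = cs$ci_new[2],
                 delta_c = NA_real_, delta_p = NA_real_,
                 hl_statistic = hl$statistic, hl_p = hl$p,
                 nri_overall = NA_real_, nri_event = NA_real_,
                 nri_non_event = NA_real_, nri_lo = NA_real_,
                 nri_hi = NA_real_, stringsAsFactors = FALSE)
    } else {
      cs <- c_statistic_delta(preds$reference, p, df$outcome)
      nr <- nri(preds$reference, p, df$outcome, n_boot = n_boot,
                seed = substream_seed(seed, paste0("nri_", mn)))
      data.frame(model = mn, c_statistic = cs$c_new,
                 c_lo = cs$ci_new[1], c_hi = cs$ci_new[2],
                 delta_c = cs$delta, delta_p = cs$p,
                 hl_statistic = hl$statistic, hl_p = hl$p,
                 nri_overall = nr$overall, nri_event = nr$event,
                 nri_non_event = nr$non_event,
                 nri_lo = if (is.null(nr$ci)) NA_real_ else nr$ci["overall", "lo"],
                 nri_hi = if (is.null(nr$ci)) NA_real_ else nr$ci["overall", "hi"],
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Polysocial pipeline run (seed", x$manifest$seed, ")\n")
  for (g in names(x$results)) {
    r <- x$results[[g]]
    cat(" ", g, ": n =", r$n, "| selected", r$trace$stop_k,
        "factors | score range",
        paste(range(r$scores$score, na.rm = TRUE), collapse = "-"), "\n")
  }
  cat("  outputs:", x$manifest$out_dir, "\n")
  invisible(x)
}
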