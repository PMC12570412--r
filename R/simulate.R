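#' Configure a synthetic survey cohort
#'
#' The generator emulates the design of an ageing survey with oversampled old
#' age strata: participants aged 70-79 and 80+ are sampled at two and three
#' times their population share and carry compensating sampling weights
#' (inverse of the inflation factor, rescaled to mean 1). The binary
#' disability outcome is drawn from a logistic model whose linear predictor is
#' an intercept plus per-level log-odds for the social factors and lifestyle
#' covariates; factor-level marginals are drawn once per configuration from a
#' Dirichlet and stored, so a configuration fully determines the cohort.
#'
#' When `intercept` is `NULL` it is calibrated at simulation time (by root
#' finding on the realised linear predictors) so the marginal outcome
#' prevalence equals `target_prevalence`.
#'
#' @param catalog A `factor_catalog`; defaults to the built-in 29-factor one.
#' @param n_participants Cohort size (default 5000).
#' @param prop_men Expected proportion of men (default 0.37).
#' @param age_distribution Population shares of the `60-69`, `70-79`, `80+`
#'   strata (default `c(0.662, 0.258, 0.080)`).
#' @param oversample_factors Sampling inflation of the two oldest strata
#'   (default `c("70-79" = 2, "80+" = 3)`).
#' @param factor_effects Named list: factor name -> named numeric vector of
#'   per-level log-odds (reference levels implicitly 0).
#' @param covariate_effects Named list of per-level log-odds for
#'   `age_group`, `gender`, `smoking`, `drinking`, `sleep_trouble`.
#' @param intercept Logistic intercept, or `NULL` to calibrate.
#' @param target_prevalence Marginal outcome prevalence used for calibration
#'   (default 0.189).
#' @param missingness List with `mechanism` (`"MCAR"` or `"MAR"`) and `rate`
#'   (average per-cell missingness of the factor columns). The default rate
#'   0.0062 makes roughly 16.5% of rows incomplete across 29 factors. Under
#'   MAR the cell rate depends on age group and gender only.
#' @param seed Master seed; every column draws from its own derived substream,
#'   so adding factors never perturbs earlier columns.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(catalog = default_catalog(),
                              n_participants = 5000L,
                              prop_men = 0.37,
                              age_distribution = c(0.662, 0.258, 0.080),
                              oversample_factors = c("70-79" = 2, "80+" = 3),
                              factor_effects = list(),
                              covariate_effects = default_covariate_effects(),
                              intercept = NULL,
                              target_prevalence = 0.189,
                              missingness = list(mechanism = "MAR", rate = 0.0062),
                              seed = 1L) {
  stopifnot(inherits(catalog, "factor_catalog"),
            n_participants >= 1, prop_men >= 0, prop_men <= 1,
            length(age_distribution) == 3L, all(age_distribution >= 0),
            all(oversample_factors >= 1),
            missingness$rate >= 0, missingness$rate <= 1)
  missingness$mechanism <- match.arg(missingness$mechanism, c("MCAR", "MAR"))
  check_factor_effects(factor_effects, catalog)
  marginals <- draw_factor_marginals(catalog, seed)
  structure(list(
    catalog = catalog,
    n_participants = as.integer(n_participants),
    prop_men = prop_men,
    age_distribution = age_distribution / sum(age_distribution),
    oversample_factors = oversample_factors,
    factor_effects = factor_effects,
    covariate_effects = covariate_effects,
    intercept = intercept,
    target_prevalence = target_prevalence,
    missingness = missingness,
    factor_marginals = marginals,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

check_factor_effects <- function(effects, catalog) {
  for (nm in names(effects)) {
    if (!nm %in% catalog_names(catalog))
      stop("factor effect declared for unknown factor ", sQuote(nm),
           call. = FALSE)
    spec <- catalog_spec(catalog, nm)
    bad <- setdiff(names(effects[[nm]]), spec$levels)
    if (length(bad))
      stop("factor ", sQuote(nm), ": effect declared for unknown level(s) ",
           paste(sQuote(bad), collapse = ", "), call. = FALSE)
    if (spec$reference %in% names(effects[[nm]]) &&
        effects[[nm]][[spec$reference]] != 0)
      stop("factor ", sQuote(nm), ": reference level must have effect 0",
           call. = FALSE)
  }
  invisible(TRUE)
}

# Dirichlet(4,...,4) marginal per factor, each from its own substream
draw_factor_marginals <- function(catalog, seed) {
  out <- lapply(catalog_names(catalog), function(nm) {
    spec <- catalog_spec(catalog, nm)
    with_seed(substream_seed(seed, paste0("marginal:", nm)), {
      g <- stats::rgamma(length(spec$levels), shape = 4)
      stats::setNames(g / sum(g), spec$levels)
    })
  })
  stats::setNames(out, catalog_names(catalog))
}

#' @rdname simulation_config
#' @export
default_covariate_effects <- function() {
  list(
    age_group = c("70-79" = 0.5, "80+" = 1.2),
    gender = c(women = 0.2),
    smoking = c(former = 0.10, current = 0.25),
    drinking = c(lt_monthly = 0, monthly_weekly = -0.05, frequent = -0.10),
    sleep_trouble = c(rarely = 0.10, sometimes = 0.30, most_of_the_time = 0.60)
  )
}

# gender-specific lifestyle covariate marginals typical of ageing surveys
covariate_marginals <- list(
  smoking = list(men = c(never = 0.23, former = 0.47, current = 0.30),
                 women = c(never = 0.78, former = 0.12, current = 0.10)),
  drinking = list(men = c(none = 0.49, lt_monthly = 0.10,
                          monthly_weekly = 0.16, frequent = 0.25),
                  women = c(none = 0.84, lt_monthly = 0.01,
                            monthly_weekly = 0.03, frequent = 0.12)),
  sleep_trouble = list(men = c(never = 0.28, rarely = 0.31,
                               sometimes = 0.29, most_of_the_time = 0.12),
                       women = c(never = 0.19, rarely = 0.29,
                                 sometimes = 0.35, most_of_the_time = 0.17))
)

#' Simulate a survey cohort from a configuration
#'
#' @param config A `simulation_config`.
#' @return A cohort data frame (see [read_cohort()] for the column contract)
#'   with attributes `true_intercept` (the calibrated or supplied intercept)
#'   and `linear_predictor` (per-participant true log-odds).
#' @examples
#' cfg <- simulation_config(n_participants = 200, seed = 7)
#' coh <- simulate_cohort(cfg)
#' mean(coh$outcome)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  catalog <- config$catalog
  n <- config$n_participants
  seed <- config$seed
  sub <- function(key) substream_seed(seed, key)

  gender <- with_seed(sub("gender"), factor(
    ifelse(stats::rbinom(n, 1, config$prop_men) == 1, "men", "women"),
    levels = gender_levels))

  inflation <- c(1, unname(config$oversample_factors[c("70-79", "80+")]))
  samp_p <- config$age_distribution * inflation
  age_group <- with_seed(sub("age_group"), factor(
    sample(age_levels, n, replace = TRUE, prob = samp_p / sum(samp_p)),
    levels = age_levels))
  w_raw <- 1 / inflation[as.integer(age_group)]
  weight <- w_raw / mean(w_raw)

  cov_cols <- lapply(names(covariate_marginals), function(cv) {
    with_seed(sub(paste0("covariate:", cv)), {
      x <- character(n)
      for (gl in gender_levels) {
        idx <- which(gender == gl)
        p <- covariate_marginals[[cv]][[gl]]
        x[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
      }
      factor(x, levels = covariate_levels[[cv]])
    })
  })
  names(cov_cols) <- names(covariate_marginals)

  factor_cols <- lapply(catalog_names(catalog), function(nm) {
    p <- config$factor_marginals[[nm]]
    with_seed(sub(paste0("factor:", nm)), factor(
      sample(names(p), n, replace = TRUE, prob = p),
      levels = catalog_spec(catalog, nm)$levels))
  })
  names(factor_cols) <- catalog_names(catalog)

  lp <- numeric(n)
  for (nm in names(config$factor_effects)) {
    eff <- config$factor_effects[[nm]]
    lp <- lp + ifelse(as.character(factor_cols[[nm]]) %in% names(eff),
                      eff[as.character(factor_cols[[nm]])], 0)
  }
  ce <- config$covariate_effects
  add_effect <- function(lp, x, eff) {
    if (is.null(eff)) return(lp)
    lp + ifelse(as.character(x) %in% names(eff), eff[as.character(x)], 0)
  }
  lp <- add_effect(lp, age_group, ce$age_group)
  lp <- add_effect(lp, gender, ce$gender)
  lp <- add_effect(lp, cov_cols$smoking, ce$smoking)
  lp <- add_effect(lp, cov_cols$drinking, ce$drinking)
  lp <- add_effect(lp, cov_cols$sleep_trouble, ce$sleep_trouble)

  b0 <- config$intercept
  if (is.null(b0)) {
    b0 <- stats::uniroot(
      function(b) mean(stats::plogis(b + lp)) - config$target_prevalence,
      interval = c(-15, 15), tol = 1e-10)$root
  }
  outcome <- with_seed(sub("outcome"),
                       stats::rbinom(n, 1, stats::plogis(b0 + lp)))

  out <- data.frame(
    id = sprintf("P%06d", seq_len(n)),
    gender = gender, age_group = age_group, weight = weight,
    outcome = as.integer(outcome),
    smoking = cov_cols$smoking, drinking = cov_cols$drinking,
    sleep_trouble = cov_cols$sleep_trouble,
    stringsAsFactors = FALSE
  )
  for (nm in names(factor_cols)) out[[nm]] <- factor_cols[[nm]]

  # item missingness applied after outcome generation, factor columns only
  rate <- config$missingness$rate
  if (rate > 0) {
    mult <- if (config$missingness$mechanism == "MAR") {
      age_m <- c("60-69" = 0.8, "70-79" = 1.1, "80+" = 1.5)
      gen_m <- c(men = 0.9, women = 1.06)
      age_m[as.character(age_group)] * gen_m[as.character(gender)]
    } else rep(1, n)
    p_cell <- pmin(rate * mult, 1)
    for (nm in names(factor_cols)) {
      miss <- with_seed(sub(paste0("missing:", nm)),
                        stats::runif(n) < p_cell)
      out[[nm]][miss] <- NA
    }
  }
  attr(out, "true_intercept") <- b0
  attr(out, "linear_predictor") <- lp
  out
}

#' Factors given nonzero effects by the alternative preset
#' @export
informative_factors <- function() {
  c("freq_social_activities", "num_friends_contact",
    "religious_services_outside", "religious_activities_outside",
    "freq_gambling", "freq_seeing_friends", "it_access", "education")
}

#' Null and alternative simulation presets
#'
#' The null preset gives every social factor a zero effect on the outcome, so
#' forward selection should stop almost immediately. The alternative preset
#' gives eight factors (see [informative_factors()]) graded protective
#' log-odds between -0.3 and -1.2 — the magnitude range implied by point
#' scores of roughly 3 to 10 per level — and leaves the other 21 factors as
#' pure noise. Both presets use the survey design defaults (5000 participants,
#' 37% men, age oversampling with compensating weights, 18.9% target
#' prevalence, MAR item missingness).
#'
#' @param catalog A `factor_catalog` (default the built-in 29-factor one).
#' @param seed Master seed for both configurations.
#' @param ... Passed on to [simulation_config()] (e.g. `n_participants`,
#'   `missingness`).
#' @return A list with elements `null` and `alternative`, each a
#'   `simulation_config`.
#' @export
null_and_alternative_presets <- function(catalog = default_catalog(),
                                         seed = 1L, ...) {
  alt_effects <- list(
    freq_social_activities = c(a_few_times_a_year = -0.6, monthly = -0.9,
                               weekly = -1.2),
    num_friends_contact = c("1_2" = -0.4, "3_5" = -0.7, "6_plus" = -1.0),
    religious_services_outside = c(yes = -0.8),
    religious_activities_outside = c(yes = -0.7),
    freq_gambling = c(sometimes = -0.35, often = -0.7),
    freq_seeing_friends = c(yearly = -0.3, monthly = -0.6, weekly = -0.9),
    it_access = c(yes = -0.75),
    education = c(high_school = -0.4, college_plus = -0.8)
  )
  list(
    null = simulation_config(catalog = catalog, factor_effects = list(),
                             seed = seed, ...),
    alternative = simulation_config(catalog = catalog,
                                    factor_effects = alt_effects,
                                    seed = seed, ...)
  )
}
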